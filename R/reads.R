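# Read processing: quality trimming, pair merging, primer removal, length
# filtering and identity-threshold mapping of merged reads onto the designed
# library. The stage order is fixed: quality-trim -> merge -> primer-trim ->
# length-filter -> map. Phred+33 only.

#' Read / write FASTQ
#'
#' Thin wrappers around Biostrings' quality-scaled FASTQ support returning a
#' plain per-read representation (id, sequence, integer Phred vector).
#'
#' @param path FASTQ path.
#' @return `read_fastq()`: tibble with columns `id`, `seq`, and list-column
#'   `quals` of integer Phred scores.
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns about dropping its own metadata
  # columns; nothing user-relevant is lost
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ids <- sub(" .*$", "", names(qs))
  quals <- as.list(methods::as(Biostrings::quality(qs), "IntegerList"))
  tibble(id = ids, seq = as.character(qs), quals = quals)
}

#' @rdname read_fastq
#' @param ids,seqs Character vectors.
#' @param quals List of integer Phred vectors (one per read).
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  qchar <- vapply(quals, function(q) intToUtf8(pmin(q, 60L) + 33L), "")
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(qchar))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' 3'-end quality trimming (partial-sum rule)
#'
#' Subtracts the cutoff from every Phred score, forms partial sums from each
#' position to the 3' end, and cuts at the position where the sum is most
#' negative (leftmost on ties); reads whose sums never drop below zero are
#' untouched. The 5' end is never trimmed. Trimming a read to length zero is
#' allowed and flagged.
#'
#' @param seq DNA string.
#' @param quals Integer Phred vector, same length as `seq`.
#' @param cutoff Quality cutoff (default 30).
#' @return List with `seq`, `quals`, `n_trimmed`, and logical `empty`.
#' @export
trim_quality <- function(seq, quals, cutoff = 30L) {
  n <- nchar(seq)
  stopifnot(length(quals) == n)
  if (n == 0L) {
    return(list(seq = seq, quals = quals, n_trimmed = 0L, empty = TRUE))
  }
  if (any(quals < 0 | quals > 60)) {
    stop("Phred scores must be in [0, 60].", call. = FALSE)
  }
  diffs <- as.numeric(quals) - cutoff
  partial <- rev(cumsum(rev(diffs)))
  cut_at <- which.min(partial)
  keep <- if (partial[cut_at] < 0) cut_at - 1L else n
  list(seq = substr(seq, 1L, keep),
       quals = quals[seq_len(keep)],
       n_trimmed = n - keep,
       empty = keep == 0L)
}

#' Merge a read pair by best overlap
#'
#' The reverse read is reverse-complemented, then every relative offset of
#' the two reads is scored as matches minus mismatches; the best-scoring
#' overlap (ties: longer overlap, then smaller shift) is accepted only if it
#' spans at least `min_overlap` columns with at most `max_diffs` mismatches.
#' Consensus base = the higher-quality base (the forward read's on equal
#' quality); consensus quality = the larger of the two.
#'
#' @param r1,r2 Lists with elements `seq` and `quals` (forward and reverse
#'   mate; `r2` as sequenced, i.e. not yet reverse-complemented).
#' @param min_overlap Minimum overlap length (default 20).
#' @param max_diffs Maximum mismatches within the overlap (default 2).
#' @return On success, a list with `seq`, `quals`, `overlap_len`, `n_diffs`
#'   and `merged = TRUE`; on rejection, `merged = FALSE` plus a `reason`
#'   (`"short_overlap"` or `"too_many_diffs"`).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_diffs = 2L) {
  s1 <- r1$seq
  s2 <- cpp_revcomp(r2$seq)
  q1 <- as.integer(r1$quals)
  q2 <- rev(as.integer(r2$quals))
  if (!nzchar(s1) || !nzchar(s2)) {
    return(list(merged = FALSE, reason = "short_overlap"))
  }
  ov <- cpp_best_overlap(s1, s2)
  if (ov$overlap_len < min_overlap) {
    return(list(merged = FALSE, reason = "short_overlap"))
  }
  if (ov$n_diffs > max_diffs) {
    return(list(merged = FALSE, reason = "too_many_diffs"))
  }
  cons <- cpp_merge_consensus(s1, q1, s2, q2, ov$shift + 1L)
  list(merged = TRUE, seq = cons$seq, quals = cons$quals,
       overlap_len = ov$overlap_len, n_diffs = ov$n_diffs)
}

#' Remove anchored primer sequences from a merged read
#'
#' Checks the 5' end against the forward primer and the 3' end against the
#' reverse primer (and, because a merged read may come out in the opposite
#' orientation, the reverse complements of the other primer), removing an end
#' whenever it matches within `max_mismatch` substitutions. A missing primer
#' on either end is allowed (partial molecules) and recorded.
#'
#' @param merged List with `seq` and `quals` (from [merge_pairs()]).
#' @param fwd,rev Primer sequences (19 and 20 nt under the defaults).
#' @param max_mismatch Maximum Hamming distance for an anchored match
#'   (default 2).
#' @return List with `seq`, `quals`, and logical flags `fwd_trimmed`,
#'   `rev_trimmed`.
#' @export
trim_primers <- function(merged, fwd, rev, max_mismatch = 2L) {
  seq <- merged$seq
  quals <- merged$quals
  five <- c(fwd, cpp_revcomp(rev))
  three <- c(rev, cpp_revcomp(fwd))
  fwd_trimmed <- FALSE
  for (p in five) {
    np <- nchar(p)
    if (nchar(seq) > np &&
        cpp_hamming(substr(seq, 1L, np), p) <= max_mismatch) {
      seq <- substr(seq, np + 1L, nchar(seq))
      quals <- quals[-seq_len(np)]
      fwd_trimmed <- TRUE
      break
    }
  }
  rev_trimmed <- FALSE
  for (p in three) {
    np <- nchar(p)
    n <- nchar(seq)
    if (n > np && cpp_hamming(substr(seq, n - np + 1L, n), p) <= max_mismatch) {
      seq <- substr(seq, 1L, n - np)
      quals <- quals[seq_len(n - np)]
      rev_trimmed <- TRUE
      break
    }
  }
  list(seq = seq, quals = quals, fwd_trimmed = fwd_trimmed,
       rev_trimmed = rev_trimmed)
}

#' Length filter for merged reads
#'
#' @param len Integer vector of read lengths.
#' @param min_len,max_len Inclusive bounds (defaults 174 and 220; reads
#'   strictly shorter or longer are filtered out).
#' @return Logical vector: pass/fail.
#' @export
length_filter <- function(len, min_len = 174L, max_len = 220L) {
  len >= min_len & len <= max_len
}

#' Build a mapping index over the library inserts
#'
#' @param manifest A `pioneer_manifest`.
#' @return Opaque index object for [map_read()] / [map_reads()].
#' @export
library_index <- function(manifest) {
  stopifnot(inherits(manifest, "pioneer_manifest"))
  ids <- manifest$id
  inserts <- manifest$insert_seq
  exact <- new.env(parent = emptyenv(), size = 2L * length(ids) + 1L)
  for (i in seq_along(ids)) {
    assign(inserts[i], c(i, 1L), envir = exact)
  }
  rcs <- revcomp(inserts)
  for (i in seq_along(ids)) {
    if (is.null(exact[[rcs[i]]])) assign(rcs[i], c(i, -1L), envir = exact)
  }
  list(ids = ids, inserts = inserts, inserts_rc = rcs, exact = exact,
       insert_len = nchar(inserts))
}

#' Map one merged read to the library
#'
#' Decision rule: a semi-global alignment (read end to end, free end gaps on
#' the reference insert) against every candidate reference on both strands;
#' identity = matches / alignment columns (gap columns count against
#' identity). The single best-identity reference is accepted if the alignment
#' spans at least `min_cols` columns and reaches `min_id` identity; a tie in
#' best identity across two or more references discards the read as
#' ambiguous. The linear gap penalty is strong (-10 against +1/-1
#' match/mismatch), so substitution-dominated reads align ungapped and the
#' identity boundary is exact. A cheap ungapped screen shortlists references
#' first
#' (`screen_margin` below the best screened identity); the accept/reject
#' decision is always made by the alignment. Reads identical to a reference
#' insert take an exact-match fast path.
#'
#' @param seq Merged, primer-trimmed read sequence.
#' @param index From [library_index()].
#' @param min_cols Minimum alignment columns (default 150).
#' @param min_id Minimum identity (default 0.985).
#' @param screen_margin Screen shortlist width (default 0.02).
#' @return List: `mapped` (logical), and when mapped `library_id`,
#'   `identity`, `aln_cols`, `insert_start`, `insert_end`, `strand`;
#'   otherwise `reason` (`"low_identity"`, `"short_alignment"`,
#'   `"ambiguous"`).
#' @export
map_read <- function(seq, index, min_cols = 150L, min_id = 0.985,
                     screen_margin = 0.02) {
  hit <- index$exact[[seq]]
  if (!is.null(hit)) {
    n <- nchar(seq)
    if (n < min_cols) return(list(mapped = FALSE, reason = "short_alignment"))
    return(list(mapped = TRUE, library_id = index$ids[hit[1]], identity = 1,
                aln_cols = n, insert_start = 1L, insert_end = n,
                strand = if (hit[2] > 0) "+" else "-"))
  }
  rc <- cpp_revcomp(seq)
  nref <- length(index$ids)
  screen_f <- vapply(index$inserts, cpp_ungapped_screen, 0, read = seq,
                     USE.NAMES = FALSE)
  screen_r <- vapply(index$inserts, cpp_ungapped_screen, 0, read = rc,
                     USE.NAMES = FALSE)
  best_screen <- max(screen_f, screen_r)
  cand <- which(pmax(screen_f, screen_r) >= best_screen - screen_margin)
  res <- lapply(cand, function(i) {
    a_f <- cpp_semiglobal(seq, index$inserts[i])
    a_r <- cpp_semiglobal(rc, index$inserts[i])
    id_f <- a_f$matches / a_f$aln_cols
    id_r <- a_r$matches / a_r$aln_cols
    if (id_f >= id_r) c(i, id_f, a_f$aln_cols, a_f$ref_start, a_f$ref_end, 1)
    else c(i, id_r, a_r$aln_cols, a_r$ref_start, a_r$ref_end, -1)
  })
  res <- do.call(rbind, res)
  ok <- res[, 3] >= min_cols & res[, 2] >= min_id
  if (!any(ok)) {
    reason <- if (any(res[, 3] >= min_cols)) "low_identity" else
      "short_alignment"
    return(list(mapped = FALSE, reason = reason))
  }
  res <- res[ok, , drop = FALSE]
  best <- max(res[, 2])
  top <- which(res[, 2] >= best - 1e-12)
  if (length(unique(res[top, 1])) > 1L) {
    return(list(mapped = FALSE, reason = "ambiguous"))
  }
  r <- res[top[1], ]
  list(mapped = TRUE, library_id = index$ids[r[1]], identity = r[2],
       aln_cols = as.integer(r[3]), insert_start = as.integer(r[4]),
       insert_end = as.integer(r[5]), strand = if (r[6] > 0) "+" else "-")
}

#' Tabulate mapped reads into a per-library count table
#'
#' @param assignments Tibble with columns `read_id`, `library_id` (`NA` for
#'   discarded reads) and `reason` (`"mapped"` or a discard reason).
#' @param manifest A `pioneer_manifest` (all its ids appear in the output,
#'   zero-filled).
#' @param sample,band Labels stored on the result.
#' @return A `band_counts` tibble (`library_id`, `count`) with attributes
#'   `sample`, `band`, `total_mapped`, `discards` (named integer vector).
#'   Counts plus discards always equal the number of input reads, and the
#'   table is independent of input read order.
#' @export
build_count_table <- function(assignments, manifest, sample = "sample",
                              band = "band") {
  stopifnot(all(c("read_id", "library_id", "reason") %in% names(assignments)))
  mapped <- assignments[assignments$reason == "mapped", ]
  unknown <- setdiff(unique(mapped$library_id), manifest$id)
  if (length(unknown)) {
    stop("Mapped ids not in manifest: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(mapped$library_id, levels = manifest$id))
  discards <- table(assignments$reason[assignments$reason != "mapped"])
  out <- tibble(library_id = manifest$id, count = as.integer(counts))
  structure(out, class = c("band_counts", class(out)),
            sample = sample, band = band,
            total_mapped = nrow(mapped),
            discards = setNames(as.integer(discards), names(discards)))
}

#' Extract a named count vector from a count table
#'
#' @param x A `band_counts` tibble (or any tibble with `library_id` and
#'   `count`), or an already-named numeric vector.
#' @return Named numeric vector of counts.
#' @export
as_counts <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stopifnot(is.data.frame(x), all(c("library_id", "count") %in% names(x)))
  setNames(as.numeric(x$count), x$library_id)
}

#' Run the full band pipeline: FASTQ pair -> count table
#'
#' Applies, in order: 3' quality trimming, pair merging, primer trimming,
#' length filtering, and identity-threshold mapping. Every input pair ends in
#' exactly one bucket: a library count or one discard reason.
#'
#' @param fastq1,fastq2 Paths to the mate FASTQ files.
#' @param manifest A `pioneer_manifest`.
#' @param sample,band Labels for the resulting count table.
#' @param cutoff Quality-trim cutoff (default 30).
#' @param min_overlap,max_diffs Merge thresholds (defaults 20 and 2).
#' @param primer_max_mismatch Primer-trim mismatch allowance (default 2).
#' @param min_len,max_len Length-filter bounds (defaults 174 and 220).
#' @param min_cols,min_id Mapping thresholds (defaults 150 and 0.985).
#' @return List with `counts` (a `band_counts`), `fragments` (tibble of
#'   mapped insert spans: `read_id`, `library_id`, `insert_start`,
#'   `insert_end`), and `assignments` (the per-read decision table).
#' @export
process_band <- function(fastq1, fastq2, manifest, sample = "sample",
                         band = "band", cutoff = 30L, min_overlap = 20L,
                         max_diffs = 2L, primer_max_mismatch = 2L,
                         min_len = 174L, max_len = 220L, min_cols = 150L,
                         min_id = 0.985) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (nrow(r1) != nrow(r2) || !identical(r1$id, r2$id)) {
    stop("FASTQ mates must be in matching order with matching ids.",
         call. = FALSE)
  }
  primers <- attr(manifest, "primers")
  index <- library_index(manifest)
  n <- nrow(r1)
  library_id <- rep(NA_character_, n)
  reason <- character(n)
  insert_start <- rep(NA_integer_, n)
  insert_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    t1 <- trim_quality(r1$seq[i], r1$quals[[i]], cutoff)
    t2 <- trim_quality(r2$seq[i], r2$quals[[i]], cutoff)
    if (t1$empty || t2$empty) {
      reason[i] <- "empty_after_trim"
      next
    }
    m <- merge_pairs(t1, t2, min_overlap, max_diffs)
    if (!m$merged) {
      reason[i] <- m$reason
      next
    }
    p <- trim_primers(m, primers[["fwd"]], primers[["rev"]],
                      primer_max_mismatch)
    if (!length_filter(nchar(p$seq), min_len, max_len)) {
      reason[i] <- "length"
      next
    }
    mp <- map_read(p$seq, index, min_cols, min_id)
    if (!mp$mapped) {
      reason[i] <- mp$reason
      next
    }
    reason[i] <- "mapped"
    library_id[i] <- mp$library_id
    insert_start[i] <- mp$insert_start
    insert_end[i] <- mp$insert_end
  }
  assignments <- tibble(read_id = r1$id, library_id = library_id,
                        reason = reason)
  counts <- build_count_table(assignments, manifest, sample, band)
  fragments <- tibble(read_id = r1$id, library_id = library_id,
                      insert_start = insert_start,
                      insert_end = insert_end)[reason == "mapped", ]
  list(counts = counts, fragments = fragments, assignments = assignments)
}
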