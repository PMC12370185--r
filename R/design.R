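#' A nucleosome positioning sequence (NPS) insert
#'
#' A 191-nt insert holding one positioned nucleosome: a 147-bp core flanked by
#' two 22-bp linkers under the defaults. The dyad index is the coordinate
#' origin for all tiling offsets.
#'
#' @param id Short label, e.g. `"601syn"`.
#' @param insert_seq 191-nt DNA string.
#' @param dyad_index 1-based dyad position within the insert (default 96; must
#'   equal the midpoint of `core_span`).
#' @param core_span Integer pair, 1-based inclusive bounds of the 147-bp core
#'   (default `c(23, 169)`).
#' @return Object of class `nps_record`.
#' @export
nps_record <- function(id, insert_seq, dyad_index = 96L,
                       core_span = c(23L, 169L)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  .check_dna(insert_seq, "insert_seq", len = 191L)
  core_span <- as.integer(core_span)
  dyad_index <- as.integer(dyad_index)
  if (length(core_span) != 2L || diff(core_span) + 1L != 147L) {
    stop("core_span must be a 147-bp 1-based inclusive interval.",
         call. = FALSE)
  }
  if (dyad_index != (core_span[1] + core_span[2]) %/% 2L) {
    stop("dyad_index must be the midpoint of core_span.", call. = FALSE)
  }
  structure(list(id = id, insert_seq = toupper(insert_seq),
                 dyad_index = dyad_index, core_span = core_span),
            class = "nps_record")
}

#' @export
print.nps_record <- function(x, ...) {
  cat("<nps_record> ", x$id, ": 191 nt, dyad @", x$dyad_index,
      ", core [", x$core_span[1], ",", x$core_span[2], "]\n", sep = "")
  invisible(x)
}

#' The default tiling grid of dyad offsets
#'
#' Motif-center offsets -74..+74 relative to the dyad: 149 positions spanning
#' the whole 147-bp core plus one position in each linker. The span is
#' configurable in [tile_tfbs()]; this default reproduces the canonical
#' 149-sequences-per-TFBS-per-NPS library layout.
#'
#' @return Integer vector of offsets.
#' @export
default_tiling_grid <- function() -74:74

#' Tile a TFBS across an NPS at every grid offset
#'
#' The motif is placed by substitution (never insertion) so every insert stays
#' 191 nt and dyad coordinates remain comparable across offsets. The motif
#' center (left-of-center base for even lengths) lands at
#' `dyad_index + offset`.
#'
#' @param nps A scrubbed [nps_record()].
#' @param motif A [tfbs_motif()].
#' @param offsets Integer dyad offsets (default [default_tiling_grid()]).
#' @param category Manifest category for the output rows: `"tiled"` for sites
#'   assigned to a factor, `"control"` for nonspecific backbones. Defaults to
#'   `"control"` when the motif has no TF assignment.
#' @return Tibble with one row per offset: `id`, `category`, `nps_id`,
#'   `tfbs_id`, `dyad_offset`, `tfbs_start`, `tfbs_end`, `insert_seq`.
#' @examples
#' nps <- nps_record("demo", paste(rep("ACGT", 48), collapse = ""),
#'                   dyad_index = 96, core_span = c(23, 169))
#' nrow(tile_tfbs(nps, tfbs_motif("Klf4-1", "CCCCACCC", tf = "KLF4")))
#' @export
tile_tfbs <- function(nps, motif, offsets = default_tiling_grid(),
                      category = NULL) {
  stopifnot(inherits(nps, "nps_record"), inherits(motif, "tfbs_motif"))
  offsets <- as.integer(offsets)
  category <- category %||% (if (length(motif$tf)) "tiled" else "control")
  L <- nchar(motif$site_seq)
  cidx <- motif_center_index(L)
  center <- nps$dyad_index + offsets
  start <- center - cidx + 1L
  end <- start + L - 1L
  bad <- which(start < 1L | end > 191L)
  if (length(bad)) {
    stop("Motif '", motif$id, "' (", L, " nt) overruns the 191-nt insert at ",
         "offset(s) ", paste(offsets[bad], collapse = ", "),
         "; shrink the grid or shorten the motif.", call. = FALSE)
  }
  inserts <- vapply(seq_along(offsets), function(i) {
    s <- nps$insert_seq
    substr(s, start[i], end[i]) <- motif$site_seq
    s
  }, "")
  tibble(
    id = sprintf("%s_%s_%+d", nps$id, motif$id, offsets),
    category = category,
    nps_id = nps$id,
    tfbs_id = motif$id,
    dyad_offset = offsets,
    tfbs_start = start,
    tfbs_end = end,
    region = NA_character_,
    score = NA_real_,
    insert_seq = inserts
  )
}

#' Default amplification primers
#'
#' A fixed 19-nt forward and 20-nt reverse primer pair (19 + 191 + 20 =
#' 230 nt). Both are arbitrary GC-balanced sequences free of the demo panel's
#' motifs; real designs should supply their own pair.
#'
#' @return Named character vector with elements `fwd` (19 nt) and `rev`
#'   (20 nt).
#' @export
default_primers <- function() {
  c(fwd = "CGTACTAGCAGTCTGCACT", rev = "TGACTGCGTAGCATCAGGTC")
}

#' Flank a 191-nt insert with primers to form a 230-nt oligo
#'
#' @param insert 191-nt DNA string.
#' @param fwd 19-nt forward primer.
#' @param rev 20-nt reverse primer.
#' @return The 230-nt oligo string `fwd + insert + rev`.
#' @export
flank_primers <- function(insert, fwd, rev) {
  .check_dna(insert, "insert", len = 191L)
  .check_dna(fwd, "fwd", len = 19L)
  .check_dna(rev, "rev", len = 20L)
  paste0(fwd, insert, rev)
}

#' Surrogate nucleosome-formation scorer
#'
#' Scores the 10-bp rotational periodicity of AA/TT/TA dinucleotides -- the
#' classic signal of bendability that favors octamer wrapping -- and maps it
#' to \[0, 1\]. The score is twice the vector strength of dinucleotide
#' positions projected on a 10-bp phase, capped at 1. This is a deliberately
#' simple, self-contained surrogate: it ranks strongly periodic sequences
#' above random ones but is not equivalent to trained genomic
#' nucleosome-occupancy models, and any scorer mapping a sequence to \[0, 1\]
#' can be plugged into [select_itns()] in its place.
#'
#' @param seq DNA string.
#' @return Score in \[0, 1\].
#' @export
periodicity_score <- function(seq) {
  .check_dna(seq, "seq")
  n <- nchar(seq)
  if (n < 12L) return(0)
  di <- substring(seq, 1:(n - 1L), 2:n)
  pos <- which(di %in% c("AA", "TT", "TA"))
  if (length(pos) < 2L) return(0)
  strength <- Mod(sum(exp(2i * pi * pos / 10))) / length(pos)
  min(1, 2 * strength)
}

#' Candidate in vivo-targeted nucleosome (ITN) windows
#'
#' Builds the candidate table from BED-convention regions plus their 191-nt
#' window sequences centered on the called nucleosome center.
#'
#' @param chrom,start,end Region coordinates (0-based half-open, BED
#'   convention).
#' @param window_seq 191-nt window sequences, one per region.
#' @param score Optional precomputed nucleosome-formation probabilities in
#'   \[0, 1\]; when missing, [select_itns()] computes them with its scorer.
#' @return Tibble of candidates.
#' @export
itn_candidates <- function(chrom, start, end, window_seq, score = NA_real_) {
  tibble(chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), window_seq = toupper(window_seq),
         score = as.numeric(score))
}

#' Select ITN candidates for the library
#'
#' A candidate is retained iff its 191-nt window contains at least one motif
#' hit and its nucleosome-formation score is at least `min_score` (candidates
#' scoring strictly below the threshold are removed). The filter is a pure
#' per-candidate predicate: input order never changes the retained set.
#'
#' @param candidates Tibble from [itn_candidates()].
#' @param motifs Motif set used to require an identifiable TFBS.
#' @param scorer Function `seq -> [0, 1]` used for candidates without a
#'   precomputed score (default [periodicity_score()]).
#' @param min_score Retention threshold (default 0.7).
#' @param min_motif_score Passed to [scan_motifs()] for PWM motifs.
#' @return List with `retained` (manifest-style tibble, category `"itn"`,
#'   `tfbs_id`/`tfbs_start`/`tfbs_end` from the best-scoring hit) and `log`
#'   (per-candidate decision with a reason).
#' @export
select_itns <- function(candidates, motifs, scorer = periodicity_score,
                        min_score = 0.7, min_motif_score = NULL) {
  motifs <- .as_motif_list(motifs)
  n <- nrow(candidates)
  rows <- vector("list", n)
  log <- vector("list", n)
  for (i in seq_len(n)) {
    reg <- sprintf("%s:%d-%d", candidates$chrom[i], candidates$start[i],
                   candidates$end[i])
    w <- candidates$window_seq[i]
    if (nchar(w) != 191L || grepl("[^ACGT]", w)) {
      stop("ITN candidate ", reg, ": window_seq must be 191 nt of A/C/G/T.",
           call. = FALSE)
    }
    sc <- candidates$score[i]
    if (is.na(sc)) sc <- scorer(w)
    if (sc < 0 || sc > 1) {
      stop("ITN candidate ", reg, ": score must be in [0, 1].", call. = FALSE)
    }
    hits <- scan_motifs(w, motifs, min_score = min_motif_score)
    keep <- nrow(hits) > 0 && sc >= min_score
    reason <- if (nrow(hits) == 0) {
      "no_tfbs"
    } else if (sc < min_score) {
      "low_formation_score"
    } else {
      "retained"
    }
    log[[i]] <- tibble(region = reg, score = sc, n_hits = nrow(hits),
                       retained = keep, reason = reason)
    if (keep) {
      best <- hits[which.max(hits$score), ]
      rows[[i]] <- tibble(
        id = paste0("ITN_", reg),
        category = "itn",
        nps_id = NA_character_,
        tfbs_id = best$motif_id,
        dyad_offset = NA_integer_,
        tfbs_start = best$start,
        tfbs_end = best$end,
        region = reg,
        score = sc,
        insert_seq = w
      )
    }
  }
  list(retained = dplyr::bind_rows(rows), log = dplyr::bind_rows(log))
}

#' Assemble the library manifest
#'
#' Combines tiled/control/ITN entries, flanks every insert with the primer
#' pair, and validates the result: unique ids, unique oligo sequences, every
#' oligo exactly 230 nt, and at most `capacity` entries.
#'
#' @param entries Tibble (or list of tibbles) of rows from [tile_tfbs()] and
#'   [select_itns()].
#' @param primers Named vector `c(fwd=, rev=)`; default [default_primers()].
#' @param capacity Maximum library size (default 7500).
#' @return A `pioneer_manifest`: the entry tibble with column `oligo_seq`
#'   added and the primer pair stored as an attribute.
#' @export
assemble_library <- function(entries, primers = default_primers(),
                             capacity = 7500L) {
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- dplyr::bind_rows(entries)
  }
  cols <- c("id", "category", "nps_id", "tfbs_id", "dyad_offset",
            "tfbs_start", "tfbs_end", "region", "score", "insert_seq")
  if (nrow(entries) == 0) {
    entries <- tibble(id = character(0), category = character(0),
                      nps_id = character(0), tfbs_id = character(0),
                      dyad_offset = integer(0), tfbs_start = integer(0),
                      tfbs_end = integer(0), region = character(0),
                      score = numeric(0), insert_seq = character(0))
  }
  stopifnot(all(cols %in% names(entries)))
  entries <- entries[cols]
  if (nrow(entries) > capacity) {
    stop("Library exceeds capacity ", capacity, " by ",
         nrow(entries) - capacity, " entr",
         if (nrow(entries) - capacity == 1L) "y" else "ies", ".",
         call. = FALSE)
  }
  dup_id <- entries$id[duplicated(entries$id)]
  if (length(dup_id)) {
    stop("Duplicate entry ids: ", paste(unique(dup_id), collapse = ", "),
         call. = FALSE)
  }
  entries$oligo_seq <- vapply(entries$insert_seq, flank_primers, "",
                              fwd = primers[["fwd"]], rev = primers[["rev"]],
                              USE.NAMES = FALSE)
  dup <- which(duplicated(entries$oligo_seq) |
                 duplicated(entries$oligo_seq, fromLast = TRUE))
  if (length(dup)) {
    pair <- split(entries$id[dup], entries$oligo_seq[dup])[[1]]
    stop("Duplicate oligo sequences, e.g. entries '", pair[1], "' and '",
         pair[2], "'.", call. = FALSE)
  }
  structure(entries, class = c("pioneer_manifest", class(entries)),
            primers = primers, capacity = capacity)
}

#' Manifest file I/O
#'
#' The manifest round-trips losslessly through a tab-separated file whose
#' header lines (`#fwd=`, `#rev=`, `#capacity=`) carry the primer pair and
#' capacity.
#'
#' @param manifest A `pioneer_manifest`.
#' @param path Output path.
#' @return `read_manifest()` returns the `pioneer_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "pioneer_manifest"))
  primers <- attr(manifest, "primers")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#fwd=", primers[["fwd"]]),
               paste0("#rev=", primers[["rev"]]),
               paste0("#capacity=", attr(manifest, "capacity"))), con)
  write.table(as.data.frame(manifest), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    line <- hdr[startsWith(hdr, paste0("#", key, "="))]
    sub(paste0("^#", key, "="), "", line[1])
  }
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  d <- as_tibble(d)
  d$dyad_offset <- as.integer(d$dyad_offset)
  d$tfbs_start <- as.integer(d$tfbs_start)
  d$tfbs_end <- as.integer(d$tfbs_end)
  d$score <- as.numeric(d$score)
  d$region <- as.character(d$region)
  d$nps_id <- as.character(d$nps_id)
  d$category <- as.character(d$category)
  d$tfbs_id <- as.character(d$tfbs_id)
  man <- d
  entries <- man[setdiff(names(man), "oligo_seq")]
  out <- assemble_library(entries,
                          primers = c(fwd = get("fwd"), rev = get("rev")),
                          capacity = as.integer(get("capacity")))
  stopifnot(identical(out$oligo_seq, man$oligo_seq))
  out
}

#' Write the library FASTA (230-nt oligos keyed by manifest id)
#'
#' @param manifest A `pioneer_manifest`.
#' @param path Output FASTA path.
#' @export
write_library_fasta <- function(manifest, path) {
  stopifnot(inherits(manifest, "pioneer_manifest"))
  x <- Biostrings::DNAStringSet(setNames(manifest$oligo_seq, manifest$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read NPS inserts from a FASTA file
#'
#' @param path FASTA of 191-nt inserts.
#' @param dyad_index,core_span Passed to [nps_record()].
#' @return Named list of [nps_record()].
#' @export
read_nps_fasta <- function(path, dyad_index = 96L, core_span = c(23L, 169L)) {
  x <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(x), function(i) {
    nps_record(names(x)[i], as.character(x[[i]]), dyad_index = dyad_index,
               core_span = core_span)
  })
  setNames(out, names(x))
}
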