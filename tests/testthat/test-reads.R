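# Brute-force oracles used below are written independently of the pipeline:
# the trimming oracle enumerates every cut point, the merge oracle slides
# the mates over every offset with raw-byte comparison, and the mapping
# oracle scores every reference by Hamming identity (reads here carry
# substitutions only, so the optimal semi-global alignment is ungapped).

trim_oracle <- function(quals, cutoff) {
  n <- length(quals)
  sums <- vapply(1:n, function(j) sum(quals[j:n] - cutoff), 0)
  j <- which.min(sums)
  if (sums[j] < 0) j - 1L else n
}

merge_oracle <- function(s1, s2raw, min_overlap = 20, max_diffs = 2) {
  s2 <- revcomp(s2raw)
  a <- charToRaw(s1)
  b <- charToRaw(s2)
  n1 <- length(a)
  n2 <- length(b)
  best <- list(score = -Inf, ov = -1L, shift = NA, diffs = NA)
  for (s in (-(n2 - 1)):(n1 - 1)) {
    lo <- max(0L, s)
    hi <- min(n1, s + n2)
    ov <- hi - lo
    if (ov < 1) next
    eq <- sum(a[(lo + 1):hi] == b[(lo - s + 1):(hi - s)])
    score <- 2 * eq - ov
    if (score > best$score ||
        (score == best$score && (ov > best$ov ||
                                 (ov == best$ov && s < best$shift)))) {
      best <- list(score = score, ov = ov, shift = s, diffs = ov - eq)
    }
  }
  list(accept = best$ov >= min_overlap && best$diffs <= max_diffs,
       overlap_len = best$ov, n_diffs = best$diffs)
}

hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(utf8ToInt(a) == utf8ToInt(b))
}

map_oracle <- function(read, manifest, min_cols = 150, min_id = 0.985) {
  ids <- manifest$id
  idents <- vapply(manifest$insert_seq, function(ref) {
    if (nchar(read) != nchar(ref)) return(NA_real_)
    max(hamming_identity(read, ref), hamming_identity(revcomp(read), ref))
  }, 0, USE.NAMES = FALSE)
  if (nchar(read) < min_cols) return(list(mapped = FALSE))
  ok <- which(idents >= min_id)
  if (!length(ok)) return(list(mapped = FALSE))
  best <- max(idents[ok])
  top <- ok[idents[ok] >= best - 1e-12]
  if (length(top) > 1) return(list(mapped = FALSE))
  list(mapped = TRUE, library_id = ids[top])
}

test_that("quality trimming follows the 3' partial-sum rule", {
  # never trims a clean read
  r <- trim_quality(rand_seq(50, seed = 1), rep(40L, 50))
  expect_equal(r$n_trimmed, 0L)
  expect_false(r$empty)

  # a low-quality tail is removed exactly
  quals <- c(rep(40L, 47), 2L, 2L, 2L)
  r2 <- trim_quality(rand_seq(50, seed = 2), quals)
  expect_equal(nchar(r2$seq), 47L)
  expect_equal(r2$n_trimmed, 3L)

  # an all-bad read collapses to empty and is flagged
  r3 <- trim_quality(rand_seq(30, seed = 3), rep(2L, 30))
  expect_true(r3$empty)
  expect_equal(nchar(r3$seq), 0L)

  # never trims 5': bad bases at the start survive
  r4 <- trim_quality(rand_seq(30, seed = 4), c(2L, 2L, rep(40L, 28)))
  expect_equal(r4$n_trimmed, 0L)

  # randomized quality vectors match the enumeration oracle
  set.seed(5)
  for (i in 1:200) {
    q <- sample(0:45, sample(5:60, 1), replace = TRUE)
    got <- trim_quality(rand_seq(length(q)), q)
    expect_equal(nchar(got$seq), trim_oracle(q, 30))
  }

  expect_error(trim_quality("AC", c(70L, 40L)), "Phred")
})

test_that("pair merging honors the overlap and mismatch thresholds", {
  oligo <- rand_seq(230, seed = 10)
  r1 <- list(seq = substr(oligo, 1, 150), quals = rep(38L, 150))
  r2 <- list(seq = revcomp(substr(oligo, 81, 230)), quals = rep(38L, 150))

  m <- merge_pairs(r1, r2)
  expect_true(m$merged)
  expect_equal(m$seq, oligo)
  expect_equal(m$overlap_len, 70L)
  expect_equal(m$n_diffs, 0L)

  # three mismatches in the overlap: rejected; two: accepted
  r2_3 <- r2
  r2_3$seq <- inject_subs_in_range(r2_3$seq, 3, 85, 145)
  expect_false(merge_pairs(r1, r2_3)$merged)
  expect_equal(merge_pairs(r1, r2_3)$reason, "too_many_diffs")
  r2_2 <- r2
  r2_2$seq <- inject_subs_in_range(r2_2$seq, 2, 85, 145)
  m2 <- merge_pairs(r1, r2_2)
  expect_true(m2$merged)
  expect_equal(m2$n_diffs, 2L)

  # overlap boundary: 19 true overlapping bases rejected, 20 accepted.
  # Homopolymer flanks make every off-target offset heavily mismatched, so
  # the best overlap is exactly the constructed one.
  set.seed(11)
  for (true_ov in c(19L, 20L)) {
    o <- paste(sample(c("G", "T"), true_ov, replace = TRUE), collapse = "")
    frag <- paste0(strrep("A", 150L - true_ov), o,
                   strrep("C", 150L - true_ov))
    a <- list(seq = substr(frag, 1, 150), quals = rep(38L, 150))
    b <- list(seq = revcomp(substr(frag, 151L - true_ov, nchar(frag))),
              quals = rep(38L, 150))
    want <- merge_oracle(a$seq, b$seq)
    expect_equal(want$overlap_len, true_ov)   # fixture sanity
    got <- merge_pairs(a, b)
    if (true_ov == 19L) {
      expect_false(got$merged)
      expect_equal(got$reason, "short_overlap")
    } else {
      expect_true(got$merged)
      expect_equal(got$overlap_len, 20L)
      expect_equal(got$seq, frag)
    }
  }

  # consensus takes the higher-quality base, the forward base on ties
  a <- list(seq = "ACGTACGTACGTACGTACGTA", quals = rep(30L, 21))
  b_seq <- a$seq
  substr(b_seq, 5, 5) <- "T"   # disagrees with r1's A
  b <- list(seq = revcomp(b_seq), quals = rep(35L, 21))
  got <- merge_pairs(a, b, min_overlap = 10)
  expect_equal(substr(got$seq, 5, 5), "T")   # r2 wins on quality
  expect_equal(got$quals[5], 35L)
  b$quals <- rep(30L, 21)
  got_tie <- merge_pairs(a, b, min_overlap = 10)
  expect_equal(substr(got_tie$seq, 5, 5), "A")  # tie -> forward base
})

test_that("merging matches the exhaustive-offset oracle on random pairs", {
  set.seed(12)
  for (i in 1:300) {
    total <- sample(170:300, 1)
    frag <- rand_seq(total)
    nerr <- sample(0:4, 1)
    a <- list(seq = substr(frag, 1, 150), quals = rep(38L, 150))
    suffix <- substr(frag, total - 149, total)
    suffix <- inject_subs(suffix, nerr)
    b <- list(seq = revcomp(suffix), quals = rep(38L, 150))
    got <- merge_pairs(a, b)
    want <- merge_oracle(a$seq, b$seq)
    expect_equal(got$merged, want$accept)
    if (got$merged) {
      expect_equal(got$overlap_len, want$overlap_len)
      expect_equal(got$n_diffs, want$n_diffs)
    }
  }
})

test_that("primer trimming is anchored and mismatch-tolerant", {
  p <- default_primers()
  insert <- rand_seq(191, seed = 13)
  oligo <- flank_primers(insert, p[["fwd"]], p[["rev"]])
  merged <- list(seq = oligo, quals = rep(38L, 230))

  t <- trim_primers(merged, p[["fwd"]], p[["rev"]])
  expect_equal(t$seq, insert)
  expect_true(t$fwd_trimmed && t$rev_trimmed)
  expect_length(t$quals, 191L)

  # one substitution in the forward primer still trims (Hamming oracle)
  oligo1 <- oligo
  substr(oligo1, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                                  substr(oligo1, 7, 7))[1]
  expect_equal(sum(utf8ToInt(substr(oligo1, 1, 19)) !=
                     utf8ToInt(p[["fwd"]])), 1L)
  t1 <- trim_primers(list(seq = oligo1, quals = rep(38L, 230)),
                     p[["fwd"]], p[["rev"]])
  expect_equal(t1$seq, insert)

  # three substitutions: no longer recognized
  oligo3 <- oligo
  for (pos in c(3, 7, 11)) {
    substr(oligo3, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                        substr(oligo3, pos, pos))[1]
  }
  t3 <- trim_primers(list(seq = oligo3, quals = rep(38L, 230)),
                     p[["fwd"]], p[["rev"]])
  expect_false(t3$fwd_trimmed)
  expect_true(t3$rev_trimmed)

  # insert-only molecule: untouched, both flags FALSE
  t0 <- trim_primers(list(seq = insert, quals = rep(38L, 191)),
                     p[["fwd"]], p[["rev"]])
  expect_equal(t0$seq, insert)
  expect_false(t0$fwd_trimmed || t0$rev_trimmed)
})

test_that("length filter bounds are inclusive exactly as stated", {
  expect_equal(length_filter(c(173L, 174L, 191L, 220L, 221L)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("mapping applies the identity and length thresholds exactly", {
  man <- simulate_demo_library(seed = 14, n_nps = 1, n_tfbs = 1, n_itn = 0)
  idx <- library_index(man)
  src <- man$insert_seq[40]

  # perfect read
  mp <- map_read(src, idx)
  expect_true(mp$mapped)
  expect_equal(mp$identity, 1)
  expect_equal(mp$aln_cols, 191L)
  expect_equal(mp$library_id, man$id[40])
  expect_equal(c(mp$insert_start, mp$insert_end), c(1L, 191L))

  # 2 substitutions: 189/191 = 0.98953 >= 0.985 -> mapped
  r2 <- inject_subs(src, 2, seed = 15)
  mp2 <- map_read(r2, idx)
  expect_true(mp2$mapped)
  expect_equal(mp2$identity, 189 / 191, tolerance = 1e-12)
  expect_equal(mp2$library_id, man$id[40])

  # 3 substitutions: 188/191 = 0.98429 < 0.985 -> rejected
  r3 <- inject_subs(src, 3, seed = 16)
  mp3 <- map_read(r3, idx)
  expect_false(mp3$mapped)
  expect_equal(mp3$reason, "low_identity")

  # strand symmetry: the reverse complement maps identically
  mp_rc <- map_read(revcomp(r2), idx)
  expect_equal(mp_rc$library_id, mp2$library_id)
  expect_equal(mp_rc$identity, mp2$identity)

  # a short fragment fails the alignment-length threshold
  mp_short <- map_read(substr(src, 1, 149), idx)
  expect_false(mp_short$mapped)
  expect_equal(mp_short$reason, "short_alignment")
  mp_150 <- map_read(substr(src, 1, 150), idx)
  expect_true(mp_150$mapped)
  expect_equal(mp_150$aln_cols, 150L)
  expect_equal(c(mp_150$insert_start, mp_150$insert_end), c(1L, 150L))
})

test_that("equidistant reads are discarded as ambiguous", {
  base <- clean_nps(seed = 17)$insert_seq
  alt <- base
  substr(alt, 91, 91) <- setdiff(c("A", "C", "G", "T"),
                                 substr(alt, 91, 91))[1]
  entries <- tibble::tibble(
    id = c("a", "b"), category = "tiled", nps_id = "n", tfbs_id = "m",
    dyad_offset = c(0L, 1L), tfbs_start = 1L, tfbs_end = 8L,
    region = NA_character_, score = NA_real_,
    insert_seq = c(base, alt))
  man <- assemble_library(entries)
  idx <- library_index(man)
  read <- base
  third <- setdiff(c("A", "C", "G", "T"),
                   c(substr(base, 91, 91), substr(alt, 91, 91)))[1]
  substr(read, 91, 91) <- third        # one mismatch to each reference
  mp <- map_read(read, idx)
  expect_false(mp$mapped)
  expect_equal(mp$reason, "ambiguous")
})

test_that("count tables conserve reads and ignore input order", {
  man <- simulate_demo_library(seed = 18, n_nps = 1, n_tfbs = 1, n_itn = 0)
  asg <- tibble::tibble(
    read_id = sprintf("r%02d", 1:12),
    library_id = c(rep(man$id[1], 10), NA, NA),
    reason = c(rep("mapped", 10), "low_identity", "length"))
  ct <- build_count_table(asg, man, sample = "s1", band = "supershift")
  expect_equal(sum(ct$count), 10L)
  expect_equal(ct$count[ct$library_id == man$id[1]], 10L)
  expect_equal(attr(ct, "total_mapped") + sum(attr(ct, "discards")), 12L)

  shuffled <- asg[sample(nrow(asg)), ]
  ct2 <- build_count_table(shuffled, man, sample = "s1", band = "supershift")
  expect_equal(as_counts(ct2), as_counts(ct))

  bad <- asg
  bad$library_id[1] <- "nonsense"
  expect_error(build_count_table(bad, man), "not in manifest")
})

test_that("mapping decisions equal the exhaustive all-reference oracle", {
  man <- simulate_demo_library(seed = 19, n_nps = 1, n_tfbs = 1, n_itn = 0,
                               offsets = -7:7)
  idx <- library_index(man)
  set.seed(20)
  n_agree_map <- 0L
  for (i in 1:150) {
    src_i <- sample(nrow(man), 1)
    read <- inject_subs(man$insert_seq[src_i], sample(0:5, 1))
    if (runif(1) < 0.5) read <- revcomp(read)
    got <- map_read(read, idx)
    want <- map_oracle(read, man)
    expect_equal(got$mapped, want$mapped)
    if (got$mapped) {
      expect_equal(got$library_id, want$library_id)
      n_agree_map <- n_agree_map + 1L
    }
  }
  expect_gt(n_agree_map, 50L)   # the comparison exercised real mappings

  # cross-check against a classical aligner: near the acceptance threshold
  # the optimal alignment of substitution-only reads is ungapped, so the
  # aligner's identity matches the closed form there, and the resulting
  # mapping decision matches map_read. (Far below the threshold a gapped
  # alignment can score higher; those references never decide a mapping.)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:15) {
    read <- inject_subs(man$insert_seq[sample(nrow(man), 1)], sample(0:4, 1))
    ids_closed <- vapply(man$insert_seq, hamming_identity, 0, a = read,
                         USE.NAMES = FALSE)
    ids_dp <- vapply(seq_len(nrow(man)), function(j) {
      a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(read), Biostrings::DNAString(man$insert_seq[j]),
        type = "global-local", substitutionMatrix = sm,
        gapOpening = 0, gapExtension = 10)
      Biostrings::nmatch(a) / Biostrings::nchar(a)
    }, 0)
    near <- ids_closed >= 0.98
    expect_equal(ids_dp[near], ids_closed[near], tolerance = 1e-12)
    # decision by the aligner's identities, same thresholds and tie rule
    ok <- which(ids_dp >= 0.985)
    dp_decision <- if (length(ok)) {
      top <- ok[ids_dp[ok] >= max(ids_dp[ok]) - 1e-12]
      if (length(top) == 1L) man$id[top] else NA_character_
    } else NA_character_
    got <- map_read(read, idx)
    expect_equal(if (got$mapped) got$library_id else NA_character_,
                 dp_decision)
  }
})

test_that("strand symmetry holds across the band pipeline mapping", {
  man <- simulate_demo_library(seed = 22, n_nps = 1, n_tfbs = 1, n_itn = 0)
  idx <- library_index(man)
  set.seed(23)
  for (i in 1:25) {
    read <- inject_subs(man$insert_seq[sample(nrow(man), 1)], sample(0:2, 1))
    a <- map_read(read, idx)
    b <- map_read(revcomp(read), idx)
    expect_equal(a$mapped, b$mapped)
    if (a$mapped) expect_equal(a$library_id, b$library_id)
  }
})
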