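# Seeded simulator: demo libraries, EMSA band read pools with known
# per-sequence enrichment, and MNase fragment pools with known dyad
# mixtures. Everything is reproducible from (config, seed), and every draw
# flows from the single global generator seeded once per call.

#' Simulation configuration
#'
#' Defaults reflect typical study conditions for this assay: 2e5 reads per
#' gel band, 2x150 paired-end reads, a per-base substitution error rate of
#' 0.002, a nucleosome formation probability of 0.8, and mononucleosomal
#' fragment lengths drawn from a truncated Normal(155 - 1 bp/min of
#' digestion, 10) clipped to \[80, 191\] so the canonical 15-minute
#' timepoint centers on ~140 bp. The error model is substitution-only.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param reads_per_band Reads simulated per gel band.
#' @param error_rate Per-base substitution probability.
#' @param read_length Read length of each mate (paired).
#' @param enrichment Named vector, library id -> fold enrichment e (e = 1 is
#'   the nonspecific baseline); unnamed ids default to 1.
#' @param abundance Named vector, library id -> relative input DNA abundance
#'   (default 1; 0 removes a sequence from every pool).
#' @param formation Named vector, library id -> nucleosome formation
#'   probability in \[0, 1\] (default 0.8).
#' @param dyad_mixture Named list (by NPS id) of data frames with columns
#'   `center`, `sd`, `weight` (weights summing to 1); default a single
#'   population at the dyad (center 96, sd 2).
#' @param frag_len_mean,frag_len_sd,frag_len_bounds Fragment-length model.
#' @param trim_per_min Mean-length shortening per minute of digestion.
#' @param fragments_per_timepoint MNase fragments simulated per timepoint.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, reads_per_band = 2e5,
                              error_rate = 0.002, read_length = 150L,
                              enrichment = NULL, abundance = NULL,
                              formation = NULL, dyad_mixture = NULL,
                              frag_len_mean = 155, frag_len_sd = 10,
                              frag_len_bounds = c(80L, 191L),
                              trim_per_min = 1, fragments_per_timepoint = 1e4) {
  if (!is.null(dyad_mixture)) {
    for (nm in names(dyad_mixture)) {
      w <- dyad_mixture[[nm]]$weight
      if (abs(sum(w) - 1) > 1e-8) {
        stop("dyad_mixture weights for '", nm, "' must sum to 1.",
             call. = FALSE)
      }
    }
  }
  if (!is.null(abundance) && any(abundance < 0)) {
    stop("abundances must be >= 0.", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), reads_per_band = reads_per_band,
                 error_rate = error_rate, read_length = as.integer(read_length),
                 enrichment = enrichment, abundance = abundance,
                 formation = formation, dyad_mixture = dyad_mixture,
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 frag_len_bounds = as.integer(frag_len_bounds),
                 trim_per_min = trim_per_min,
                 fragments_per_timepoint = fragments_per_timepoint),
            class = "sim_config")
}

.expand_param <- function(param, ids, default) {
  out <- rep(default, length(ids))
  names(out) <- ids
  if (!is.null(param)) {
    unknown <- setdiff(names(param), ids)
    if (length(unknown)) {
      stop("Parameter references unknown library ids: ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    out[names(param)] <- param
  }
  out
}

#' Generate a seeded synthetic NPS insert
#'
#' A random 191-nt insert (dyad at 96, core \[23, 169\]) scrubbed of every
#' motif in `motifs`. These are synthetic stand-ins for real positioning
#' sequences -- random backbones with the same geometry, not the published
#' 601/5S/MMTV sequences.
#'
#' @param id Label for the record.
#' @param motifs Motif set to scrub against.
#' @return A scrubbed [nps_record()].
#' @export
synthetic_nps <- function(id, motifs = pioneer_tfbs_panel()) {
  seq <- paste(sample(c("A", "C", "G", "T"), 191L, replace = TRUE),
               collapse = "")
  scrub_nps(nps_record(id, seq), motifs)
}

#' Simulate a demonstration library
#'
#' Builds a small but complete manifest through the design module: `n_nps`
#' synthetic NPS backbones, each tiled with `n_tfbs` binding-site variants at
#' every grid offset, plus `n_itn` ITN-like entries (random 191-nt windows
#' with one embedded motif and an injected formation score in \[0.7, 0.99\],
#' passed through [select_itns()]). Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param n_nps Number of synthetic NPS backbones (<= 3 get the conventional
#'   ids `601syn`, `5Ssyn`, `MMTVsyn`).
#' @param n_tfbs Number of TFBS variants tiled (taken in a fixed
#'   factor-diverse order from `motifs`).
#' @param n_itn Number of ITN entries.
#' @param motifs Motif panel (default [pioneer_tfbs_panel()]).
#' @param offsets Tiling grid (default [default_tiling_grid()]).
#' @param capacity Library capacity (default 7500).
#' @return A `pioneer_manifest`.
#' @examples
#' man <- simulate_demo_library(seed = 1, n_nps = 1, n_tfbs = 2, n_itn = 5)
#' table(man$category)
#' @export
simulate_demo_library <- function(seed = 1L, n_nps = 2L, n_tfbs = 4L,
                                  n_itn = 20L,
                                  motifs = pioneer_tfbs_panel(),
                                  offsets = default_tiling_grid(),
                                  capacity = 7500L) {
  set.seed(seed)
  motifs <- .as_motif_list(motifs)
  nps_ids <- if (n_nps <= 3L) {
    c("601syn", "5Ssyn", "MMTVsyn")[seq_len(n_nps)]
  } else {
    sprintf("nps%02d", seq_len(n_nps))
  }
  preferred <- c("Klf4-1", "SOX2", "OCT4", "MYC", "Oct4-Sox2", "Klf4-1RC",
                 "p53-1", "NS", "Klf4-2", "Klf4-2RC", "p53-1RC", "p53-2")
  order_ids <- c(intersect(preferred, names(motifs)),
                 setdiff(names(motifs), preferred))
  if (n_tfbs > length(order_ids)) {
    stop("n_tfbs exceeds the motif panel size.", call. = FALSE)
  }
  tile_ids <- order_ids[seq_len(n_tfbs)]
  # A backbone can make two tiled entries collide (e.g. when it matches the
  # prefix of a composite site next to a placement of the contained site);
  # redraw such backbones so the generated library is always valid.
  tile_one_nps <- function(nps_id) {
    for (attempt in 1:25) {
      np <- synthetic_nps(nps_id, motifs = motifs)
      tiles <- lapply(tile_ids, function(mid) {
        tile_tfbs(np, motifs[[mid]], offsets)
      })
      tiles <- dplyr::bind_rows(tiles)
      if (!anyDuplicated(tiles$insert_seq)) return(tiles)
    }
    stop("Could not draw a collision-free backbone for ", nps_id,
         call. = FALSE)
  }
  tiled <- lapply(nps_ids, tile_one_nps)
  entries <- dplyr::bind_rows(tiled)
  if (n_itn > 0L) {
    embed_ids <- if (length(tile_ids)) tile_ids else names(motifs)
    windows <- character(n_itn)
    for (i in seq_len(n_itn)) {
      w <- synthetic_nps(sprintf("w%03d", i), motifs)$insert_seq
      m <- motifs[[sample(embed_ids, 1L)]]
      L <- nchar(m$site_seq)
      s <- sample(30:(160 - L), 1L)
      substr(w, s, s + L - 1L) <- m$site_seq
      windows[i] <- w
    }
    cand <- itn_candidates(
      chrom = sprintf("chr%d", sample(1:22, n_itn, replace = TRUE)),
      start = st <- sample(1e6:2e6, n_itn),
      end = st + 191L,
      window_seq = windows,
      score = runif(n_itn, 0.7, 0.99)
    )
    itns <- select_itns(cand, motifs)$retained
    entries <- dplyr::bind_rows(entries, itns)
  }
  assemble_library(entries, capacity = capacity)
}

.band_probs <- function(manifest, config) {
  ids <- manifest$id
  a <- .expand_param(config$abundance, ids, 1)
  f <- .expand_param(config$formation, ids, 0.8)
  e <- .expand_param(config$enrichment, ids, 1)
  if (any(e < 0)) stop("enrichment must be >= 0.", call. = FALSE)
  norm <- function(x) {
    if (sum(x) <= 0) stop("All band weights are zero.", call. = FALSE)
    x / sum(x)
  }
  list(input = norm(a),
       naked_dna = norm(a * (1 - f)),
       nucleosome_null = norm(a * f),
       supershift = norm(a * f * e),
       enrichment = e)
}

#' Simulate per-band library counts (no reads)
#'
#' Draws the four gel bands as multinomials over the manifest: input DNA
#' proportional to abundance, the naked-DNA band to `abundance * (1 -
#' formation)`, the TF-null nucleosome band to `abundance * formation`, and
#' the supershift band to `abundance * formation * enrichment`. This is the
#' count-level counterpart of [simulate_emsa()] for statistic-level studies
#' where read simulation is unnecessary.
#'
#' @param manifest A `pioneer_manifest`.
#' @param config A [simulation_config()].
#' @return List: `counts` (named list of named count vectors per band) and
#'   `truth` (expected counts per band and per-id true log2 enrichment).
#' @export
simulate_band_counts <- function(manifest, config = simulation_config()) {
  set.seed(config$seed)
  probs <- .band_probs(manifest, config)
  bands <- c("input", "naked_dna", "nucleosome_null", "supershift")
  counts <- lapply(bands, function(b) {
    setNames(as.numeric(rmultinom(1L, config$reads_per_band, probs[[b]])),
             manifest$id)
  })
  names(counts) <- bands
  expected <- lapply(bands, function(b) {
    setNames(config$reads_per_band * probs[[b]], manifest$id)
  })
  names(expected) <- bands
  list(counts = counts,
       truth = list(expected = expected,
                    log2_enrichment = log2(probs$enrichment),
                    seed = config$seed))
}

# Substitution-only error model. Returns mutated sequences plus the error
# positions so quality strings can mark them: sequencing errors occur at
# low-confidence base calls, so error-injected positions carry the
# rate-derived Phred score and every other base q40. (A constant low
# quality across whole reads would make the q30 trimming stage delete
# error-free reads wholesale, which no real base caller produces.)
.mutate_seqs <- function(seqs, rate) {
  pos_list <- vector("list", length(seqs))
  if (rate <= 0 || !length(seqs)) {
    return(list(seqs = seqs, pos = pos_list))
  }
  bases <- c("A", "C", "G", "T")
  nmut <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nmut > 0L)) {
    pos <- sort(sample.int(nchar(seqs[i]), nmut[i]))
    s <- seqs[i]
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(bases[bases != cur], 1L)
    }
    seqs[i] <- s
    pos_list[[i]] <- pos
  }
  list(seqs = seqs, pos = pos_list)
}

.phred_for_rate <- function(rate) {
  if (rate <= 0) return(40L)
  max(2L, min(40L, as.integer(round(-10 * log10(rate)))))
}

.write_pair_fastq <- function(ids, seqs, err_pos, read_length, q_err,
                              prefix) {
  n <- length(seqs)
  len <- nchar(seqs)
  rl <- pmin(read_length, len)
  r1 <- substr(seqs, 1L, rl)
  r2 <- revcomp(substr(seqs, len - rl + 1L, len))
  q1 <- vector("list", n)
  q2 <- vector("list", n)
  for (i in seq_len(n)) {
    qfull <- rep(40L, len[i])
    qfull[err_pos[[i]]] <- q_err
    q1[[i]] <- qfull[seq_len(rl[i])]
    q2[[i]] <- rev(qfull[(len[i] - rl[i] + 1L):len[i]])
  }
  write_fastq(ids, r1, q1, paste0(prefix, "_R1.fastq"))
  write_fastq(ids, r2, q2, paste0(prefix, "_R2.fastq"))
  c(fastq1 = paste0(prefix, "_R1.fastq"), fastq2 = paste0(prefix, "_R2.fastq"))
}

#' Simulate an EMSA experiment as paired FASTQ band pools
#'
#' Draws band counts as in [simulate_band_counts()], then writes each band's
#' molecules as paired 150-nt reads: the forward mate is the oligo's prefix
#' and the reverse mate the reverse complement of its suffix, so a 230-nt
#' oligo yields a 70-nt true overlap. Substitution errors are applied at
#' `error_rate` and the constant quality string matches that rate.
#'
#' @param manifest A `pioneer_manifest`.
#' @param config A [simulation_config()].
#' @param out_dir Output directory for FASTQ files and the samplesheet.
#' @param sample Sample label used in file names and the samplesheet.
#' @return List: `samplesheet` (tibble: sample, band, fastq1, fastq2),
#'   `truth` (drawn per-band counts, expected counts, true log2 enrichment,
#'   seed).
#' @export
simulate_emsa <- function(manifest, config = simulation_config(),
                          out_dir = tempfile("emsa"), sample = "sim") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_band_counts(manifest, config)
  oligo <- setNames(manifest$oligo_seq, manifest$id)
  q <- .phred_for_rate(config$error_rate)
  rows <- list()
  for (band in names(sim$counts)) {
    cnt <- sim$counts[[band]]
    src <- rep(names(cnt), cnt)
    mut <- .mutate_seqs(unname(oligo[src]), config$error_rate)
    ids <- sprintf("%s_%s_%06d", sample, band, seq_along(src))
    files <- .write_pair_fastq(ids, mut$seqs, mut$pos, config$read_length, q,
                               file.path(out_dir, paste0(sample, "_", band)))
    rows[[band]] <- tibble(sample = sample, band = band,
                           fastq1 = files[["fastq1"]],
                           fastq2 = files[["fastq2"]])
  }
  list(samplesheet = dplyr::bind_rows(rows),
       truth = list(band_counts = sim$counts,
                    expected = sim$truth$expected,
                    log2_enrichment = sim$truth$log2_enrichment,
                    seed = config$seed))
}

#' Simulate MNase digestion fragments over the library
#'
#' Per timepoint, fragments are assigned to library sequences proportionally
#' to `abundance * formation`; each fragment's center is drawn from its NPS's
#' dyad mixture (ITN entries use the default single-population mixture) and
#' its length from the truncated-Normal length model whose mean shortens by
#' `trim_per_min` per minute of digestion. Spans are clipped to the 191-nt
#' insert.
#'
#' @param manifest A `pioneer_manifest`.
#' @param config A [simulation_config()].
#' @param timepoints Digestion times in minutes (default 15).
#' @param out_dir If non-NULL, paired FASTQ pools per timepoint are also
#'   written (reads taken from the fragment subsequence).
#' @return List: `fragments` (tibble: library_id, insert_start, insert_end,
#'   length, timepoint, component), `truth` (mixture definitions, seed), and
#'   `samplesheet` when FASTQ was written.
#' @export
simulate_mnase <- function(manifest, config = simulation_config(),
                           timepoints = 15, out_dir = NULL) {
  set.seed(config$seed)
  ids <- manifest$id
  a <- .expand_param(config$abundance, ids, 1)
  f <- .expand_param(config$formation, ids, 0.8)
  w <- a * f
  if (sum(w) <= 0) stop("All fragment weights are zero.", call. = FALSE)
  default_mix <- data.frame(center = 96, sd = 2, weight = 1)
  mix_for <- function(nps_id) {
    if (!is.na(nps_id) && !is.null(config$dyad_mixture[[nps_id]])) {
      config$dyad_mixture[[nps_id]]
    } else {
      default_mix
    }
  }
  nps_of <- setNames(manifest$nps_id, manifest$id)
  out <- list()
  rows <- list()
  for (tp in timepoints) {
    n <- config$fragments_per_timepoint
    lib <- sample(ids, n, replace = TRUE, prob = w / sum(w))
    center <- integer(n)
    comp <- integer(n)
    for (u in unique(nps_of[lib])) {
      sel <- which(is.na(nps_of[lib]) == is.na(u) &
                     (is.na(u) | nps_of[lib] == u))
      mix <- mix_for(u)
      k <- sample.int(nrow(mix), length(sel), replace = TRUE,
                      prob = mix$weight)
      center[sel] <- as.integer(round(rnorm(length(sel), mix$center[k],
                                            mix$sd[k])))
      comp[sel] <- k
    }
    mean_t <- config$frag_len_mean - config$trim_per_min * tp
    len <- as.integer(round(rnorm(n, mean_t, config$frag_len_sd)))
    len <- pmin(pmax(len, config$frag_len_bounds[1]),
                config$frag_len_bounds[2])
    start <- center - (len - 1L) %/% 2L
    end <- start + len - 1L
    start <- pmax(start, 1L)
    end <- pmin(end, 191L)
    bad <- start > end
    start[bad] <- pmax(1L, pmin(191L, center[bad]))
    end[bad] <- start[bad]
    frag <- tibble(library_id = lib, insert_start = start, insert_end = end,
                   length = end - start + 1L, timepoint = tp,
                   component = comp)
    out[[as.character(tp)]] <- frag
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      insert <- setNames(manifest$insert_seq, manifest$id)
      mut <- .mutate_seqs(unname(substr(insert[lib], start, end)),
                          config$error_rate)
      idsr <- sprintf("mnase_t%s_%06d", tp, seq_len(n))
      files <- .write_pair_fastq(idsr, mut$seqs, mut$pos,
                                 config$read_length,
                                 .phred_for_rate(config$error_rate),
                                 file.path(out_dir, paste0("mnase_t", tp)))
      rows[[as.character(tp)]] <- tibble(sample = "mnase",
                                         band = paste0("mnase_t", tp),
                                         fastq1 = files[["fastq1"]],
                                         fastq2 = files[["fastq2"]])
    }
  }
  res <- list(fragments = dplyr::bind_rows(out),
              truth = list(dyad_mixture = config$dyad_mixture %||%
                             list(default = default_mix),
                           seed = config$seed))
  if (!is.null(out_dir)) res$samplesheet <- dplyr::bind_rows(rows)
  res
}
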