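# MNase-seq analytics on the designed library coordinate system (1..191):
# per-base protection, size-filtered fragment-center histograms, population
# summaries, protection centers, and nucleosome formation efficiency.

.check_fragments <- function(fragments, insert_len = 191L) {
  stopifnot(all(c("library_id", "insert_start", "insert_end") %in%
                  names(fragments)))
  s <- fragments$insert_start
  e <- fragments$insert_end
  if (any(s < 1L | e > insert_len | s > e)) {
    stop("Fragment spans must satisfy 1 <= start <= end <= ", insert_len,
         ".", call. = FALSE)
  }
  invisible(fragments)
}

#' Per-base MNase protection
#'
#' Protection at base i of a library sequence is the number of fragments
#' covering i (inclusive spans) divided by the total number of fragments
#' mapped to that sequence; bases never covered are 0.
#'
#' @param fragments Tibble with `library_id`, `insert_start`, `insert_end`
#'   and optionally `timepoint`.
#' @param insert_len Insert length (default 191).
#' @return Long tibble: `library_id` (and `timepoint` if present), `pos`
#'   (1..insert_len), `protection` in \[0, 1\], plus `n_fragments` per group.
#' @export
protection_matrix <- function(fragments, insert_len = 191L) {
  .check_fragments(fragments, insert_len)
  keys <- c("library_id", intersect("timepoint", names(fragments)))
  groups <- split(fragments, fragments[keys], drop = TRUE)
  out <- lapply(groups, function(g) {
    delta <- numeric(insert_len + 1L)
    for (i in seq_len(nrow(g))) {
      delta[g$insert_start[i]] <- delta[g$insert_start[i]] + 1
      delta[g$insert_end[i] + 1L] <- delta[g$insert_end[i] + 1L] - 1
    }
    cover <- cumsum(delta[seq_len(insert_len)])
    base <- tibble(pos = seq_len(insert_len),
                   protection = cover / nrow(g),
                   n_fragments = nrow(g))
    for (k in rev(keys)) base <- dplyr::bind_cols(setNames(
      tibble(rep(g[[k]][1], insert_len)), k), base)
    base
  })
  dplyr::bind_rows(out)
}

#' Size-filtered fragment-center histogram
#'
#' Fragments are filtered to the mononucleosome size range (inclusive
#' bounds), then binned by center position, with the center of an
#' even-length fragment taken as the left-of-center base
#' (`floor((start + end) / 2)`).
#'
#' @param fragments Tibble with `library_id`, `insert_start`, `insert_end`.
#' @param min_len,max_len Inclusive size bounds (defaults 107 and 150).
#' @return Tibble `library_id`, `center`, `n` with attributes `n_pass` and
#'   `n_fail` (`n_pass + n_fail` equals the number of input fragments).
#' @export
center_histogram <- function(fragments, min_len = 107L, max_len = 150L) {
  .check_fragments(fragments)
  len <- fragments$insert_end - fragments$insert_start + 1L
  pass <- len >= min_len & len <= max_len
  kept <- fragments[pass, ]
  hist <- tibble(
    library_id = kept$library_id,
    center = (kept$insert_start + kept$insert_end) %/% 2L
  ) |>
    dplyr::count(.data$library_id, .data$center, name = "n") |>
    arrange(.data$library_id, .data$center)
  structure(hist, n_pass = sum(pass), n_fail = sum(!pass))
}

.smooth_ma <- function(x, k = 3L) {
  if (k <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

#' Summarise a fragment-center histogram around a reference center
#'
#' Reports the fraction of histogram mass within `ref_center +/- tol`, and
#' the modes (local maxima after 3-bp moving-average smoothing) that
#' describe multi-population positioning.
#'
#' @param hist A center histogram (tibble with `center`, `n`; extra grouping
#'   columns are ignored, i.e. the mass is pooled).
#' @param ref_center Reference center position (bp).
#' @param tol Window half-width in bp (default 10).
#' @param smooth_bp Moving-average width for mode calling (default 3).
#' @return List: `fraction`, `n_within`, `total`, `modes` (center positions
#'   of local maxima, increasing).
#' @export
population_summary <- function(hist, ref_center, tol = 10L, smooth_bp = 3L) {
  stopifnot(all(c("center", "n") %in% names(hist)))
  if (nrow(hist) == 0 || sum(hist$n) == 0) {
    stop("Empty center histogram: no fragment mass to summarise.",
         call. = FALSE)
  }
  counts <- tapply(hist$n, hist$center, sum)
  centers <- as.integer(names(counts))
  total <- sum(counts)
  within <- centers >= ref_center - tol & centers <= ref_center + tol
  # zero-pad so edge positions are smoothed (and mode-eligible) like any
  # interior position
  pad <- smooth_bp
  grid <- seq(min(centers) - pad, max(centers) + pad)
  full <- numeric(length(grid))
  full[match(centers, grid)] <- counts
  sm <- .smooth_ma(full, smooth_bp)
  sm[is.na(sm)] <- 0
  # local-maximum plateaus of the smoothed series; within each plateau the
  # mode is the position with the largest raw count (leftmost on ties)
  left <- c(0, sm[-length(sm)])
  right <- c(sm[-1], 0)
  peak <- sm > 0 & sm >= left & sm >= right
  runs <- rle(peak)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  modes <- integer(0)
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    modes <- c(modes, grid[idx[which.max(full[idx])]])
  }
  list(fraction = sum(counts[within]) / total,
       n_within = as.integer(sum(counts[within])),
       total = as.integer(total),
       modes = modes)
}

#' Center of MNase protection
#'
#' Default: the protection-weighted centroid, `round(sum(i * p_i) /
#' sum(p_i))` with half-up rounding. Alternative `"mode"`: the position of
#' maximal protection after 3-bp smoothing (leftmost on ties).
#'
#' @param protection Long tibble from [protection_matrix()] (columns
#'   `library_id`, `pos`, `protection`).
#' @param method `"centroid"` (default) or `"mode"`.
#' @return Tibble: `library_id`, `center`.
#' @export
protection_center <- function(protection, method = c("centroid", "mode")) {
  method <- match.arg(method)
  protection |>
    group_by(.data$library_id) |>
    summarise(center = {
      p <- .data$protection
      pos <- .data$pos
      if (sum(p) == 0) {
        NA_integer_
      } else if (method == "centroid") {
        as.integer(round_half_up(sum(pos * p) / sum(p)))
      } else {
        sm <- .smooth_ma(p, 3L)
        sm[is.na(sm)] <- 0
        as.integer(pos[which.max(sm)])
      }
    }, .groups = "drop")
}

#' Nucleosome formation efficiency
#'
#' Per-sequence log2 ratio of nucleosome-band to naked-DNA-band reads,
#' median-centered across the library so that the typical sequence scores 0.
#' Sequences in the lowest `flag_percentile` of centered efficiency are
#' flagged as poorly forming (candidates for the supershift gap logic).
#'
#' @param nucleosome,naked Counts for the nucleosome and naked-DNA bands
#'   (`band_counts` or named numeric vectors over the same ids).
#' @param pseudocount Added to every count (default 0.5).
#' @param flag_percentile Fraction flagged at the bottom (default 0.05).
#' @return Tibble: `library_id`, `efficiency` (median-centered log2),
#'   `flagged`.
#' @export
formation_efficiency <- function(nucleosome, naked, pseudocount = 0.5,
                                 flag_percentile = 0.05) {
  nuc <- as_counts(nucleosome)
  nkd <- as_counts(naked)
  if (!setequal(names(nuc), names(nkd))) {
    stop("nucleosome and naked bands must cover the same library ids.",
         call. = FALSE)
  }
  nkd <- nkd[names(nuc)]
  e <- log2((nuc + pseudocount) / (nkd + pseudocount))
  centered <- e - median(e)
  cutoff <- stats::quantile(centered, flag_percentile, names = FALSE)
  tibble(library_id = names(nuc), efficiency = unname(centered),
         flagged = unname(centered < cutoff))
}
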