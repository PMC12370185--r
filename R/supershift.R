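# Relative supershift quantification: nonspecific control selection, the
# per-sequence log2 statistic, replicate profiles, concentration selection,
# and the ITN-level analyses (distance to MNase-protection center,
# near-center bound fraction).

.tfbs_center_pos <- function(tfbs_start, tfbs_end) {
  len <- tfbs_end - tfbs_start + 1L
  tfbs_start + motif_center_index(len) - 1L
}

.is_linker <- function(tfbs_start, tfbs_end, core_span = c(23L, 169L)) {
  ctr <- .tfbs_center_pos(tfbs_start, tfbs_end)
  ctr < core_span[1] | ctr > core_span[2]
}

#' Select nonspecific control sequences for a focal TF
#'
#' Controls are tiled/control entries on the same nucleosome positioning
#' sequence whose TFBS is assigned to factors other than the focal TF
#' (reverse-complement variants of focal sites are excluded too, via
#' [focal_motif_ids()]). Optionally, candidate motifs whose linker-position
#' variants show supershift above a bootstrap null in a screening run are
#' excluded as cross-bound and logged.
#'
#' @param manifest A `pioneer_manifest`.
#' @param motifs Motif set carrying TF assignments.
#' @param tf Focal transcription factor.
#' @param nps_id NPS backbone to draw controls from.
#' @param linker_values Optional screening run: tibble with `library_id`,
#'   `value` (relative supershift of the focal TF) covering linker-position
#'   sequences; motifs showing cross-binding are excluded.
#' @param screen_quantile Bootstrap-null quantile above which a candidate
#'   motif's mean linker supershift triggers exclusion (default 0.95).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param min_controls Minimum control set size (default 25); fewer is an
#'   error.
#' @param core_span Core bounds defining "linker" (default `c(23, 169)`).
#' @return List of class `control_set`: `tf`, `nps_id`, `control_ids`,
#'   `excluded_motifs` (tibble with exclusion evidence).
#' @export
select_controls <- function(manifest, motifs, tf, nps_id,
                            linker_values = NULL, screen_quantile = 0.95,
                            n_boot = 1000L, min_controls = 25L,
                            core_span = c(23L, 169L)) {
  stopifnot(inherits(manifest, "pioneer_manifest"))
  motifs <- .as_motif_list(motifs)
  focal <- focal_motif_ids(motifs, tf)
  cand <- manifest[manifest$category %in% c("tiled", "control") &
                     manifest$nps_id %in% nps_id &
                     !(manifest$tfbs_id %in% focal), , drop = FALSE]
  excluded <- tibble(tfbs_id = character(0), mean_linker = numeric(0),
                     null_cutoff = numeric(0))
  if (!is.null(linker_values) && nrow(cand) > 0) {
    linker <- cand[.is_linker(cand$tfbs_start, cand$tfbs_end, core_span), ]
    lv <- linker_values[linker_values$library_id %in% linker$id, ]
    lv <- dplyr::left_join(lv, linker[, c("id", "tfbs_id")],
                           by = c(library_id = "id"))
    lv <- lv[is.finite(lv$value), ]
    if (nrow(lv) > 0) {
      per_motif <- split(lv$value, lv$tfbs_id)
      pooled <- lv$value
      for (mid in names(per_motif)) {
        obs <- mean(per_motif[[mid]])
        k <- length(per_motif[[mid]])
        boots <- vapply(seq_len(n_boot), function(b) {
          mean(sample(pooled, k, replace = TRUE))
        }, 0)
        cutoff <- stats::quantile(boots, screen_quantile, names = FALSE)
        if (obs > cutoff) {
          excluded <- dplyr::bind_rows(
            excluded, tibble(tfbs_id = mid, mean_linker = obs,
                             null_cutoff = cutoff))
          cand <- cand[cand$tfbs_id != mid, , drop = FALSE]
        }
      }
    }
  }
  if (nrow(cand) < min_controls) {
    stop("Only ", nrow(cand), " control sequences remain for TF '", tf,
         "' on NPS '", paste(nps_id, collapse = ","), "' (minimum ",
         min_controls, "); review the motif panel, manifest, or screening ",
         "threshold.", call. = FALSE)
  }
  structure(list(tf = tf, nps_id = nps_id, control_ids = cand$id,
                 excluded_motifs = excluded),
            class = "control_set")
}

#' Relative supershift per library sequence
#'
#' For every sequence N, with pseudocount c and control (nonspecific) set NS:
#' \deqn{log2( ((SS_N + c) / mean_{NS}(SS + c)) /
#'             ((Null_N + c) / mean_{NS}(Null + c)) )}
#' where SS is the supershift band and Null the nucleosome band of the
#' TF-null lane of the same gel. Sequences whose raw TF-null count falls
#' below `input_floor` reads formed nucleosomes too inefficiently to
#' quantify; their value is withheld (`status = "missing_low_input"`).
#'
#' @param ss,null Counts for the supershift and TF-null nucleosome bands: a
#'   `band_counts` table or named numeric vector over the same ids.
#' @param controls A `control_set` (or character vector of control ids).
#' @param pseudocount Added to every count (default 0.5).
#' @param input_floor Minimum raw TF-null count (default 10).
#' @return Tibble: `library_id`, `value` (log2 units; `NA` when withheld),
#'   `status` (`"ok"`/`"missing_low_input"`).
#' @examples
#' ids <- paste0("s", 1:4)
#' ss <- setNames(c(400, 100, 100, 100), ids)
#' null <- setNames(c(50, 50, 50, 50), ids)
#' relative_supershift(ss, null, controls = ids[2:4])
#' @export
relative_supershift <- function(ss, null, controls, pseudocount = 0.5,
                                input_floor = 10L) {
  ss <- as_counts(ss)
  null <- as_counts(null)
  if (!setequal(names(ss), names(null))) {
    stop("supershift and TF-null bands must cover the same library ids.",
         call. = FALSE)
  }
  null <- null[names(ss)]
  if (sum(ss) == 0 || sum(null) == 0) {
    stop("A band with zero total reads cannot be normalized.", call. = FALSE)
  }
  ctrl <- if (inherits(controls, "control_set")) controls$control_ids else
    as.character(controls)
  missing_ctrl <- setdiff(ctrl, names(ss))
  if (length(missing_ctrl)) {
    stop("Control ids absent from the count tables: ",
         paste(head(missing_ctrl, 5), collapse = ", "), call. = FALSE)
  }
  if (!length(ctrl)) stop("Control set is empty.", call. = FALSE)
  c0 <- pseudocount
  mean_ss_ns <- mean(ss[ctrl] + c0)
  mean_null_ns <- mean(null[ctrl] + c0)
  value <- log2(((ss + c0) / mean_ss_ns) / ((null + c0) / mean_null_ns))
  status <- ifelse(null < input_floor, "missing_low_input", "ok")
  tibble(library_id = names(ss),
         value = unname(ifelse(status == "ok", value, NA_real_)),
         status = unname(status))
}

#' Aggregate replicate supershift values into a position profile
#'
#' Groups values by (TFBS, NPS, dyad offset) and reports the replicate mean
#' and SEM (sd / sqrt(n); reported only for n >= 2). Offsets where every
#' replicate was withheld yield a gap (`mean = NA`, `n = 0`) -- the breaks in
#' a plotted trace where nucleosomes formed too inefficiently.
#'
#' @param values Tibble with `library_id`, `replicate`, `value`, `status`
#'   (rows from [relative_supershift()], one set per replicate).
#' @param manifest A `pioneer_manifest`.
#' @return Tibble: `tfbs_id`, `nps_id`, `dyad_offset`, `mean`, `sem`, `n`.
#' @export
build_profile <- function(values, manifest) {
  stopifnot(all(c("library_id", "replicate", "value", "status") %in%
                  names(values)))
  meta <- manifest[manifest$category %in% c("tiled", "control"),
                   c("id", "tfbs_id", "nps_id", "dyad_offset")]
  joined <- dplyr::inner_join(values, meta, by = c(library_id = "id"))
  joined |>
    group_by(.data$tfbs_id, .data$nps_id, .data$dyad_offset) |>
    summarise(
      mean = if (any(.data$status == "ok"))
        mean(.data$value[.data$status == "ok"]) else NA_real_,
      sem = if (sum(.data$status == "ok") >= 2L)
        sd(.data$value[.data$status == "ok"]) /
          sqrt(sum(.data$status == "ok")) else NA_real_,
      n = sum(.data$status == "ok"),
      .groups = "drop"
    ) |>
    arrange(.data$tfbs_id, .data$nps_id, .data$dyad_offset)
}

#' Choose the working TF concentration from a titration
#'
#' For each concentration, scores the separation between specific and
#' nonspecific binding at linker positions (where binding is most likely):
#' mean supershift of linker-position focal-TFBS sequences minus the mean of
#' linker-position nonspecific sequences, standardized by the pooled SEM.
#' Returns the concentration with the largest score; exact ties resolve to
#' the lowest concentration.
#'
#' @param values Tibble with `library_id`, `concentration`, `replicate`,
#'   `value`, `status`.
#' @param manifest A `pioneer_manifest`.
#' @param motifs Motif set carrying TF assignments.
#' @param tf Focal transcription factor.
#' @param core_span Core bounds defining "linker" (default `c(23, 169)`).
#' @return List: `concentration` (chosen) and `table` (per-concentration
#'   scores).
#' @export
select_concentration <- function(values, manifest, motifs, tf,
                                 core_span = c(23L, 169L)) {
  motifs <- .as_motif_list(motifs)
  focal <- focal_motif_ids(motifs, tf)
  meta <- manifest[manifest$category %in% c("tiled", "control"), ]
  meta <- meta[.is_linker(meta$tfbs_start, meta$tfbs_end, core_span), ]
  meta$specific <- meta$tfbs_id %in% focal
  v <- dplyr::inner_join(values, meta[, c("id", "specific")],
                         by = c(library_id = "id"))
  v <- v[v$status == "ok", ]
  if (nrow(v) == 0) stop("No usable linker-position values.", call. = FALSE)
  tab <- v |>
    group_by(.data$concentration) |>
    summarise(
      mean_specific = mean(.data$value[.data$specific]),
      mean_nonspecific = mean(.data$value[!.data$specific]),
      sem_specific = sd(.data$value[.data$specific]) /
        sqrt(sum(.data$specific)),
      sem_nonspecific = sd(.data$value[!.data$specific]) /
        sqrt(sum(!.data$specific)),
      .groups = "drop"
    ) |>
    mutate(
      pooled_sem = sqrt(.data$sem_specific^2 + .data$sem_nonspecific^2),
      score = (.data$mean_specific - .data$mean_nonspecific) /
        pmax(.data$pooled_sem, 1e-9)
    ) |>
    arrange(.data$concentration)
  best <- which.max(tab$score)   # first max -> lowest concentration on ties
  list(concentration = tab$concentration[best], table = tab)
}

#' Replicate-averaged supershift per in vivo-targeted nucleosome
#'
#' One value per ITN: the mean over replicates with usable data, flagged
#' bound when the mean reaches `bound_threshold`. ITNs with no usable
#' replicate (failed nucleosome formation) get `status = "missing"` and no
#' flag.
#'
#' @param values Tibble with `library_id`, `replicate`, `value`, `status`.
#' @param manifest A `pioneer_manifest`.
#' @param bound_threshold Log2 units for the bound call (default 1.0).
#' @return Tibble: `library_id`, `mean_supershift`, `n`, `bound`, `status`,
#'   `replicate_disagreement` (replicates straddle the threshold).
#' @export
itn_supershift <- function(values, manifest, bound_threshold = 1.0) {
  itn_ids <- manifest$id[manifest$category == "itn"]
  v <- values[values$library_id %in% itn_ids, ]
  v |>
    group_by(.data$library_id) |>
    summarise(
      mean_supershift = if (any(.data$status == "ok"))
        mean(.data$value[.data$status == "ok"]) else NA_real_,
      n = sum(.data$status == "ok"),
      .groups = "drop"
    ) |>
    mutate(
      status = ifelse(.data$n > 0, "ok", "missing"),
      bound = ifelse(.data$status == "ok",
                     .data$mean_supershift >= bound_threshold, NA)
    ) -> out
  disagree <- v |>
    group_by(.data$library_id) |>
    summarise(replicate_disagreement =
                sum(.data$status == "ok") >= 2L &&
                any(.data$value[.data$status == "ok"] >= bound_threshold) &&
                any(.data$value[.data$status == "ok"] < bound_threshold),
              .groups = "drop")
  dplyr::left_join(out, disagree, by = "library_id")
}

#' ITN binding versus distance from the MNase-protection center
#'
#' Computes, per TF, (i) the Spearman correlation between the ITN supershift
#' and the distance of its TFBS center from the MNase-protection center, and
#' (ii) among ITNs whose TFBS lies within `window` bp of the protection
#' center, the fraction called bound. With zero near-center ITNs the fraction
#' is undefined and reported as `NA` with `n = 0`, never as 0%.
#'
#' @param itn_results Tibble from [itn_supershift()], optionally with a `tf`
#'   column (otherwise a single pooled group is analysed).
#' @param centers Tibble with `library_id`, `center` (from
#'   [protection_center()]).
#' @param manifest A `pioneer_manifest` (for TFBS positions).
#' @param window Near-center distance in bp (default 40).
#' @return List: `distances` (per-ITN joined table), `correlation` (tibble
#'   with `tf`, `n`, `rho`, `p_value`), `near_center` (tibble with `tf`,
#'   `n`, `n_bound`, `fraction`, `percent`).
#' @export
distance_analysis <- function(itn_results, centers, manifest, window = 40L) {
  if (!"tf" %in% names(itn_results)) itn_results$tf <- "all"
  meta <- manifest[manifest$category == "itn",
                   c("id", "tfbs_start", "tfbs_end")]
  d <- itn_results |>
    dplyr::inner_join(meta, by = c(library_id = "id")) |>
    dplyr::inner_join(centers, by = "library_id") |>
    mutate(distance = abs(.tfbs_center_pos(.data$tfbs_start, .data$tfbs_end) -
                            .data$center))
  ok <- d[d$status == "ok", ]
  correlation <- ok |>
    group_by(.data$tf) |>
    summarise(n = dplyr::n(),
              rho = if (dplyr::n() >= 3)
                suppressWarnings(cor.test(.data$mean_supershift,
                                          .data$distance,
                                          method = "spearman"))$estimate
              else NA_real_,
              p_value = if (dplyr::n() >= 3)
                suppressWarnings(cor.test(.data$mean_supershift,
                                          .data$distance,
                                          method = "spearman"))$p.value
              else NA_real_,
              .groups = "drop")
  near <- ok |>
    filter(.data$distance <= window) |>
    group_by(.data$tf) |>
    summarise(n = dplyr::n(), n_bound = sum(.data$bound), .groups = "drop")
  near <- dplyr::left_join(tibble(tf = unique(ok$tf)), near, by = "tf")
  near$n[is.na(near$n)] <- 0L
  near$n_bound[is.na(near$n_bound) & near$n == 0L] <- 0L
  near$fraction <- ifelse(near$n > 0, near$n_bound / near$n, NA_real_)
  near$percent <- 100 * near$fraction
  list(distances = d, correlation = correlation, near_center = near)
}
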