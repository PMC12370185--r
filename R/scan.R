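#' Scan a sequence for TFBS occurrences on both strands
#'
#' Consensus motifs (no PWM) are matched exactly, including overlapping
#' occurrences, on the forward and reverse strand; their reported score is
#' `2 * motif length`, the log2-odds of a perfect match against a flat
#' 0.25-per-base background. PWM motifs are scored at every position as the
#' sum of per-position log2-odds and reported when the score reaches
#' `min_score`.
#'
#' @param seq DNA string (A/C/G/T only; ambiguity codes are rejected).
#' @param motifs A [tfbs_motif()] or list of them.
#' @param min_score Log2-odds threshold for PWM motifs. Default: 80% of each
#'   PWM's maximum attainable score. Ignored for consensus motifs.
#' @return Tibble with columns `motif_id`, `start`, `end` (1-based inclusive,
#'   forward-strand coordinates), `strand` (`"+"`/`"-"`), `score`, sorted by
#'   `start`, then motif id, then strand. Zero rows when nothing matches.
#' @examples
#' scan_motifs("TTCCCCACCCTT", tfbs_motif("Klf4-1", "CCCCACCC"))
#' @export
scan_motifs <- function(seq, motifs, min_score = NULL) {
  .check_dna(seq, "seq")
  motifs <- .as_motif_list(motifs)
  out <- lapply(motifs, function(m) {
    if (is.null(m$pwm)) {
      .scan_consensus(seq, m)
    } else {
      .scan_pwm(seq, m, min_score)
    }
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(motif_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  score = numeric(0)))
  }
  dplyr::arrange(out, .data$start, .data$motif_id, .data$strand)
}

# all (overlapping) exact occurrences via zero-width lookahead
.match_starts <- function(seq, site) {
  if (nchar(site) > nchar(seq)) return(integer(0))
  hits <- gregexpr(paste0("(?=", site, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

.scan_consensus <- function(seq, m) {
  L <- nchar(m$site_seq)
  fwd <- .match_starts(seq, m$site_seq)
  rev <- .match_starts(seq, revcomp(m$site_seq))
  tibble(
    motif_id = m$id,
    start = c(fwd, rev),
    end = c(fwd, rev) + L - 1L,
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    score = 2 * L
  )
}

.pwm_scores <- function(seq, pwm) {
  L <- ncol(pwm)
  n <- nchar(seq)
  if (L > n) return(numeric(0))
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  starts <- seq_len(n - L + 1L)
  vapply(starts, function(s) {
    sum(pwm[cbind(idx[s:(s + L - 1L)], seq_len(L))])
  }, 0)
}

# reverse-complemented PWM: scan the forward sequence for minus-strand sites
.rc_pwm <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

.scan_pwm <- function(seq, m, min_score) {
  thr <- min_score %||% (0.8 * sum(apply(m$pwm, 2, max)))
  L <- ncol(m$pwm)
  sc_f <- .pwm_scores(seq, m$pwm)
  sc_r <- .pwm_scores(seq, .rc_pwm(m$pwm))
  f <- which(sc_f >= thr)
  r <- which(sc_r >= thr)
  tibble(
    motif_id = m$id,
    start = as.integer(c(f, r)),
    end = as.integer(c(f, r)) + L - 1L,
    strand = c(rep("+", length(f)), rep("-", length(r))),
    score = c(sc_f[f], sc_r[r])
  )
}

# Does a specific previously-reported hit still match the current sequence?
.hit_alive <- function(seq, m, start, strand, min_score) {
  L <- nchar(m$site_seq)
  window <- substr(seq, start, start + L - 1L)
  if (is.null(m$pwm)) {
    target <- if (strand == "+") m$site_seq else revcomp(m$site_seq)
    identical(window, target)
  } else {
    thr <- min_score %||% (0.8 * sum(apply(m$pwm, 2, max)))
    pwm <- if (strand == "+") m$pwm else .rc_pwm(m$pwm)
    .pwm_scores(window, pwm) >= thr
  }
}

#' Remove all motif occurrences from an NPS insert by minimal substitution
#'
#' Iteratively rescans and edits until no motif in the set matches. Per round,
#' each surviving hit receives one substitution: at the hit position with the
#' largest score contribution (leftmost on ties), replaced by the base that
#' minimizes that contribution (alphabetically first on ties, never the
#' current base). Consensus motifs contribute equally at every position, so
#' the leftmost base of the matched window is edited. Edits for minus-strand
#' hits are chosen on the matched strand and complemented back.
#'
#' @param nps An [nps_record()].
#' @inheritParams scan_motifs
#' @param max_rounds Maximum scan-and-edit rounds before failing (default 10).
#' @return The scrubbed [nps_record()] with attributes `n_substitutions` and
#'   `rounds`.
#' @export
scrub_nps <- function(nps, motifs, max_rounds = 10L, min_score = NULL) {
  stopifnot(inherits(nps, "nps_record"))
  motifs <- .as_motif_list(motifs)
  seq <- nps$insert_seq
  n_sub <- 0L
  rounds <- 0L
  bases <- c("A", "C", "G", "T")
  while (rounds < max_rounds) {
    hits <- scan_motifs(seq, motifs, min_score = min_score)
    if (nrow(hits) == 0) break
    rounds <- rounds + 1L
    for (h in seq_len(nrow(hits))) {
      m <- motifs[[hits$motif_id[h]]]
      start <- hits$start[h]
      strand <- hits$strand[h]
      # earlier edits this round may already have destroyed this hit
      if (!.hit_alive(seq, m, start, strand, min_score)) next
      L <- nchar(m$site_seq)
      window <- substr(seq, start, start + L - 1L)
      matched <- if (strand == "+") window else revcomp(window)
      mbases <- strsplit(matched, "", fixed = TRUE)[[1]]
      if (is.null(m$pwm)) {
        pos <- 1L                          # equal contribution everywhere
        cur <- mbases[pos]
        repl <- bases[bases != cur][1L]    # alphabetical
      } else {
        contrib <- m$pwm[cbind(match(mbases, bases), seq_len(L))]
        pos <- which.max(contrib)
        cur <- mbases[pos]
        col <- m$pwm[, pos]
        cand <- bases[bases != cur]
        repl <- cand[which.min(col[cand])] # which.min: first (alphabetical) tie
      }
      # map position on the matched strand back to forward coordinates
      if (strand == "+") {
        fpos <- start + pos - 1L
        fbase <- repl
      } else {
        fpos <- start + (L - pos)
        fbase <- revcomp(repl)
      }
      substr(seq, fpos, fpos) <- fbase
      n_sub <- n_sub + 1L
    }
  }
  residual <- scan_motifs(seq, motifs, min_score = min_score)
  if (nrow(residual) > 0) {
    stop("scrub_nps: ", nrow(residual), " motif hit(s) remain after ",
         max_rounds, " rounds: ",
         paste(unique(residual$motif_id), collapse = ", "), call. = FALSE)
  }
  out <- nps_record(nps$id, seq, dyad_index = nps$dyad_index,
                    core_span = nps$core_span)
  attr(out, "n_substitutions") <- n_sub
  attr(out, "rounds") <- rounds
  out
}
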