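#' TFBS motif definitions
#'
#' A motif is either a consensus string (matched exactly on both strands) or a
#' position weight matrix (PWM) of per-position log2-odds against a flat
#' 0.25-per-base background. Reverse-complement variants can be linked through
#' `rc_of` so that control selection treats them as the same factor's sites.
#'
#' @param id Motif label, e.g. `"Klf4-1"`.
#' @param site_seq DNA string that is substituted into the insert during
#'   tiling; 4--40 nt.
#' @param tf Character vector of transcription factor names this site is
#'   assigned to (may be empty for a nonspecific site, or length > 1 for a
#'   composite site such as an Oct4-Sox2 element).
#' @param pwm Optional 4 x L numeric matrix of log2-odds, rows named
#'   A, C, G, T. When present, scanning is score-based instead of exact.
#' @param rc_of Optional id of the motif this one is the reverse complement of.
#' @return An object of class `tfbs_motif`.
#' @examples
#' tfbs_motif("Klf4-1", "CCCCACCC", tf = "KLF4")
#' @export
tfbs_motif <- function(id, site_seq, tf = character(0), pwm = NULL,
                       rc_of = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  .check_dna(site_seq, "site_seq")
  site_seq <- toupper(site_seq)
  L <- nchar(site_seq)
  if (L < 4L || L > 40L) {
    stop("site_seq must be 4-40 nt (got ", L, ").", call. = FALSE)
  }
  if (!is.null(pwm)) {
    if (!is.matrix(pwm) || nrow(pwm) != 4L || ncol(pwm) != L ||
        !identical(rownames(pwm), c("A", "C", "G", "T"))) {
      stop("pwm must be a 4 x ", L,
           " matrix with rows named A, C, G, T.", call. = FALSE)
    }
    storage.mode(pwm) <- "double"
  }
  structure(
    list(id = id, site_seq = site_seq, tf = as.character(tf), pwm = pwm,
         rc_of = rc_of),
    class = "tfbs_motif"
  )
}

#' @export
print.tfbs_motif <- function(x, ...) {
  cat("<tfbs_motif> ", x$id, ": ", x$site_seq,
      if (length(x$tf)) paste0(" [", paste(x$tf, collapse = "/"), "]") else "",
      if (!is.na(x$rc_of)) paste0(" (rc of ", x$rc_of, ")") else "",
      if (!is.null(x$pwm)) " +PWM" else "", "\n", sep = "")
  invisible(x)
}

.as_motif_list <- function(motifs) {
  if (inherits(motifs, "tfbs_motif")) motifs <- list(motifs)
  if (!is.list(motifs) || !all(vapply(motifs, inherits, TRUE, "tfbs_motif"))) {
    stop("`motifs` must be a tfbs_motif or a list of them.", call. = FALSE)
  }
  names(motifs) <- vapply(motifs, `[[`, "", "id")
  if (anyDuplicated(names(motifs))) {
    stop("Duplicated motif ids: ",
         paste(unique(names(motifs)[duplicated(names(motifs))]),
               collapse = ", "), call. = FALSE)
  }
  motifs
}

#' The demonstration TFBS panel
#'
#' The twelve binding-site variants used throughout the package documentation
#' and the demo library: four KLF4 sites (the canonical CCCCACCC element, a
#' long GC-rich embryonic-stem-cell element, and their reverse complements),
#' the OCT4 site, a composite Oct4-Sox2 element (assigned to both factors),
#' the SOX2 monomer site, the palindromic MYC E-box, three p53 sites, and one
#' nonspecific site assigned to no factor. The second p53 variant is a
#' representative canonical tandem half-site consensus.
#'
#' @return Named list of [tfbs_motif()] objects.
#' @examples
#' names(pioneer_tfbs_panel())
#' @export
pioneer_tfbs_panel <- function() {
  m <- list(
    tfbs_motif("Klf4-1", "CCCCACCC", tf = "KLF4"),
    tfbs_motif("Klf4-1RC", revcomp("CCCCACCC"), tf = "KLF4",
               rc_of = "Klf4-1"),
    tfbs_motif("Klf4-2", "GCCCCGCCCCGCCCC", tf = "KLF4"),
    tfbs_motif("Klf4-2RC", revcomp("GCCCCGCCCCGCCCC"), tf = "KLF4",
               rc_of = "Klf4-2"),
    tfbs_motif("OCT4", "TATGCAAAT", tf = "OCT4"),
    tfbs_motif("Oct4-Sox2", "CTTTGTTATGCAAAT", tf = c("OCT4", "SOX2")),
    tfbs_motif("SOX2", "ACAATGG", tf = "SOX2"),
    tfbs_motif("MYC", "ACCACGTGGT", tf = "MYC"),
    tfbs_motif("p53-1", "GGGCATGTCCGGGCATGTCC", tf = "p53"),
    tfbs_motif("p53-1RC", revcomp("GGGCATGTCCGGGCATGTCC"), tf = "p53",
               rc_of = "p53-1"),
    tfbs_motif("p53-2", "GGACATGTCCGGACATGTCC", tf = "p53"),
    tfbs_motif("NS", "TGTTTACTTTG")
  )
  .as_motif_list(m)
}

#' Motif ids assigned to a focal transcription factor
#'
#' Includes reverse-complement variants linked by `rc_of` in either direction,
#' so a control set can never contain a disguised focal site.
#'
#' @param motifs List of [tfbs_motif()].
#' @param tf Focal transcription factor name.
#' @return Character vector of motif ids.
#' @export
focal_motif_ids <- function(motifs, tf) {
  motifs <- .as_motif_list(motifs)
  direct <- names(motifs)[vapply(motifs, function(m) tf %in% m$tf, TRUE)]
  rc_of <- vapply(motifs, function(m) m$rc_of %||% NA_character_, "")
  repeat {
    extra <- names(motifs)[(rc_of %in% direct) | (names(motifs) %in% rc_of[direct])]
    grown <- union(direct, extra)
    if (setequal(grown, direct)) break
    direct <- grown
  }
  sort(direct)
}

#' Read/write a motif table
#'
#' Tab-separated columns: `id`, `site_seq`, `tf` (semicolon-separated, may be
#' empty), `rc_of` (may be empty). PWMs are not round-tripped through this
#' format.
#'
#' @param path File path.
#' @return `read_motif_table()` returns a named list of [tfbs_motif()].
#' @export
read_motif_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "site_seq")
  if (!all(need %in% names(d))) {
    stop("Motif table must have columns id and site_seq.", call. = FALSE)
  }
  m <- lapply(seq_len(nrow(d)), function(i) {
    tfs <- if ("tf" %in% names(d) && nzchar(d$tf[i] %||% "")) {
      strsplit(d$tf[i], ";", fixed = TRUE)[[1]]
    } else character(0)
    rc <- if ("rc_of" %in% names(d) && nzchar(d$rc_of[i] %||% "")) {
      d$rc_of[i]
    } else NA_character_
    tfbs_motif(d$id[i], d$site_seq[i], tf = tfs, rc_of = rc)
  })
  .as_motif_list(m)
}

#' @rdname read_motif_table
#' @param motifs Named list of [tfbs_motif()].
#' @export
write_motif_table <- function(motifs, path) {
  motifs <- .as_motif_list(motifs)
  d <- data.frame(
    id = names(motifs),
    site_seq = vapply(motifs, `[[`, "", "site_seq"),
    tf = vapply(motifs, function(m) paste(m$tf, collapse = ";"), ""),
    rc_of = vapply(motifs, function(m) {
      if (is.na(m$rc_of)) "" else m$rc_of
    }, "")
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
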