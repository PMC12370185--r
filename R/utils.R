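# Small shared helpers: DNA validation, reverse complement, coordinate
# conventions. Inserts are 1-based inclusive internally; BED input is 0-based
# half-open and converted here and nowhere else.

.check_dna <- function(x, what = "sequence", len = NULL) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`", what, "` must be a single character string.", call. = FALSE)
  }
  if (nzchar(x) && grepl("[^ACGT]", x)) {
    stop("`", what, "` contains characters outside A/C/G/T; ",
         "ambiguity codes and N are not accepted.", call. = FALSE)
  }
  if (!is.null(len) && nchar(x) != len) {
    stop("`", what, "` must be exactly ", len, " nt (got ", nchar(x), ").",
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round() in R rounds half to even; positional centroids use half-up so that
# e.g. a flat protection block over [1,50] gives 26, reproducibly.
round_half_up <- function(x) floor(x + 0.5)

# 1-based index of a motif's center base; left-of-center for even lengths.
motif_center_index <- function(len) as.integer(floor((len + 1L) / 2L))

# BED (0-based half-open) -> 1-based inclusive
bed_to_1based <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
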