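#' Round half away from zero
#'
#' Printed tables in the field round 0.5 up (away from zero), whereas base R
#' rounds to even; report-time rounding goes through this helper so printed
#' values match that convention.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.complementBase <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string (character in, character out)
#' @noRd
.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Total size of a region set in base pairs
#'
#' @param regions a [GenomicRanges::GRanges] of merged intervals.
#' @param unit `"bp"` or `"Mb"`.
#' @return numeric total size.
#' @export
regionSize <- function(regions, unit = c("bp", "Mb")) {
  unit <- match.arg(unit)
  s <- sum(as.numeric(GenomicRanges::width(regions)))
  if (unit == "Mb") s / 1e6 else s
}
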