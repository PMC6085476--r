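.SUB_CLASSES <- c("GC>AT", "TA>CG", "GC>CG", "GC>TA", "TA>AT", "TA>GC")

.CLASS_TABLE <- c(
  "C>T" = "GC>AT", "G>A" = "GC>AT",
  "T>C" = "TA>CG", "A>G" = "TA>CG",
  "C>G" = "GC>CG", "G>C" = "GC>CG",
  "C>A" = "GC>TA", "G>T" = "GC>TA",
  "T>A" = "TA>AT", "A>T" = "TA>AT",
  "T>G" = "TA>GC", "A>C" = "TA>GC")

#' Strand-collapsed substitution class
#'
#' Maps a single-base substitution to one of the six strand-collapsed
#' classes (`GC>AT`, `TA>CG`, `GC>CG`, `GC>TA`, `TA>AT`, `TA>GC`): a
#' substitution and its reverse complement belong to the same class, so
#' C>T and G>A are both the EMS-canonical `GC>AT` transition. Non-SNV
#' alleles (indels) return `"non_SNV"`.
#'
#' @param ref,alt allele strings (vectorized).
#' @return Character vector of classes.
#' @export
substitutionClass <- function(ref, alt) {
  out <- rep("non_SNV", length(ref))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L
  if (any(snv)) {
    badBase <- snv & (!ref %in% c("A", "C", "G", "T") |
                      !alt %in% c("A", "C", "G", "T"))
    if (any(badBase))
      .stopf("non-ACGT base in substitution %s>%s",
             ref[badBase][1], alt[badBase][1])
    out[snv] <- .CLASS_TABLE[paste0(ref[snv], ">", alt[snv])]
  }
  out
}

#' Transition/transversion ratio
#'
#' Ratio of transitions (`GC>AT` + `TA>CG`) to transversions (the other four
#' classes), rounded to one decimal; identical whether computed from counts
#' or from percentage shares. Returns `NA` when there are no transversions.
#'
#' @param transitions,transversions counts or percentage shares.
#' @return One-decimal ratio, or `NA_real_` when `transversions` is zero.
#' @export
tsTvRatio <- function(transitions, transversions) {
  if (transversions == 0) return(NA_real_)
  roundHalfUp(transitions / transversions, 1)
}

#' Substitution spectrum of a variant set
#'
#' Counts and percentage shares of the six strand-collapsed substitution
#' classes among the SNVs of a callset (indels are tallied separately and
#' excluded from all denominators), the transition and transversion shares,
#' and the Ts/Tv ratio. Percentages are rounded to one decimal at report
#' time; full precision is kept internally for the ratio.
#'
#' @param calls a [VariantCalls-class] object, or a character vector of
#'   classes as returned by [substitutionClass()].
#' @return A list with elements `counts` (named, six classes), `percent`
#'   (one decimal), `nSnv`, `nNonSnv`, `transitionPercent`,
#'   `transversionPercent` and `tsTv` (`NA` when no transversions).
#' @export
mutationSpectrum <- function(calls) {
  cls <- if (is(calls, "VariantCalls"))
    substitutionClass(refAllele(calls), altAllele(calls))
  else as.character(calls)
  nNonSnv <- sum(cls == "non_SNV")
  cls <- cls[cls != "non_SNV"]
  if (length(cls) == 0)
    .stopf("mutationSpectrum needs at least one SNV")
  counts <- table(factor(cls, levels = .SUB_CLASSES))
  counts <- stats::setNames(as.integer(counts), .SUB_CLASSES)
  n <- sum(counts)
  nTs <- counts[["GC>AT"]] + counts[["TA>CG"]]
  nTv <- n - nTs
  list(counts = counts,
       percent = roundHalfUp(100 * counts / n, 1),
       nSnv = n,
       nNonSnv = nNonSnv,
       transitionPercent = roundHalfUp(100 * nTs / n, 1),
       transversionPercent = roundHalfUp(100 * nTv / n, 1),
       tsTv = tsTvRatio(nTs, nTv))
}

#' Mutation density over a scored genome
#'
#' Density in mutations/Mb and its inverse spacing (kb per mutation) over
#' the scored (reliable) genome size, with an optional per-chromosome
#' breakdown. Report values are rounded (density to one decimal, spacing to
#' the nearest kb); unrounded values are returned alongside.
#'
#' @param calls a [VariantCalls-class] object, or a single mutation count.
#' @param regions the scored genome: a [GenomicRanges::GRanges] or a total
#'   size in bp.
#' @return A list with `n`, `sizeBp`, `densityPerMb`, `spacingKb`, their
#'   unrounded counterparts, and `perChromosome` (a data.frame, or `NULL`
#'   when `calls` is a bare count or `regions` a bare size).
#' @export
mutationDensity <- function(calls, regions) {
  n <- if (is(calls, "VariantCalls")) length(calls) else as.numeric(calls)
  if (n < 0) .stopf("negative mutation count")
  sizeBp <- if (is(regions, "GRanges")) regionSize(regions)
            else as.numeric(regions)
  if (sizeBp <= 0) .stopf("scored genome size must be positive")
  density <- n / (sizeBp / 1e6)
  spacing <- if (n > 0) (sizeBp / n) / 1e3 else NA_real_
  perChrom <- NULL
  if (is(calls, "VariantCalls") && is(regions, "GRanges")) {
    chromBp <- tapply(as.numeric(GenomicRanges::width(regions)),
                      as.character(GenomicRanges::seqnames(regions)), sum)
    cnt <- table(factor(variantChrom(calls), levels = names(chromBp)))
    perChrom <- data.frame(
      chrom = names(chromBp),
      reliableBp = as.numeric(chromBp),
      n = as.integer(cnt),
      densityPerMb = roundHalfUp(as.integer(cnt) /
                                   (as.numeric(chromBp) / 1e6), 1),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  list(n = n, sizeBp = sizeBp,
       densityPerMb = roundHalfUp(density, 1),
       spacingKb = if (is.na(spacing)) NA_real_ else roundHalfUp(spacing, 0),
       densityUnrounded = density,
       spacingUnrounded = spacing,
       perChromosome = perChrom)
}
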