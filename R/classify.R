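#' Genotype-quality filter
#'
#' Sample calls with GQ at or below `minGQ` are masked to `missing` (the
#' retained calls are those with GQ strictly greater than the threshold).
#' Variants left without any sample carrying the ALT allele are dropped:
#' no evidence for the variant remains.
#'
#' @param calls a [VariantCalls-class] object.
#' @param minGQ phred threshold; calls with `GQ > minGQ` survive (default 20).
#' @return The filtered [VariantCalls-class].
#' @export
gqFilter <- function(calls, minGQ = 20) {
  if (length(calls) == 0) return(calls)
  gt <- genotypes(calls)
  gq <- genotypeQuals(calls)
  mask <- is.na(gq) | gq <= minGQ
  gt[mask] <- "missing"
  carries <- rowSums(gt == "het" | gt == "hom_alt") > 0
  out <- calls
  out@gt <- gt
  out[carries]
}

#' Family-level genotype of a pooled callset
#'
#' Aggregates the per-sample calls of one family into a single zygosity:
#' `absent` when no sample carries the ALT allele, `het` when at least one
#' carrying sample is heterozygous, `hom_alt` when all carrying samples are
#' homozygous ALT. With pooled DNA samples a segregating (heterozygous)
#' mutation shows up as a heterozygous pool call, so any heterozygous sample
#' marks the variant as still segregating in the family.
#'
#' @param calls a [VariantCalls-class] object.
#' @return Character vector (`"absent"`, `"het"`, `"hom_alt"`), one per
#'   variant.
#' @export
familyGenotype <- function(calls) {
  gt <- genotypes(calls)
  anyHet <- rowSums(gt == "het") > 0
  anyHom <- rowSums(gt == "hom_alt") > 0
  ifelse(anyHet, "het", ifelse(anyHom, "hom_alt", "absent"))
}

#' Classify variants of two mutant families
#'
#' Partitions the filtered variants of two families into: variants shared by
#' both families (spontaneous background polymorphisms), family-specific
#' homozygous variants (spontaneous polymorphisms fixed in one family, not
#' EMS), and family-specific heterozygous variants — the operational
#' EMS-induced mutation set. Sharing requires the identical
#' (chrom, pos, ref, alt) allele in both families.
#'
#' @param callsets named list of two [VariantCalls-class] objects, one per
#'   family; names are the family identifiers.
#' @param sharedRegions optional [GenomicRanges::GRanges]; when supplied both
#'   callsets are first restricted to it (positions must be reliable in both
#'   families for cross-family comparison to be meaningful).
#' @return A [ClassifiedCallset-class].
#' @export
classifyVariants <- function(callsets, sharedRegions = NULL) {
  if (length(callsets) != 2 || is.null(names(callsets)) ||
      anyDuplicated(names(callsets)))
    .stopf("classifyVariants needs a named list of two distinct families")
  fams <- names(callsets)
  if (!is.null(sharedRegions))
    callsets <- lapply(callsets, filterCallsByRegions, regions = sharedRegions)
  keys <- lapply(callsets, variantKeys)
  fg <- lapply(callsets, familyGenotype)
  # variants with no surviving carrier cannot be assessed
  for (f in fams) {
    present <- fg[[f]] != "absent"
    callsets[[f]] <- callsets[[f]][present]
    keys[[f]] <- keys[[f]][present]
    fg[[f]] <- fg[[f]][present]
  }
  sharedKeys <- intersect(keys[[1]], keys[[2]])
  shared <- list(); specificHom <- list(); ems <- list()
  homInShared <- list()
  for (f in fams) {
    isShared <- keys[[f]] %in% sharedKeys
    shared[[f]] <- callsets[[f]][isShared]
    homInShared[[f]] <- sharedKeys %in% keys[[f]][isShared & fg[[f]] == "hom_alt"]
    spec <- !isShared
    specificHom[[f]] <- callsets[[f]][spec & fg[[f]] == "hom_alt"]
    ems[[f]] <- callsets[[f]][spec & fg[[f]] == "het"]
  }
  new("ClassifiedCallset", familyIds = fams, shared = shared,
      specificHom = specificHom, ems = ems,
      sharedHomBoth = sum(homInShared[[1]] & homInShared[[2]]))
}

#' Fraction of a family's variants shared with the other family
#'
#' `100 * shared / (shared + family-specific)` for one family, rounded to one
#' decimal. Large shared fractions indicate background polymorphisms of the
#' common founder genotype rather than induced mutations.
#'
#' @param classified a [ClassifiedCallset-class].
#' @param family family identifier.
#' @return Percentage (one decimal).
#' @export
sharedFraction <- function(classified, family) {
  ns <- length(classified@shared[[family]])
  tot <- ns + length(classified@specificHom[[family]]) +
    length(classified@ems[[family]])
  sharedPercent(ns, tot)
}

#' @rdname sharedFraction
#' @param nShared,nTotal shared and total variant counts for one family.
#' @export
sharedPercent <- function(nShared, nTotal) {
  if (nTotal == 0) .stopf("family total variant count is zero")
  roundHalfUp(100 * nShared / nTotal, 1)
}
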