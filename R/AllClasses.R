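#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges
NULL

.GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Per-sample variant calls
#'
#' Holds one record per (position, ALT allele) with per-sample genotype
#' category, genotype quality (GQ) and read depth (DP). Multi-allelic VCF
#' records are split into one `VariantCalls` row per ALT allele. Positions
#' are 1-based.
#'
#' @slot chrom chromosome name per variant.
#' @slot pos 1-based reference position per variant.
#' @slot ref,alt reference and alternate allele strings (`ref != alt`).
#' @slot gt character matrix (variants x samples) with values
#'   `"hom_ref"`, `"het"`, `"hom_alt"` or `"missing"`.
#' @slot gq,gq numeric matrix of phred-scaled genotype qualities.
#' @slot dp numeric matrix of per-sample read depths.
#' @slot samples sample names (matrix column names).
#'
#' @export
setClass("VariantCalls", representation(
  chrom = "character",
  pos = "integer",
  ref = "character",
  alt = "character",
  gt = "matrix",
  gq = "matrix",
  dp = "matrix",
  samples = "character"
))

setValidity("VariantCalls", function(object) {
  n <- length(object@pos)
  msg <- character()
  if (length(object@chrom) != n || length(object@ref) != n ||
      length(object@alt) != n)
    msg <- c(msg, "chrom/pos/ref/alt lengths differ")
  for (sl in c("gt", "gq", "dp")) {
    m <- slot(object, sl)
    if (nrow(m) != n)
      msg <- c(msg, sprintf("%s matrix has %d rows for %d variants", sl, nrow(m), n))
    if (ncol(m) != length(object@samples))
      msg <- c(msg, sprintf("%s matrix columns do not match samples", sl))
  }
  if (n > 0) {
    if (any(object@pos < 1L)) msg <- c(msg, "positions must be >= 1")
    if (any(object@ref == object@alt)) msg <- c(msg, "ref equal to alt")
    bad <- !(object@gt %in% .GT_LEVELS)
    if (any(bad)) msg <- c(msg, "invalid genotype category")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantCalls object
#'
#' @param chrom,pos,ref,alt parallel vectors describing each variant allele.
#' @param gt,gq,dp matrices (variants x samples); `gt` uses the categories
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @param samples sample names; defaults to `colnames(gt)`.
#' @return A [VariantCalls-class] object, sorted by (chrom, pos, alt).
#' @export
VariantCalls <- function(chrom, pos, ref, alt, gt, gq, dp,
                         samples = colnames(gt)) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  gt <- as.matrix(gt); gq <- as.matrix(gq); dp <- as.matrix(dp)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  colnames(gt) <- colnames(gq) <- colnames(dp) <- samples
  o <- order(chrom, pos, alt)
  new("VariantCalls",
      chrom = chrom[o], pos = pos[o], ref = ref[o], alt = alt[o],
      gt = gt[o, , drop = FALSE], gq = gq[o, , drop = FALSE],
      dp = dp[o, , drop = FALSE], samples = samples)
}

#' @describeIn VariantCalls number of variant records
#' @param x a `VariantCalls` object.
#' @export
setMethod("length", "VariantCalls", function(x) length(x@pos))

#' @export
setMethod("[", "VariantCalls", function(x, i, j, ..., drop = TRUE) {
  if (is.logical(i)) i <- which(i)
  new("VariantCalls",
      chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i], alt = x@alt[i],
      gt = x@gt[i, , drop = FALSE], gq = x@gq[i, , drop = FALSE],
      dp = x@dp[i, , drop = FALSE], samples = x@samples)
})

#' @export
setMethod("show", "VariantCalls", function(object) {
  cat("VariantCalls with", length(object), "records over",
      length(object@samples), "samples\n")
  if (length(object)) {
    k <- head(variantKeys(object), 5)
    cat("  ", paste(k, collapse = ", "),
        if (length(object) > 5) ", ..." else "", "\n", sep = "")
  }
})

#' Accessors for VariantCalls slots
#'
#' `variantKeys` returns the canonical `"chrom:pos:ref>alt"` identity used
#' when comparing callsets across families; `isSnv` flags single-base
#' substitutions; `sampleNames` returns sample names; `genotypes`,
#' `genotypeQuals` and `readDepths` return the per-sample matrices;
#' `variantRanges` returns the variant positions as a [GenomicRanges::GRanges].
#'
#' @param x a [VariantCalls-class] object.
#' @return See individual descriptions.
#' @export
variantKeys <- function(x) {
  paste0(x@chrom, ":", x@pos, ":", x@ref, ">", x@alt)
}

#' @rdname variantKeys
#' @export
isSnv <- function(x) nchar(x@ref) == 1L & nchar(x@alt) == 1L

#' @rdname variantKeys
#' @export
sampleNames <- function(x) x@samples

#' @rdname variantKeys
#' @export
genotypes <- function(x) x@gt

#' @rdname variantKeys
#' @export
genotypeQuals <- function(x) x@gq

#' @rdname variantKeys
#' @export
readDepths <- function(x) x@dp

#' @rdname variantKeys
#' @export
refAllele <- function(x) x@ref

#' @rdname variantKeys
#' @export
altAllele <- function(x) x@alt

#' @rdname variantKeys
#' @export
variantChrom <- function(x) x@chrom

#' @rdname variantKeys
#' @export
variantPos <- function(x) x@pos

#' @rdname variantKeys
#' @export
variantRanges <- function(x) {
  GRanges(x@chrom, IRanges(x@pos, width = pmax(nchar(x@ref), 1L)))
}

#' Gene model
#'
#' A single transcript model: sorted non-overlapping exons, CDS segments
#' contained in the exons, and the derived untranslated regions. All
#' intervals are 1-based closed genomic [IRanges::IRanges] on `chrom`.
#' For a complete model the total CDS length is divisible by 3.
#'
#' @slot geneId gene/transcript identifier.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons,cds,utr5,utr3 genomic intervals in ascending order.
#' @export
setClass("GeneModel", representation(
  geneId = "character",
  chrom = "character",
  strand = "character",
  exons = "IRanges",
  cds = "IRanges",
  utr5 = "IRanges",
  utr3 = "IRanges"
))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) > 1) {
    if (is.unsorted(IRanges::start(ex)))
      msg <- c(msg, "exons not sorted")
    if (any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons overlap or touch")
  }
  cds <- object@cds
  if (length(cds)) {
    outside <- sum(IRanges::width(cds)) !=
      sum(IRanges::width(IRanges::intersect(cds, ex)))
    if (outside)
      msg <- c(msg, sprintf("CDS outside exons in gene %s", object@geneId))
    if (sum(IRanges::width(cds)) %% 3L != 0L)
      msg <- c(msg, sprintf("CDS length of gene %s not divisible by 3",
                            object@geneId))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds genomic [IRanges::IRanges] (1-based closed).
#' @param utr5,utr3 optional UTR intervals; derived from `exons \ cds` by
#'   strand when missing.
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(geneId, chrom, strand, exons, cds,
                      utr5 = NULL, utr3 = NULL) {
  exons <- exons[order(IRanges::start(exons))]
  cds <- cds[order(IRanges::start(cds))]
  if (is.null(utr5) || is.null(utr3)) {
    noncds <- IRanges::setdiff(exons, cds)
    if (length(cds)) {
      cs <- min(IRanges::start(cds)); ce <- max(IRanges::end(cds))
      left <- noncds[IRanges::end(noncds) < cs]
      right <- noncds[IRanges::start(noncds) > ce]
      if (strand == "+") { u5 <- left; u3 <- right } else { u5 <- right; u3 <- left }
    } else {
      u5 <- IRanges(); u3 <- IRanges()
    }
    if (is.null(utr5)) utr5 <- u5
    if (is.null(utr3)) utr3 <- u3
  }
  new("GeneModel", geneId = as.character(geneId), chrom = as.character(chrom),
      strand = strand, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
}

#' @export
setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s:%d-%d, strand %s): %d exon(s), CDS %d bp\n",
              object@geneId, object@chrom,
              min(IRanges::start(object@exons)), max(IRanges::end(object@exons)),
              object@strand, length(object@exons),
              sum(IRanges::width(object@cds))))
})

#' @rdname GeneModel
#' @param x a `GeneModel`.
#' @export
geneBounds <- function(x) {
  IRanges(min(IRanges::start(x@exons)), max(IRanges::end(x@exons)))
}

#' Classified two-family callset
#'
#' Result of [classifyVariants()]: variants partitioned into polymorphisms
#' shared by both families, family-specific homozygous variants (treated as
#' spontaneous background) and family-specific heterozygous variants, the
#' operational EMS-induced set.
#'
#' @slot familyIds the two family identifiers.
#' @slot shared named list of two [VariantCalls-class]: each family's view of
#'   the shared variants.
#' @slot specificHom,ems named lists of two `VariantCalls` with the
#'   family-specific homozygous and heterozygous sets.
#' @slot sharedHomBoth number of shared variants homozygous in both families.
#' @export
setClass("ClassifiedCallset", representation(
  familyIds = "character",
  shared = "list",
  specificHom = "list",
  ems = "list",
  sharedHomBoth = "integer"
))

setValidity("ClassifiedCallset", function(object) {
  msg <- character()
  if (length(object@familyIds) != 2 || anyDuplicated(object@familyIds))
    msg <- c(msg, "exactly two distinct family ids required")
  for (sl in c("shared", "specificHom", "ems")) {
    l <- slot(object, sl)
    if (!identical(names(l), object@familyIds))
      msg <- c(msg, sprintf("%s list names must equal familyIds", sl))
  }
  if (length(object@shared[[1]]) != length(object@shared[[2]]))
    msg <- c(msg, "shared views of the two families differ in size")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ClassifiedCallset", function(object) {
  f <- object@familyIds
  cat("ClassifiedCallset for families", paste(f, collapse = " / "), "\n")
  cat(sprintf("  shared: %d (hom in both: %d)\n",
              length(object@shared[[1]]), object@sharedHomBoth))
  for (fam in f)
    cat(sprintf("  %s: specific hom %d, EMS (specific het) %d\n", fam,
                length(object@specificHom[[fam]]), length(object@ems[[fam]])))
})

#' Accessors for ClassifiedCallset
#'
#' @param x a [ClassifiedCallset-class].
#' @param family family identifier.
#' @return `emsCalls`/`specificHomCalls`/`sharedCalls` return the
#'   [VariantCalls-class] for one family; `familyIds` the two identifiers;
#'   `classCounts` a data.frame of per-category counts.
#' @export
emsCalls <- function(x, family) x@ems[[family]]

#' @rdname emsCalls
#' @export
specificHomCalls <- function(x, family) x@specificHom[[family]]

#' @rdname emsCalls
#' @export
sharedCalls <- function(x, family) x@shared[[family]]

#' @rdname emsCalls
#' @export
familyIds <- function(x) x@familyIds

#' @rdname emsCalls
#' @export
classCounts <- function(x) {
  f <- x@familyIds
  data.frame(
    family = rep(f, each = 3),
    category = rep(c("shared", "specific_hom", "ems"), 2),
    n = c(length(x@shared[[f[1]]]), length(x@specificHom[[f[1]]]),
          length(x@ems[[f[1]]]),
          length(x@shared[[f[2]]]), length(x@specificHom[[f[2]]]),
          length(x@ems[[f[2]]])),
    stringsAsFactors = FALSE)
}
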