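#' Depth-reliable genome regions
#'
#' A position is reliable when its depth lies within `[minDepth, maxDepth]`
#' in every sample of the family; a single sample failing the bounds removes
#' the position. The bounds are inclusive: the filter removes depth < 8 or
#' > 100 at the defaults, so depths of exactly 8 or 100 pass. The depth
#' ceiling is a proxy for collapsed segmental duplications.
#'
#' @param tracks list of per-sample depth tracks ([S4Vectors::RleList], as
#'   returned by [readDepthTrack()] or the simulator), all on the same genome.
#' @param minDepth,maxDepth inclusive depth bounds (defaults 8 and 100).
#' @return A merged [GenomicRanges::GRanges] of reliable regions.
#' @export
depthReliableRegions <- function(tracks, minDepth = 8, maxDepth = 100) {
  if (length(tracks) == 0)
    .stopf("depthReliableRegions needs at least one depth track")
  if (minDepth <= 0 || minDepth > maxDepth)
    .stopf("require 0 < minDepth <= maxDepth")
  ok <- Reduce(`&`, lapply(tracks, function(t) t >= minDepth & t <= maxDepth))
  irl <- IRanges::IRangesList(lapply(ok, function(r) as(r, "IRanges")))
  gr <- GRanges(irl)
  lens <- vapply(tracks[[1]], length, 0L)
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  GenomicRanges::reduce(gr)
}

#' Sliding windows over a genome
#'
#' Windows of `windowSize` bp every `step` bp, anchored at the start of each
#' chromosome (plus `offset`), including a final partial window.
#'
#' @param seqlengths named integer vector of chromosome lengths.
#' @param windowSize,step window size and step in bp.
#' @param offset shift of the first window start in bp (default 0).
#' @return A [GenomicRanges::GRanges] of windows.
#' @export
genomeWindows <- function(seqlengths, windowSize = 1000L, step = 500L,
                          offset = 0L) {
  if (step > windowSize) .stopf("step must be <= windowSize")
  starts <- lapply(names(seqlengths), function(chr)
    seq.int(1L + offset, seqlengths[[chr]], by = step))
  chrom <- rep(names(seqlengths), lengths(starts))
  starts <- unlist(starts)
  ends <- pmin(starts + windowSize - 1L,
               unname(seqlengths[chrom]))
  gr <- GRanges(chrom, IRanges(starts, ends),
                seqinfo = GenomeInfoDb::Seqinfo(names(seqlengths),
                                                unname(seqlengths)))
  gr
}

#' Hyperpolymorphic windows
#'
#' Sliding 1-kb / 500-bp windows with more than `maxVariantsPerWindow`
#' variants are flagged as likely mapping artifacts; the union of flagged
#' windows is returned as a merged region set to be subtracted from the
#' reliable genome (variants inside it are dropped). A position is removed
#' whenever any covering window is hyperpolymorphic.
#'
#' @param calls a [VariantCalls-class] object (variant positions counted per
#'   window).
#' @param seqlengths named chromosome lengths.
#' @param windowSize,step,offset window tiling parameters, see
#'   [genomeWindows()].
#' @param maxVariantsPerWindow maximum tolerated variants per window
#'   (default 1).
#' @return A merged [GenomicRanges::GRanges] of discarded windows (empty when
#'   no window exceeds the threshold).
#' @export
hyperpolymorphicWindows <- function(calls, seqlengths, windowSize = 1000L,
                                    step = 500L, maxVariantsPerWindow = 1L,
                                    offset = 0L) {
  if (maxVariantsPerWindow < 1L) .stopf("maxVariantsPerWindow must be >= 1")
  win <- genomeWindows(seqlengths, windowSize, step, offset)
  if (length(calls) == 0)
    return(GRanges(seqlengths = seqlengths))
  sites <- GRanges(variantChrom(calls), IRanges(variantPos(calls), width = 1L))
  n <- GenomicRanges::countOverlaps(win, sites)
  GenomicRanges::reduce(win[n > maxVariantsPerWindow])
}

#' Region set arithmetic
#'
#' Thin strand-agnostic wrappers around [GenomicRanges::setdiff()] and
#' [GenomicRanges::intersect()] returning merged region sets.
#'
#' @param a,b region sets ([GenomicRanges::GRanges]) on the same genome.
#' @return A merged [GenomicRanges::GRanges].
#' @export
regionSubtract <- function(a, b) {
  GenomicRanges::reduce(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
}

#' @rdname regionSubtract
#' @export
regionIntersect <- function(a, b) {
  GenomicRanges::reduce(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Restrict variant calls to a region set
#'
#' Keeps variants whose reference position falls inside `regions`.
#'
#' @param calls a [VariantCalls-class] object.
#' @param regions a [GenomicRanges::GRanges].
#' @return The filtered [VariantCalls-class].
#' @export
filterCallsByRegions <- function(calls, regions) {
  if (length(calls) == 0) return(calls)
  sites <- GRanges(variantChrom(calls), IRanges(variantPos(calls), width = 1L))
  keep <- GenomicRanges::countOverlaps(sites, regions,
                                       ignore.strand = TRUE) > 0
  calls[keep]
}

#' Pairwise-distance variant filter
#'
#' Alternative formulation of the clustered-variant filter: drop every
#' variant that has another variant closer than `minSpacing` bp on the same
#' chromosome. This differs from the windowed filter on edge cases (for
#' example two variants 900 bp apart straddling a window boundary survive the
#' windowed filter but not this one); the windowed filter is the canonical
#' one in [runPipeline()].
#'
#' @param calls a [VariantCalls-class] object.
#' @param minSpacing minimum tolerated distance in bp (default 1000).
#' @return The filtered [VariantCalls-class].
#' @export
pairwiseDistanceFilter <- function(calls, minSpacing = 1000L) {
  if (length(calls) < 2) return(calls)
  chrom <- variantChrom(calls); pos <- variantPos(calls)
  keep <- rep(TRUE, length(calls))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    p <- pos[i]
    o <- order(p); p <- p[o]
    d <- diff(p)
    close <- d < minSpacing
    bad <- logical(length(p))
    bad[c(close, FALSE)] <- TRUE
    bad[c(FALSE, close)] <- TRUE
    keep[i[o]] <- !bad
  }
  calls[keep]
}
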