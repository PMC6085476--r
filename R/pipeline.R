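#' Run the full EMS mutation-discovery pipeline
#'
#' Executes the filtering and classification stages in order: genotype-quality
#' filter, per-family depth-reliable regions, removal of hyperpolymorphic
#' windows, intersection of the two family region sets into the shared scored
#' genome, cross-family classification, then spectrum, density, flanking
#' context and (when gene models are supplied) consequence annotation of the
#' per-family EMS sets. Variant counts never increase across successive
#' stages.
#'
#' @param calls named list of two [VariantCalls-class] objects (one per
#'   family).
#' @param depth named list (per family) of per-sample depth tracks
#'   ([S4Vectors::RleList]).
#' @param genome named [Biostrings::DNAStringSet] (needed for context
#'   profiles and annotation; optional).
#' @param geneModels list of [GeneModel-class] (optional; enables
#'   annotation).
#' @param minGQ genotype-quality threshold (calls with GQ > minGQ survive).
#' @param minDepth,maxDepth inclusive per-sample depth bounds.
#' @param windowSize,step,maxVariantsPerWindow hyperpolymorphic-window
#'   parameters.
#' @return A list with `summary` (stage counts, Mb retained, per-family EMS
#'   counts, density, spectrum, Ts/Tv, annotation tallies), `classified`
#'   (the [ClassifiedCallset-class]), `regions` (per-family and shared),
#'   `density`, `spectrum`, `context` and `annotation` per family.
#' @export
runPipeline <- function(calls, depth, genome = NULL, geneModels = NULL,
                        minGQ = 20, minDepth = 8, maxDepth = 100,
                        windowSize = 1000L, step = 500L,
                        maxVariantsPerWindow = 1L) {
  if (length(calls) != 2 || is.null(names(calls)))
    .stopf("classify stage requires exactly two named family callsets")
  fams <- names(calls)
  if (!identical(sort(fams), sort(names(depth))))
    .stopf("depth tracks must be named by the same families as calls")
  stageCounts <- list()
  rec <- function(stage, cl) {
    stageCounts[[length(stageCounts) + 1L]] <<- data.frame(
      stage = stage, family = fams, n = vapply(cl, length, 0L),
      stringsAsFactors = FALSE)
  }
  rec("input", calls)

  calls <- lapply(calls, gqFilter, minGQ = minGQ)
  rec("gq_filter", calls)

  famRegions <- lapply(fams, function(f)
    depthReliableRegions(depth[[f]], minDepth, maxDepth))
  names(famRegions) <- fams
  calls <- lapply(fams, function(f)
    filterCallsByRegions(calls[[f]], famRegions[[f]]))
  names(calls) <- fams
  rec("depth_filter", calls)

  seqlens <- vapply(depth[[1]][[1]], length, 0L)
  badWindows <- lapply(fams, function(f)
    hyperpolymorphicWindows(calls[[f]], seqlens, windowSize, step,
                            maxVariantsPerWindow))
  names(badWindows) <- fams
  famRegions2 <- lapply(fams, function(f)
    regionSubtract(famRegions[[f]], badWindows[[f]]))
  names(famRegions2) <- fams
  calls <- lapply(fams, function(f)
    filterCallsByRegions(calls[[f]], famRegions2[[f]]))
  names(calls) <- fams
  rec("window_filter", calls)

  sharedRegions <- regionIntersect(famRegions2[[1]], famRegions2[[2]])
  calls <- lapply(calls, filterCallsByRegions, regions = sharedRegions)
  rec("intersection", calls)

  classified <- classifyVariants(calls, sharedRegions = NULL)

  density <- list(); spectrum <- list(); context <- list(); annotation <- list()
  for (f in fams) {
    ems <- emsCalls(classified, f)
    density[[f]] <- mutationDensity(ems, sharedRegions)
    spectrum[[f]] <- if (sum(isSnv(ems)) > 0) mutationSpectrum(ems) else NULL
    if (!is.null(genome) && length(ems))
      context[[f]] <- tryCatch(contextProfile(ems, genome),
                               error = function(e) NULL)
    if (!is.null(genome) && !is.null(geneModels) && length(ems))
      annotation[[f]] <- annotateVariants(ems, geneModels, genome)
  }

  stageCounts <- do.call(rbind, stageCounts)
  summary <- list(
    schemaVersion = 1L,
    stages = stageCounts,
    mbRetained = list(
      depthReliable = vapply(famRegions, regionSize, 0, unit = "Mb"),
      afterWindows = vapply(famRegions2, regionSize, 0, unit = "Mb"),
      shared = regionSize(sharedRegions, unit = "Mb")),
    classCounts = classCounts(classified),
    sharedFraction = vapply(fams, function(f)
      sharedFraction(classified, f), 0),
    emsCounts = vapply(fams, function(f) length(emsCalls(classified, f)), 0L),
    densityPerMb = vapply(fams, function(f) density[[f]]$densityPerMb, 0),
    spacingKb = vapply(fams, function(f) density[[f]]$spacingKb, 0),
    tsTv = vapply(fams, function(f)
      if (is.null(spectrum[[f]])) NA_real_ else spectrum[[f]]$tsTv, 0),
    annotationCounts = if (length(annotation))
      summarizeAnnotations(annotation) else NULL)
  list(summary = summary, classified = classified,
       regions = list(family = famRegions2, shared = sharedRegions,
                      depthReliable = famRegions,
                      discardedWindows = badWindows),
       density = density, spectrum = spectrum, context = context,
       annotation = annotation)
}
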