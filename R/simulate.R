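#' Simulation parameters
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' two mutant families, four pooled samples each, median depth 35, an
#' EMS spectrum dominated by GC>AT transitions (share 0.80) with TA>CG at
#' 0.07 and the four transversions splitting the remaining 0.13, and a
#' twofold site-selection enrichment for a pyrimidine flanking the mutated
#' C. Variant counts are per-Mb rates over a 10 Mb genome. True variants are
#' placed with a hard minimum spacing of `minSpacing` bp (real EMS mutations
#' are tens of kb apart; sub-kb clusters are treated as artifacts), while
#' injected artifact clusters deliberately violate it to exercise the window
#' filter.
#'
#' @param genomeLength total genome size in bp.
#' @param nChromosomes number of chromosomes.
#' @param gcContent genome GC fraction in (0, 1].
#' @param nGenes number of gene models.
#' @param sharedHom,sharedSeg spontaneous polymorphisms present in both
#'   families (homozygous / still segregating).
#' @param specificHom per-family counts of family-specific homozygous
#'   (spontaneous, fixed) variants.
#' @param emsPerFamily per-family counts of EMS (family-specific
#'   heterozygous) mutations.
#' @param emsSpectrum probability vector over the six substitution classes.
#' @param contextBias site-selection weight multiplier for GC>AT sites whose
#'   oriented -1 or +1 base is a pyrimidine.
#' @param meanDepth,depthDispersion mean read depth and gamma shape of the
#'   per-chunk depth distribution.
#' @param gqMean,gqSd,lowGqRate genotype-quality distribution and the rate of
#'   spuriously low-GQ calls.
#' @param nSamples pooled samples per family.
#' @param familyIds the two family names.
#' @param lowDepthFraction,highDepthFraction genome fractions forced to
#'   low (one sample) / high (all samples) depth per family.
#' @param artifactClusters,artifactClusterSize clustered artifact variants
#'   injected per family (clusters of this many variants within ~250 bp).
#' @param minSpacing minimum distance between true variants in bp.
#' @return A validated list of class `SimParams`.
#' @export
simParams <- function(genomeLength = 10e6,
                      nChromosomes = 4,
                      gcContent = 0.37,
                      nGenes = 200,
                      sharedHom = 220,
                      sharedSeg = 60,
                      specificHom = c(L1 = 35, L2 = 25),
                      emsPerFamily = c(L1 = 120, L2 = 60),
                      emsSpectrum = c("GC>AT" = 0.80, "TA>CG" = 0.07,
                                      "GC>CG" = 0.0325, "GC>TA" = 0.0325,
                                      "TA>AT" = 0.0325, "TA>GC" = 0.0325),
                      contextBias = 2.0,
                      meanDepth = 35,
                      depthDispersion = 20,
                      gqMean = 70, gqSd = 8, lowGqRate = 0.005,
                      nSamples = 4,
                      familyIds = c("L1", "L2"),
                      lowDepthFraction = 0.01,
                      highDepthFraction = 0.005,
                      artifactClusters = 5,
                      artifactClusterSize = 3,
                      minSpacing = 1001) {
  p <- as.list(environment())
  if (p$gcContent <= 0 || p$gcContent > 1)
    .stopf("gcContent must lie in (0, 1]")
  if (abs(sum(p$emsSpectrum) - 1) > 1e-8)
    .stopf("emsSpectrum must sum to 1")
  if (!setequal(names(p$emsSpectrum), .SUB_CLASSES))
    .stopf("emsSpectrum must name the six substitution classes")
  if (length(p$familyIds) != 2 || anyDuplicated(p$familyIds))
    .stopf("exactly two distinct familyIds required")
  names(p$specificHom) <- names(p$emsPerFamily) <- p$familyIds
  if (any(c(p$sharedHom, p$sharedSeg, p$specificHom, p$emsPerFamily) < 0))
    .stopf("variant counts must be non-negative")
  class(p) <- "SimParams"
  p
}

#' Simulate a random genome
#'
#' Bases are drawn i.i.d. with the requested GC content and split into
#' near-equal chromosomes. Reproducible under `set.seed()`.
#'
#' @param genomeLength total size in bp.
#' @param nChromosomes number of chromosomes (`chr1`, `chr2`, ...).
#' @param gcContent GC fraction in (0, 1].
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulateGenome <- function(genomeLength = 10e6, nChromosomes = 4,
                           gcContent = 0.37) {
  if (genomeLength <= 0) .stopf("genomeLength must be positive")
  if (gcContent <= 0 || gcContent > 1) .stopf("gcContent must lie in (0, 1]")
  L <- as.integer(genomeLength)
  prob <- c((1 - gcContent) / 2, gcContent / 2, gcContent / 2,
            (1 - gcContent) / 2)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob)
  per <- rep(L %/% nChromosomes, nChromosomes)
  per[nChromosomes] <- per[nChromosomes] + L %% nChromosomes
  ends <- cumsum(per); starts <- ends - per + 1
  seqs <- vapply(seq_len(nChromosomes), function(i)
    paste(bases[starts[i]:ends[i]], collapse = ""), "")
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(nChromosomes))
  g
}

# replace internal stop codons and fix start/stop of a CDS char vector of
# codons; returns the corrected transcript-strand CDS string
.completeCds <- function(cdsSeq) {
  codons <- substring(cdsSeq, seq(1, nchar(cdsSeq), 3),
                      seq(3, nchar(cdsSeq), 3))
  codons[1] <- "ATG"
  nc <- length(codons)
  stops <- c("TAA", "TAG", "TGA")
  internal <- which(codons[-nc] %in% stops)
  if (length(internal))
    codons[internal] <- paste0(substr(codons[internal], 1, 2), "C")
  codons[nc] <- "TAA"
  paste(codons, collapse = "")
}

#' Simulate gene models and write their coding sequences into the genome
#'
#' Places non-overlapping multi-exon genes on both strands with 5' and 3'
#' UTRs in the terminal exons, then patches the genome so every CDS is
#' complete: starts with ATG, ends with a stop codon, has no internal stop,
#' and has length divisible by 3.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param nGenes number of genes to place.
#' @param exonRange,intronRange,utrRange ranges (bp) to draw exon, intron and
#'   UTR lengths from.
#' @return A list with `models` (list of [GeneModel-class]) and `genome`
#'   (the patched [Biostrings::DNAStringSet]).
#' @export
simulateGeneModels <- function(genome, nGenes,
                               exonRange = c(150, 400),
                               intronRange = c(80, 300),
                               utrRange = c(30, 90)) {
  if (nGenes == 0) return(list(models = list(), genome = genome))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  occupied <- lapply(lens, function(x) IRanges::IRanges())
  names(occupied) <- names(genome)
  models <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    placed <- FALSE
    for (try in seq_len(200)) {
      nEx <- sample(2:4, 1)
      exW <- sample(exonRange[1]:exonRange[2], nEx, replace = TRUE)
      inW <- if (nEx > 1) sample(intronRange[1]:intronRange[2], nEx - 1,
                                 replace = TRUE) else integer()
      span <- sum(exW) + sum(inW)
      chr <- sample(names(genome), 1, prob = lens)
      if (lens[[chr]] < span + 200) next
      start <- sample.int(lens[[chr]] - span - 100, 1) + 50L
      gene <- IRanges::IRanges(start, start + span - 1L)
      if (length(IRanges::findOverlaps(
            gene, occupied[[chr]], maxgap = 1000L))) next
      exStarts <- start + cumsum(c(0L, exW[-nEx] + inW))
      exons <- IRanges::IRanges(exStarts, width = exW)
      strand <- sample(c("+", "-"), 1)
      u5 <- sample(utrRange[1]:utrRange[2], 1)
      u3 <- sample(utrRange[1]:utrRange[2], 1)
      cdsLen <- sum(exW) - u5 - u3
      u3 <- u3 + cdsLen %% 3L
      cdsLen <- cdsLen - cdsLen %% 3L
      if (cdsLen < 30) next
      if (strand == "+") {
        cdsSpan <- IRanges::IRanges(start + u5,
                                    start + span - 1L - u3)
      } else {
        cdsSpan <- IRanges::IRanges(start + u3,
                                    start + span - 1L - u5)
      }
      cds <- IRanges::intersect(exons, cdsSpan)
      if (sum(IRanges::width(cds)) %% 3L != 0L) next
      models[[g]] <- GeneModel(sprintf("gene%03d", g), chr, strand,
                               exons, cds)
      occupied[[chr]] <- c(occupied[[chr]], gene)
      placed <- TRUE
      break
    }
    if (!placed)
      .stopf("could not place gene %d without overlap; genome too small", g)
  }
  # patch CDS sequences so each model is complete
  for (m in models) {
    gpos <- .cdsGenomicPositions(m)
    fwd <- as.character(Biostrings::extractAt(
      genome[[m@chrom]], IRanges::IRanges(sort(gpos), width = 1L)))
    txt <- if (m@strand == "+") paste(fwd, collapse = "")
           else .revcomp(paste(fwd, collapse = ""))
    fixed <- .completeCds(txt)
    txBases <- strsplit(fixed, "")[[1]]
    fwdBases <- if (m@strand == "+") txBases
                else rev(unname(.complementBase[txBases]))
    genome[[m@chrom]] <- Biostrings::replaceLetterAt(
      genome[[m@chrom]], sort(gpos), paste(fwdBases, collapse = ""))
  }
  list(models = models, genome = genome)
}

# map per-chrom (chrom, pos) helpers -----------------------------------------

.sampleSpacedSites <- function(genome, n, minSpacing, flankPad = 2L,
                               headroom = 3) {
  lens <- Biostrings::width(genome)
  L <- sum(as.numeric(lens))
  cumEnd <- cumsum(as.numeric(lens))
  cumStart <- cumEnd - as.numeric(lens)
  target <- ceiling(headroom * n)
  got <- NULL
  for (round in 1:6) {
    m <- min(L, max(6L * target * 2^(round - 1), 2000L))
    gpos <- sort(sample.int(L, min(m, L)))
    chrIdx <- findInterval(gpos - 1, cumEnd) + 1L
    pos <- as.integer(gpos - cumStart[chrIdx])
    ok <- pos > flankPad & pos <= lens[chrIdx] - flankPad
    chrIdx <- chrIdx[ok]; pos <- pos[ok]
    keep <- logical(length(pos))
    last <- rep(-Inf, length(lens))
    for (i in seq_along(pos)) {
      if (pos[i] - last[chrIdx[i]] >= minSpacing) {
        keep[i] <- TRUE
        last[chrIdx[i]] <- pos[i]
      }
    }
    cand <- data.frame(chrom = names(genome)[chrIdx[keep]], pos = pos[keep],
                       stringsAsFactors = FALSE)
    # oriented trinucleotide around each site, for base and bias lookups
    tri <- character(nrow(cand))
    for (chr in unique(cand$chrom)) {
      i <- cand$chrom == chr
      tri[i] <- as.character(Biostrings::extractAt(
        genome[[chr]], IRanges::IRanges(cand$pos[i] - 1L, cand$pos[i] + 1L)))
    }
    cand$base <- substr(tri, 2, 2)
    cand$left <- substr(tri, 1, 1)
    cand$right <- substr(tri, 3, 3)
    cand <- cand[!grepl("N", tri, fixed = TRUE), ]
    got <- cand
    if (nrow(cand) >= target) break
  }
  if (nrow(got) < n)
    .stopf("could not place %d variants with %d bp spacing; genome too small",
           n, minSpacing)
  got[sample.int(nrow(got)), ]
}

.spontaneousAlt <- function(ref, pTransition = 0.535) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  out <- character(length(ref))
  isTs <- stats::runif(length(ref)) < pTransition
  out[isTs] <- transition[ref[isTs]]
  for (i in which(!isTs))
    out[i] <- sample(setdiff(c("A", "C", "G", "T"),
                             c(ref[i], transition[[ref[i]]])), 1)
  out
}

.emsAlt <- function(cls, ref) {
  pyr <- c("GC>AT" = "T", "GC>CG" = "G", "GC>TA" = "A",
           "TA>CG" = "C", "TA>AT" = "A", "TA>GC" = "G")[cls]
  # pyr is the alt when ref is the pyrimidine of the class (C or T);
  # complement when ref is the purine
  ifelse(ref %in% c("C", "T"), pyr, unname(.complementBase[pyr]))
}

#' Simulate two-family pooled variant callsets with ground truth
#'
#' Places shared (homozygous and still-segregating) background polymorphisms,
#' family-specific homozygous spontaneous variants, family-specific
#' heterozygous EMS mutations drawn from the configured substitution spectrum
#' with pyrimidine-flank site bias, and clustered artifact variants. Pooled
#' samples are simulated at the genotype level: a segregating mutation is a
#' heterozygous call in every pool of the family, a fixed variant a
#' homozygous one. Per-sample depth tracks are piecewise-constant around the
#' mean depth, with low-depth dropouts (one sample) and high-depth
#' duplication-like intervals (all samples) as default noise.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param params a [simParams()] list.
#' @return A list with `calls` (named list of two [VariantCalls-class]),
#'   `depth` (per family, a list of per-sample [S4Vectors::RleList] tracks),
#'   and `truth` (data.frame ledger: chrom, pos, ref, alt, origin, family,
#'   zygosity).
#' @export
simulateFamilies <- function(genome, params = simParams()) {
  fams <- params$familyIds
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  nTrue <- params$sharedHom + params$sharedSeg +
    sum(params$specificHom) + sum(params$emsPerFamily)
  cand <- .sampleSpacedSites(genome, nTrue, params$minSpacing)

  isGC <- cand$base %in% c("C", "G")
  gcPool <- which(isGC); taPool <- which(!isGC)
  takeRows <- integer(); truth <- list()

  emit <- function(rows, alt, origin, family, zygosity) {
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = cand$chrom[rows], pos = cand$pos[rows],
      ref = cand$base[rows], alt = alt, origin = origin,
      family = family, zygosity = zygosity, stringsAsFactors = FALSE)
  }

  # EMS mutations per family, classes drawn from the spectrum
  clsByFam <- lapply(fams, function(f) {
    nf <- params$emsPerFamily[[f]]
    if (nf == 0) return(character())
    sample(names(params$emsSpectrum), nf, replace = TRUE,
           prob = params$emsSpectrum)
  })
  names(clsByFam) <- fams
  gcClasses <- c("GC>AT", "GC>CG", "GC>TA")
  needGCtot <- sum(unlist(clsByFam) %in% gcClasses)
  needTAtot <- sum(!unlist(clsByFam) %in% gcClasses)
  nSpont <- params$sharedHom + params$sharedSeg + sum(params$specificHom)
  if (needGCtot > length(gcPool) || needTAtot > length(taPool) ||
      needGCtot + needTAtot + nSpont > length(gcPool) + length(taPool))
    .stopf("requested variant counts exceed available well-spaced sites")
  for (f in fams) {
    cls <- clsByFam[[f]]
    if (length(cls) == 0) next
    needGC <- cls %in% gcClasses
    nGcAt <- sum(cls == "GC>AT")
    # pyrimidine-flank weighting for the canonical transitions: the oriented
    # -1/+1 bases are the forward neighbors for a C site, their complements
    # for a G site
    pool <- gcPool
    orientPyr <- ifelse(cand$base[pool] == "C",
                        cand$left[pool] %in% c("C", "T") |
                          cand$right[pool] %in% c("C", "T"),
                        cand$left[pool] %in% c("A", "G") |
                          cand$right[pool] %in% c("A", "G"))
    w <- ifelse(orientPyr, params$contextBias, 1)
    gcat <- pool[sample.int(length(pool), nGcAt, prob = w)]
    gcPool <- setdiff(gcPool, gcat)
    otherGC <- sample(gcPool, sum(needGC) - nGcAt)
    gcPool <- setdiff(gcPool, otherGC)
    ta <- sample(taPool, sum(!needGC))
    taPool <- setdiff(taPool, ta)
    rows <- integer(length(cls))
    rows[cls == "GC>AT"] <- gcat
    rows[needGC & cls != "GC>AT"] <- otherGC
    rows[!needGC] <- ta
    emit(rows, .emsAlt(cls, cand$base[rows]), "ems", f, "het")
    takeRows <- c(takeRows, rows)
  }

  # spontaneous variants from the remaining pool
  rest <- sample(c(gcPool, taPool))
  takeSpont <- function(n) {
    if (n == 0) return(integer())
    r <- rest[seq_len(n)]; rest <<- rest[-seq_len(n)]; r
  }
  r <- takeSpont(params$sharedHom)
  emit(r, .spontaneousAlt(cand$base[r]), "shared_hom", "both", "hom")
  r <- takeSpont(params$sharedSeg)
  emit(r, .spontaneousAlt(cand$base[r]), "shared_seg", "both", "het")
  for (f in fams) {
    r <- takeSpont(params$specificHom[[f]])
    emit(r, .spontaneousAlt(cand$base[r]), "specific_hom", f, "hom")
  }
  truth <- do.call(rbind, truth)

  # clustered artifact variants, per family, far from true variants
  for (f in fams) {
    made <- 0L
    while (made < params$artifactClusters) {
      chr <- sample(names(genome), 1, prob = lens)
      if (lens[[chr]] < 2000) next
      center <- sample.int(lens[[chr]] - 1000L, 1) + 500L
      nearTrue <- any(truth$chrom == chr & abs(truth$pos - center) < 2500)
      if (nearTrue) next
      offs <- sort(sample(-125:125, params$artifactClusterSize))
      pos <- center + offs
      ref <- as.character(Biostrings::extractAt(
        genome[[chr]], IRanges::IRanges(pos, width = 1L)))
      if (any(ref == "N")) next
      truth <- rbind(truth, data.frame(
        chrom = chr, pos = pos, ref = ref, alt = .spontaneousAlt(ref),
        origin = "artifact", family = f, zygosity = "het",
        stringsAsFactors = FALSE))
      made <- made + 1L
    }
  }

  # depth tracks: piecewise-constant chunks with dropout / duplication noise
  chunk <- 2000L
  depth <- list(); chunkVals <- list()
  for (f in fams) {
    sampleIds <- paste0(f, "_S", seq_len(params$nSamples))
    vals <- lapply(sampleIds, function(s) {
      lapply(lens, function(len) {
        nch <- ceiling(len / chunk)
        pmax(0, round(stats::rgamma(nch, shape = params$depthDispersion,
                                    rate = params$depthDispersion /
                                      params$meanDepth)))
      })
    })
    names(vals) <- sampleIds
    for (chr in names(genome)) {
      nch <- ceiling(lens[[chr]] / chunk)
      nLowRuns <- ceiling(params$lowDepthFraction * lens[[chr]] / (3 * chunk))
      nHighRuns <- ceiling(params$highDepthFraction * lens[[chr]] / (2 * chunk))
      if (nLowRuns > 0 && nch > 4) {
        for (k in seq_len(nLowRuns)) {
          at <- sample.int(nch - 3L, 1)
          s <- sample(sampleIds, 1)
          vals[[s]][[chr]][at:(at + 2L)] <- 3
        }
      }
      if (nHighRuns > 0 && nch > 3) {
        for (k in seq_len(nHighRuns)) {
          at <- sample.int(nch - 2L, 1)
          for (s in sampleIds) vals[[s]][[chr]][at:(at + 1L)] <- 150
        }
      }
    }
    chunkVals[[f]] <- vals
    depth[[f]] <- lapply(vals, function(v) {
      rls <- lapply(names(genome), function(chr) {
        len <- lens[[chr]]
        nch <- length(v[[chr]])
        runLen <- rep(chunk, nch)
        runLen[nch] <- len - chunk * (nch - 1L)
        S4Vectors::Rle(v[[chr]], runLen)
      })
      names(rls) <- names(genome)
      methods::as(rls, "RleList")
    })
  }

  # assemble per-family calls
  calls <- list()
  for (f in fams) {
    inFam <- truth$family %in% c(f, "both")
    tf <- truth[inFam, ]
    n <- nrow(tf)
    sampleIds <- paste0(f, "_S", seq_len(params$nSamples))
    gtcat <- ifelse(tf$zygosity == "hom", "hom_alt", "het")
    gt <- matrix(rep(gtcat, params$nSamples), n,
                 dimnames = list(NULL, sampleIds))
    gq <- matrix(pmin(99, pmax(2, round(stats::rnorm(n * params$nSamples,
                                                     params$gqMean,
                                                     params$gqSd)))),
                 n, dimnames = list(NULL, sampleIds))
    lowGq <- stats::runif(length(gq)) < params$lowGqRate
    gq[lowGq] <- sample(5:20, sum(lowGq), replace = TRUE)
    dp <- matrix(0, n, params$nSamples, dimnames = list(NULL, sampleIds))
    chIdx <- (tf$pos - 1L) %/% chunk + 1L
    for (s in sampleIds)
      dp[, s] <- vapply(seq_len(n), function(i)
        chunkVals[[f]][[s]][[tf$chrom[i]]][chIdx[i]], 0)
    calls[[f]] <- VariantCalls(tf$chrom, tf$pos, tf$ref, tf$alt,
                               gt = gt, gq = gq, dp = dp)
  }
  list(calls = calls, depth = depth, truth = truth)
}

#' Simulate a complete two-family dataset
#'
#' Orchestrates [simulateGenome()], [simulateGeneModels()] and
#' [simulateFamilies()] under a single seed; identical parameters and seed
#' give identical output.
#'
#' @param params a [simParams()] list.
#' @param seed integer seed fixing all randomness.
#' @return list with `genome`, `models`, `calls`, `depth`, `truth`, `params`.
#' @export
simulateDataset <- function(params = simParams(), seed = 1L) {
  set.seed(seed)
  genome <- simulateGenome(params$genomeLength, params$nChromosomes,
                           params$gcContent)
  gm <- simulateGeneModels(genome, params$nGenes)
  fam <- simulateFamilies(gm$genome, params)
  c(list(genome = gm$genome, models = gm$models, params = params,
         seed = seed), fam)
}

#' Write a simulated dataset to standard formats
#'
#' Writes `ref.fa`, `genes.gff3`, one VCF per family, one BedGraph per
#' sample, and `truth.tsv` into `dir`.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenome(sim$genome, file.path(dir, "ref.fa"))
  if (length(sim$models))
    writeGeneModels(sim$models, file.path(dir, "genes.gff3"))
  for (f in names(sim$calls)) {
    writeVcfCalls(sim$calls[[f]], file.path(dir, paste0(f, ".vcf")))
    for (s in names(sim$depth[[f]]))
      writeDepthTrack(sim$depth[[f]][[s]],
                      file.path(dir, paste0(s, ".depth.bedgraph")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Compare recovered EMS calls with the simulation ledger
#'
#' @param classified a [ClassifiedCallset-class] from the pipeline.
#' @param truth the `truth` ledger of [simulateFamilies()].
#' @return data.frame per family with `nTruth`, `nRecovered`, `precision`,
#'   `recall` and `gcAtShare` (fraction of recovered EMS calls in the GC>AT
#'   class).
#' @export
evaluateRecovery <- function(classified, truth) {
  fams <- familyIds(classified)
  rows <- lapply(fams, function(f) {
    tt <- truth[truth$origin == "ems" & truth$family == f, ]
    truthKeys <- paste0(tt$chrom, ":", tt$pos, ":", tt$ref, ">", tt$alt)
    rec <- variantKeys(emsCalls(classified, f))
    tp <- length(intersect(rec, truthKeys))
    spec <- mutationSpectrum(emsCalls(classified, f))
    data.frame(family = f, nTruth = length(truthKeys),
               nRecovered = length(rec),
               precision = if (length(rec)) tp / length(rec) else NA_real_,
               recall = if (length(truthKeys)) tp / length(truthKeys)
                        else NA_real_,
               gcAtShare = spec$counts[["GC>AT"]] / spec$nSnv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
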