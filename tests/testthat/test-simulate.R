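test_that("simulated genomes honor GC content, boundaries and the seed", {
  set.seed(8)
  g <- simulateGenome(1e6, 2, 0.5)
  freq <- Biostrings::alphabetFrequency(g, collapse = TRUE)
  gc <- (freq[["G"]] + freq[["C"]]) / 1e6
  expect_lt(abs(gc - 0.5), 0.002)
  expect_equal(sum(Biostrings::width(g)), 1e6)

  set.seed(8)
  g2 <- simulateGenome(1e6, 2, 0.5)
  expect_identical(as.character(g), as.character(g2))

  set.seed(8)
  gAll <- simulateGenome(1e4, 1, 1.0)
  f <- Biostrings::alphabetFrequency(gAll, collapse = TRUE)
  expect_equal(f[["A"]] + f[["T"]], 0L)
  expect_error(simulateGenome(1e4, 1, 1.5), "gcContent")
})

test_that("simulated gene models are complete and survive GFF3 round trips", {
  set.seed(21)
  g <- simulateGenome(3e5, 1, 0.4)
  sm <- simulateGeneModels(g, 25)
  expect_equal(length(sm$models), 25L)
  expect_identical(simulateGeneModels(g, 0)$models, list())
  strands <- vapply(sm$models, function(m) m@strand, "")
  expect_setequal(unique(strands), c("+", "-"))
  for (m in sm$models) {
    expect_true(validObject(m))           # exon/CDS invariants
    # the patched genome carries a translatable CDS: ATG ... stop, no
    # internal stop
    gpos <- sort(unlist(lapply(seq_along(m@cds), function(i)
      IRanges::start(m@cds)[i]:IRanges::end(m@cds)[i])))
    s <- paste(vapply(gpos, function(p)
      as.character(Biostrings::subseq(sm$genome[[m@chrom]], p, p)), ""),
      collapse = "")
    if (m@strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(s, 1, 3), "ATG")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  f <- tempfile(fileext = ".gff3")
  writeGeneModels(sm$models, f)
  back <- readGeneModels(f)
  expect_equal(length(back), 25L)
  ids <- vapply(back, function(m) m@geneId, "")
  for (m in sm$models) {
    b <- back[[match(m@geneId, ids)]]
    expect_equal(b@exons, m@exons)
    expect_equal(b@cds, m@cds)
    expect_equal(b@strand, m@strand)
  }
})

test_that("family simulation is deterministic and matches its own ledger", {
  sim1 <- smallSim(seed = 5)
  sim2 <- smallSim(seed = 5)
  expect_identical(as.character(sim1$genome), as.character(sim2$genome))
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(genotypes(sim1$calls$L1), genotypes(sim2$calls$L1))
  expect_identical(as.numeric(sim1$depth$L1[[1]][[1]]),
                   as.numeric(sim2$depth$L1[[1]][[1]]))

  # every EMS ledger entry is family-specific and heterozygous by construction
  tt <- sim1$truth
  ems <- tt[tt$origin == "ems", ]
  expect_true(all(ems$zygosity == "het"))
  expect_true(all(ems$family %in% c("L1", "L2")))
  key <- paste(tt$chrom, tt$pos)
  expect_false(any(duplicated(key)))
  # true (non-artifact) variants respect the hard minimum spacing
  true <- tt[tt$origin != "artifact", ]
  for (chr in unique(true$chrom)) {
    p <- sort(true$pos[true$chrom == chr])
    if (length(p) > 1) expect_gte(min(diff(p)), 1001)
  }
})

test_that("ledger spectrum follows the configured class probabilities", {
  p <- simParams(genomeLength = 8e6, nChromosomes = 2, nGenes = 0,
                 sharedHom = 50, sharedSeg = 20,
                 specificHom = c(L1 = 10, L2 = 10),
                 emsPerFamily = c(L1 = 1000, L2 = 1000))
  sim <- simulateDataset(p, seed = 3)
  ems <- sim$truth[sim$truth$origin == "ems", ]
  cls <- substitutionClass(ems$ref, ems$alt)
  share <- as.numeric(table(factor(cls, levels = names(p$emsSpectrum)))) /
    nrow(ems)
  # each share within ~3.5 multinomial standard errors of its probability
  se <- sqrt(p$emsSpectrum * (1 - p$emsSpectrum) / nrow(ems))
  expect_true(all(abs(share - p$emsSpectrum) < 3.5 * se + 1e-9))
})

test_that("zero EMS mutations yield empty classifier EMS sets", {
  p <- simParams(genomeLength = 1e6, nChromosomes = 1, nGenes = 0,
                 sharedHom = 20, sharedSeg = 5,
                 specificHom = c(L1 = 5, L2 = 5),
                 emsPerFamily = c(L1 = 0, L2 = 0),
                 artifactClusters = 0)
  sim <- simulateDataset(p, seed = 2)
  cl <- classifyVariants(lapply(sim$calls, gqFilter))
  expect_equal(length(emsCalls(cl, "L1")), 0L)
  expect_equal(length(emsCalls(cl, "L2")), 0L)
})

test_that("clustered artifacts are fully removed by the window filter", {
  sim <- smallSim(seed = 13)
  res <- runPipeline(sim$calls, sim$depth)
  art <- sim$truth[sim$truth$origin == "artifact", ]
  artKeys <- paste0(art$chrom, ":", art$pos, ":", art$ref, ">", art$alt)
  surviving <- unlist(lapply(familyIds(res$classified), function(f)
    c(variantKeys(sharedCalls(res$classified, f)),
      variantKeys(specificHomCalls(res$classified, f)),
      variantKeys(emsCalls(res$classified, f)))))
  expect_length(intersect(artKeys, surviving), 0)
  # and they really were present before filtering
  expect_true(all(artKeys[art$family == "L1"] %in%
                    variantKeys(sim$calls$L1)))
})

test_that("simulation output files round-trip through the standard formats", {
  p <- simParams(genomeLength = 4e5, nChromosomes = 1, nGenes = 5,
                 sharedHom = 10, sharedSeg = 4,
                 specificHom = c(L1 = 3, L2 = 2),
                 emsPerFamily = c(L1 = 8, L2 = 6),
                 artifactClusters = 1)
  sim <- simulateDataset(p, seed = 9)
  dir <- tempfile()
  writeSimulation(sim, dir)
  g <- readGenome(file.path(dir, "ref.fa"))
  expect_identical(as.character(g), as.character(sim$genome))
  l1 <- readVcfCalls(file.path(dir, "L1.vcf"))
  expect_equal(variantKeys(l1), variantKeys(sim$calls$L1))
  expect_equal(genotypes(l1), genotypes(sim$calls$L1), ignore_attr = TRUE)
  tr <- readDepthTrack(file.path(dir, "L1_S1.depth.bedgraph"),
                       seqlengths = c(chr1 = 4e5))
  expect_identical(as.numeric(tr[[1]]), as.numeric(sim$depth$L1$L1_S1[[1]]))
  models <- readGeneModels(file.path(dir, "genes.gff3"))
  expect_equal(length(models), 5L)
})
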