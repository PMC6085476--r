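# one-gene fixture with a designed coding sequence:
# pad(10) + exon1 [11,25] + intron [26,45] + exon2 [46,75] + pad
# CDS spans both exons: 15 + 30 = 45 bp = 15 codons
annoFixture <- function() {
  cds1 <- "ATGCAACTGGACGAA"                       # M  Q  L  D  E
  cds2 <- "GGTATCGATGAGCATCTTCCAGCGTGGTAA"        # 10 codons ending in stop
  intron <- paste0("GT", strrep("A", 16), "AG")   # canonical donor/acceptor
  seq <- paste0(strrep("T", 10), cds1, intron, cds2, strrep("T", 20000))
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  gm <- GeneModel("g1", "chr1", "+",
                  exons = IRanges(c(11, 46), c(25, 75)),
                  cds = IRanges(c(11, 46), c(25, 75)))
  list(genome = genome, gm = gm)
}

test_that("codon-level consequences match hand-derived examples", {
  fx <- annoFixture()
  # codon 2 is CAA (Gln); C>T at its first base (pos 14) makes TAA = stop
  rec <- annotateVariants(makeCalls("chr1", 14, "C", "T"), list(fx$gm),
                          fx$genome)
  expect_equal(rec$location, "exon")
  expect_equal(rec$proteinChange, "nonsense")
  expect_equal(rec$detail, "stop_gained")
  expect_equal(rec$impact, "HIGH")
  # codon 3 is CTG (Leu); C>T at pos 17 makes TTG = Leu: silent
  rec <- annotateVariants(makeCalls("chr1", 17, "C", "T"), list(fx$gm),
                          fx$genome)
  expect_equal(rec$proteinChange, "silent")
  expect_equal(rec$impact, "LOW")
  # codon 4 GAC -> AAC (Asp -> Asn): missense, MODERATE
  rec <- annotateVariants(makeCalls("chr1", 20, "G", "A"), list(fx$gm),
                          fx$genome)
  expect_equal(rec$proteinChange, "missense")
  expect_equal(rec$impact, "MODERATE")
})

test_that("splice, intron, upstream and intergenic classes follow position", {
  fx <- annoFixture()
  ann <- function(pos, ref, alt = "A")
    annotateVariants(makeCalls("chr1", pos, ref, alt), list(fx$gm), fx$genome)
  # first intron base: the G of the GT donor
  rec <- ann(26, "G")
  expect_equal(rec$location, "splice_site")
  expect_equal(rec$detail, "splice_donor")
  expect_equal(rec$impact, "HIGH")
  # last intron base: acceptor core
  rec <- ann(45, "G", "C")
  expect_equal(rec$detail, "splice_acceptor")
  expect_equal(rec$impact, "HIGH")
  # intronic base 4 from the donor: splice region, LOW
  rec <- ann(29, "A", "G")
  expect_equal(rec$location, "splice_site")
  expect_equal(rec$detail, "splice_region")
  expect_equal(rec$impact, "LOW")
  # mid-intron: plain intron, MODIFIER
  rec <- ann(35, "A", "G")
  expect_equal(rec$location, "intron")
  expect_equal(rec$impact, "MODIFIER")
  # 100 bp 5' of a plus-strand gene: upstream; far away: intergenic
  expect_equal(ann(5, "T")$location, "upstream")
  expect_equal(ann(76 + 200, "T")$location, "downstream")
  rec <- ann(76 + 15000, "T")
  expect_equal(rec$location, "intergenic")
  expect_equal(rec$impact, "MODIFIER")
  # disagreement between VCF ref and genome is an error naming the position
  expect_error(ann(14, "G"), "chr1:14")
})

test_that("coding calls agree with the CDS-rebuild translation oracle", {
  set.seed(91)
  g <- simulateGenome(8e5, 2, 0.42)
  sm <- simulateGeneModels(g, 60)
  genome <- sm$genome
  checked <- 0L
  for (gm in sm$models) {
    chars <- strsplit(as.character(genome[[gm@chrom]]), "")[[1]]
    cdsPos <- unlist(lapply(seq_along(gm@cds), function(i)
      IRanges::start(gm@cds)[i]:IRanges::end(gm@cds)[i]))
    for (pos in sample(cdsPos, 17)) {
      ref <- chars[pos]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      rec <- annotateVariants(makeCalls(gm@chrom, pos, ref, alt), list(gm),
                              genome)
      rec <- rec[rec$geneId == gm@geneId & rec$location == "exon", ]
      expect_equal(rec$proteinChange,
                   oracleCodingChange(gm, pos, ref, alt, genome),
                   label = sprintf("%s %s:%d %s>%s (%s strand)", gm@geneId,
                                   gm@chrom, pos, ref, alt, gm@strand))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 1000L)
  expect_true(any(vapply(sm$models, function(m) m@strand == "-", TRUE)))
})

test_that("impact tier is a pure function of the detail class", {
  expect_equal(impactTier(c("stop_gained", "splice_donor", "splice_acceptor",
                            "frameshift", "stop_lost", "start_lost")),
               rep("HIGH", 6))
  expect_equal(impactTier(c("missense", "inframe_indel")),
               rep("MODERATE", 2))
  expect_equal(impactTier(c("silent", "splice_region")), rep("LOW", 2))
  expect_equal(impactTier(c("intron", "five_prime_UTR", "three_prime_UTR",
                            "upstream", "downstream", "intergenic")),
               rep("MODIFIER", 6))
  expect_error(impactTier("mystery"), "unknown")
})

test_that("annotation summaries use the documented denominators", {
  one <- data.frame(key = "k", chrom = "chr1", pos = 1, ref = "C", alt = "T",
                    geneId = NA, location = "intergenic",
                    proteinChange = "not_applicable", impact = "MODIFIER",
                    detail = "intergenic", note = "")
  s <- summarizeAnnotations(one)
  expect_equal(s$location$percent[s$location$category == "intergenic"], 100)
  expect_equal(s$impact$percent[s$impact$category == "MODIFIER"], 100)

  cnt <- annotationSummaryFromCounts(
    location = c(exon = 422, intron = 645, splice_site = 29,
                 intergenic = 1369, UTR = 142, up_downstream = 3192),
    proteinChange = c(missense = 281, nonsense = 11, silent = 130),
    impact = c(LOW = 157, MODERATE = 281, MODIFIER = 3973, HIGH = 19))
  loc <- cnt$location
  expect_equal(loc$percent[loc$category == "exon"], 7.3)
  expect_equal(loc$percent[loc$category == "intron"], 11.1)
  expect_equal(cnt$proteinChange$percent[1], 66.6)
  expect_equal(cnt$impact$percent[cnt$impact$category == "HIGH"], 0.4)
})

test_that("frameshift and in-frame indels in CDS get the right tier", {
  fx <- annoFixture()
  rec <- annotateVariants(makeCalls("chr1", 14, "CA", "C"), list(fx$gm),
                          fx$genome)
  expect_equal(rec$detail, "frameshift")
  expect_equal(rec$impact, "HIGH")
  rec <- annotateVariants(makeCalls("chr1", 14, "CAAC", "C"), list(fx$gm),
                          fx$genome)
  expect_equal(rec$detail, "inframe_indel")
  expect_equal(rec$impact, "MODERATE")
})
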