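# in-code fixtures and independent oracles shared across test files

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(S4Vectors)
})

# quick VariantCalls builder: gt is a character vector (one sample) or matrix
makeCalls <- function(chrom, pos, ref, alt, gt = "het", gq = 60, dp = 30) {
  n <- length(pos)
  if (!is.matrix(gt)) gt <- matrix(rep(gt, length.out = n), n, 1)
  ns <- ncol(gt)
  if (!is.matrix(gq)) gq <- matrix(rep(gq, length.out = n * ns), n, ns)
  if (!is.matrix(dp)) dp <- matrix(rep(dp, length.out = n * ns), n, ns)
  colnames(gt) <- paste0("S", seq_len(ns))
  VariantCalls(rep(chrom, length.out = n), pos,
               rep(ref, length.out = n), rep(alt, length.out = n),
               gt = gt, gq = gq, dp = dp)
}

# per-base membership mask of a GRanges on a single chromosome
regionMask <- function(gr, chrom, len) {
  m <- logical(len)
  gr <- gr[as.character(seqnames(gr)) == chrom]
  for (i in seq_along(gr)) m[start(gr)[i]:end(gr)[i]] <- TRUE
  m
}

# brute-force window-filter oracle: per-base mask of all discarded windows
bruteDiscardMask <- function(positions, len, window = 1000, step = 500,
                             maxPer = 1) {
  m <- logical(len)
  starts <- seq(1, len, by = step)
  for (s in starts) {
    e <- min(s + window - 1, len)
    if (sum(positions >= s & positions <= e) > maxPer) m[s:e] <- TRUE
  }
  m
}

# independent coding-consequence oracle: rebuild the whole CDS, substitute
# the base, translate both sequences with Biostrings and diff them
oracleCodingChange <- function(gm, pos, ref, alt, genome) {
  cds <- gm@cds
  segs <- lapply(seq_along(cds), function(i)
    as.character(subseq(genome[[gm@chrom]], start(cds)[i], end(cds)[i])))
  cdsSeq <- paste(unlist(segs), collapse = "")
  # genomic offset of pos within the concatenated forward-strand CDS
  off <- 0L; hit <- NA
  for (i in seq_along(cds)) {
    if (pos >= start(cds)[i] && pos <= end(cds)[i]) {
      hit <- off + (pos - start(cds)[i] + 1L); break
    }
    off <- off + width(cds)[i]
  }
  stopifnot(!is.na(hit), substr(cdsSeq, hit, hit) == ref)
  altSeq <- cdsSeq
  substr(altSeq, hit, hit) <- alt
  if (gm@strand == "-") {
    cdsSeq <- as.character(reverseComplement(DNAString(cdsSeq)))
    altSeq <- as.character(reverseComplement(DNAString(altSeq)))
  }
  # literal codon-table translation (no initiator-codon special casing)
  aaRef <- as.character(translate(DNAString(cdsSeq), no.init.codon = TRUE))
  aaAlt <- as.character(translate(DNAString(altSeq), no.init.codon = TRUE))
  d <- which(strsplit(aaRef, "")[[1]] != strsplit(aaAlt, "")[[1]])
  if (length(d) == 0) return("silent")
  a <- substr(aaAlt, d[1], d[1])
  r <- substr(aaRef, d[1], d[1])
  if (a == "*") "nonsense" else if (r == "*") "nonsense" else "missense"
}

# a deterministic small two-family dataset for pipeline-level tests
smallSim <- function(seed = 11) {
  p <- simParams(genomeLength = 2e6, nChromosomes = 2, nGenes = 40,
                 sharedHom = 44, sharedSeg = 12,
                 specificHom = c(L1 = 7, L2 = 5),
                 emsPerFamily = c(L1 = 24, L2 = 12))
  simulateDataset(p, seed = seed)
}
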