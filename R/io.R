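#' Read variant calls from a VCF file
#'
#' Reads a VCF 4.x file with `GT`, `GQ` and `DP` FORMAT fields and returns a
#' [VariantCalls-class] object. Multi-allelic records are split into one
#' record per ALT allele; for each allele a sample genotype is categorized as
#' `hom_alt` (both called alleles equal the ALT), `het` (one does), `hom_ref`
#' (none does) or `missing` (uncalled genotype).
#'
#' @param path path to a VCF file (plain text).
#' @return A [VariantCalls-class] object.
#' @export
readVcfCalls <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  g <- VariantAnnotation::geno(vcf)
  for (fld in c("GT", "GQ", "DP"))
    if (!fld %in% names(g))
      .stopf("VCF %s lacks required FORMAT field %s", path, fld)
  rr <- SummarizedExperiment::rowRanges(vcf)
  altl <- VariantAnnotation::alt(vcf)
  nalt <- lengths(altl)
  idx <- rep(seq_along(nalt), nalt)           # original record per output row
  aidx <- unlist(lapply(nalt, seq_len))       # ALT allele index per row
  gtRaw <- g$GT[idx, , drop = FALSE]
  samples <- colnames(g$GT)

  cat_one <- function(gtstr, a) {
    if (is.na(gtstr) || gtstr %in% c(".", "./.", ".|."))
      return("missing")
    al <- strsplit(gtstr, "[/|]")[[1]]
    if (any(al == ".")) return("missing")
    nhit <- sum(al == as.character(a))
    if (nhit == length(al)) "hom_alt" else if (nhit >= 1) "het" else "hom_ref"
  }
  gt <- matrix("missing", nrow(gtRaw), ncol(gtRaw),
               dimnames = list(NULL, samples))
  for (j in seq_along(samples))
    gt[, j] <- mapply(cat_one, gtRaw[, j], aidx)

  gq <- matrix(as.numeric(g$GQ[idx, , drop = FALSE]), nrow = length(idx),
               dimnames = list(NULL, samples))
  dp <- matrix(as.numeric(g$DP[idx, , drop = FALSE]), nrow = length(idx),
               dimnames = list(NULL, samples))
  VariantCalls(
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = GenomicRanges::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = as.character(unlist(altl)),
    gt = gt, gq = gq, dp = dp, samples = samples)
}

#' Write variant calls to a VCF file
#'
#' Inverse of [readVcfCalls()]: genotype categories are written back as
#' `0/0`, `0/1`, `1/1` or `./.` with one VCF record per variant allele, so a
#' read/write/read cycle preserves the in-memory representation.
#'
#' @param calls a [VariantCalls-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfCalls <- function(calls, path) {
  gtMap <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  samples <- sampleNames(calls)
  n <- length(calls)
  gt <- matrix(gtMap[genotypes(calls)], n, length(samples),
               dimnames = list(NULL, samples))
  gq <- matrix(as.integer(round(genotypeQuals(calls))), n,
               dimnames = list(NULL, samples))
  dp <- matrix(as.integer(round(readDepths(calls))), n,
               dimnames = list(NULL, samples))
  hdr <- VariantAnnotation::VCFHeader(
    samples = samples,
    header = IRanges::DataFrameList(
      fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"),
      FORMAT = DataFrame(
        Number = c("1", "1", "1"),
        Type = c("String", "Integer", "Integer"),
        Description = c("Genotype", "Genotype Quality", "Read Depth"),
        row.names = c("GT", "GQ", "DP"))))
  vcf <- VariantAnnotation::VCF(
    rowRanges = GRanges(variantChrom(calls),
                        IRanges(variantPos(calls), width = 1L)),
    fixed = DataFrame(
      REF = Biostrings::DNAStringSet(refAllele(calls)),
      ALT = Biostrings::DNAStringSetList(as.list(altAllele(calls))),
      QUAL = rep(NA_real_, n), FILTER = rep(".", n)),
    geno = SimpleList(GT = gt, GQ = gq, DP = dp),
    colData = DataFrame(row.names = samples),
    exptData = list(header = hdr))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet], uppercased; only A/C/G/T/N
#'   bases are accepted.
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- vapply(strsplit(names(g), "\\s+"), `[`, "", 1)
  if (anyDuplicated(names(g)))
    .stopf("duplicate chromosome names in %s", path)
  g <- Biostrings::DNAStringSet(toupper(g))
  freq <- Biostrings::alphabetFrequency(g, collapse = TRUE)
  other <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (other > 0)
    .stopf("%s contains %d bases outside A/C/G/T/N", path, other)
  g
}

#' @rdname readGenome
#' @param genome a named [Biostrings::DNAStringSet].
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a per-base depth track from BedGraph
#'
#' BedGraph intervals are 0-based half-open on disk; rtracklayer converts
#' them to 1-based closed ranges. Positions not covered by any interval get
#' depth 0. Overlapping intervals are rejected.
#'
#' @param path BedGraph file.
#' @param seqlengths optional named integer vector of chromosome lengths; the
#'   returned coverage is padded with zeros to these lengths.
#' @return An [S4Vectors::RleList] of per-base depths, one element per
#'   chromosome.
#' @export
readDepthTrack <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    .stopf("overlapping intervals in depth track %s", path)
  if (any(gr$score < 0))
    .stopf("negative depth in %s", path)
  if (is.null(seqlengths)) {
    GenomicRanges::coverage(gr, weight = gr$score)
  } else {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomicRanges::coverage(gr, weight = gr$score, width = as.list(seqlengths))
  }
}

#' @rdname readDepthTrack
#' @param track an [S4Vectors::RleList] of per-base depths.
#' @export
writeDepthTrack <- function(track, path) {
  gr <- as(track, "GRanges")
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read/write region sets as BED
#'
#' @param path BED file (0-based half-open on disk).
#' @return `readRegionsBed` returns a merged [GenomicRanges::GRanges].
#' @export
readRegionsBed <- function(path) {
  GenomicRanges::reduce(rtracklayer::import(path, format = "bed"))
}

#' @rdname readRegionsBed
#' @param regions a [GenomicRanges::GRanges].
#' @export
writeRegionsBed <- function(regions, path) {
  rtracklayer::export(regions, path, format = "bed")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds one [GeneModel-class] per `mRNA` feature from its child `exon` and
#' `CDS` features. GFF3 coordinates are 1-based inclusive, matching the
#' internal convention. A CDS falling outside the exons, or a CDS whose total
#' length is not divisible by 3, raises an error naming the gene.
#'
#' @param path GFF3 file.
#' @return A list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  out <- vector("list", length(mrna))
  for (i in seq_along(mrna)) {
    id <- mrna$ID[i]
    kids <- !is.na(parent) & parent == id
    ex <- gr[kids & typ == "exon"]
    cds <- gr[kids & typ == "CDS"]
    u5 <- gr[kids & typ == "five_prime_UTR"]
    u3 <- gr[kids & typ == "three_prime_UTR"]
    out[[i]] <- GeneModel(
      geneId = id,
      chrom = as.character(GenomicRanges::seqnames(mrna))[i],
      strand = as.character(GenomicRanges::strand(mrna))[i],
      exons = IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex)),
      cds = IRanges(GenomicRanges::start(cds), GenomicRanges::end(cds)),
      utr5 = if (length(u5)) IRanges(GenomicRanges::start(u5),
                                     GenomicRanges::end(u5)) else NULL,
      utr3 = if (length(u3)) IRanges(GenomicRanges::start(u3),
                                     GenomicRanges::end(u3)) else NULL)
  }
  out
}

#' @rdname readGeneModels
#' @param models list of [GeneModel-class] objects.
#' @export
writeGeneModels <- function(models, path) {
  rows <- lapply(models, function(m) {
    gid <- paste0(m@geneId, ".gene")
    b <- geneBounds(m)
    feats <- list(
      data.frame(start = IRanges::start(b), end = IRanges::end(b),
                 type = "gene", ID = gid, Parent = NA, phase = NA),
      data.frame(start = IRanges::start(b), end = IRanges::end(b),
                 type = "mRNA", ID = m@geneId, Parent = gid, phase = NA),
      data.frame(start = IRanges::start(m@exons), end = IRanges::end(m@exons),
                 type = "exon", ID = NA, Parent = m@geneId, phase = NA))
    if (length(m@cds)) {
      # GFF3 phase: bases to skip at segment start, in transcript order
      w <- IRanges::width(m@cds)
      ord <- if (m@strand == "+") seq_along(w) else rev(seq_along(w))
      before <- cumsum(c(0, w[ord]))[seq_along(w)]
      phase <- (3L - before %% 3L) %% 3L
      ph <- integer(length(w)); ph[ord] <- phase
      feats <- c(feats, list(
        data.frame(start = IRanges::start(m@cds), end = IRanges::end(m@cds),
                   type = "CDS", ID = NA, Parent = m@geneId, phase = ph)))
    }
    for (ut in c("utr5", "utr3")) {
      ir <- slot(m, ut)
      if (length(ir))
        feats <- c(feats, list(data.frame(
          start = IRanges::start(ir), end = IRanges::end(ir),
          type = if (ut == "utr5") "five_prime_UTR" else "three_prime_UTR",
          ID = NA, Parent = m@geneId, phase = NA)))
    }
    df <- do.call(rbind, feats)
    df$chrom <- m@chrom
    df$strand <- m@strand
    df
  })
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                type = df$type, ID = df$ID, phase = as.integer(df$phase))
  gr$Parent <- IRanges::CharacterList(lapply(df$Parent, function(p)
    if (is.na(p)) character() else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
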