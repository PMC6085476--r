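.IMPACT_OF_DETAIL <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  splice_donor = "HIGH", splice_acceptor = "HIGH", frameshift = "HIGH",
  missense = "MODERATE", inframe_indel = "MODERATE",
  silent = "LOW", splice_region = "LOW",
  intron = "MODIFIER", five_prime_UTR = "MODIFIER",
  three_prime_UTR = "MODIFIER", upstream = "MODIFIER",
  downstream = "MODIFIER", intergenic = "MODIFIER")

#' Impact tier of a consequence detail class
#'
#' Pure lookup from the detail consequence (e.g. `stop_gained`,
#' `splice_donor`, `missense`, `silent`, `intron`) to the
#' HIGH/MODERATE/LOW/MODIFIER tier.
#'
#' @param detail character vector of detail classes.
#' @return Character vector of impact tiers.
#' @export
impactTier <- function(detail) {
  out <- .IMPACT_OF_DETAIL[detail]
  if (anyNA(out)) .stopf("unknown consequence detail '%s'",
                         detail[is.na(out)][1])
  unname(out)
}

# CDS genomic positions of a gene model in transcript (5'->3') order
.cdsGenomicPositions <- function(gm) {
  segs <- gm@cds
  if (gm@strand == "+") {
    unlist(lapply(seq_along(segs), function(i)
      IRanges::start(segs)[i]:IRanges::end(segs)[i]))
  } else {
    unlist(lapply(rev(seq_along(segs)), function(i)
      IRanges::end(segs)[i]:IRanges::start(segs)[i]))
  }
}

# coding change for a SNV at genomic position pos with given ref/alt
.codingChange <- function(gm, pos, ref, alt, genome) {
  gpos <- .cdsGenomicPositions(gm)
  cpos <- match(pos, gpos)
  codonIdx <- (cpos - 1L) %/% 3L
  inCodon <- (cpos - 1L) %% 3L + 1L
  codonG <- gpos[codonIdx * 3L + 1:3]
  seqChr <- genome[[gm@chrom]]
  bases <- as.character(Biostrings::extractAt(
    seqChr, IRanges::IRanges(codonG, width = 1L)))
  if (gm@strand == "-") bases <- .complementBase[bases]
  refT <- if (gm@strand == "-") .complementBase[[ref]] else ref
  altT <- if (gm@strand == "-") .complementBase[[alt]] else alt
  if (bases[inCodon] != refT)
    .stopf("reference allele %s disagrees with genome at %s:%d",
           ref, gm@chrom, pos)
  refCodon <- paste(bases, collapse = "")
  altBases <- bases; altBases[inCodon] <- altT
  altCodon <- paste(altBases, collapse = "")
  aaRef <- Biostrings::GENETIC_CODE[[refCodon]]
  aaAlt <- Biostrings::GENETIC_CODE[[altCodon]]
  detail <- if (aaRef == aaAlt) "silent"
    else if (aaAlt == "*") "stop_gained"
    else if (aaRef == "*") "stop_lost"
    else if (codonIdx == 0L) "start_lost"
    else "missense"
  proteinChange <- switch(detail,
    silent = "silent", stop_gained = "nonsense", stop_lost = "nonsense",
    start_lost = "missense", missense = "missense")
  list(detail = detail, proteinChange = proteinChange,
       note = sprintf("codon %d %s>%s p.%s%d%s", codonIdx + 1L,
                      refCodon, altCodon, aaRef, codonIdx + 1L, aaAlt))
}

# splice classification of an intronic position; introns are the gaps
# between consecutive exons. Returns NULL when pos is not intronic.
.introns <- function(gm) {
  ex <- gm@exons
  if (length(ex) < 2) return(IRanges::IRanges())
  IRanges::IRanges(IRanges::end(ex)[-length(ex)] + 1L,
                   IRanges::start(ex)[-1] - 1L)
}

.annotateOneGene <- function(gm, pos, ref, alt, genome, spliceCore,
                             spliceRegionIntron, spliceRegionExon) {
  isSnvRec <- nchar(ref) == 1L && nchar(alt) == 1L
  introns <- .introns(gm)
  inIntron <- which(pos >= IRanges::start(introns) &
                    pos <= IRanges::end(introns))
  if (length(inIntron)) {
    i <- inIntron[1]
    s <- IRanges::start(introns)[i]; e <- IRanges::end(introns)[i]
    dLeft <- pos - s; dRight <- e - pos   # 0-based distance into the intron
    # transcriptionally, the donor side abuts the upstream exon
    donorLeft <- gm@strand == "+"
    if (dLeft < spliceCore)
      return(list(location = "splice_site",
                  detail = if (donorLeft) "splice_donor" else "splice_acceptor"))
    if (dRight < spliceCore)
      return(list(location = "splice_site",
                  detail = if (donorLeft) "splice_acceptor" else "splice_donor"))
    if ((dLeft + 1L) >= spliceRegionIntron[1] &&
        (dLeft + 1L) <= spliceRegionIntron[2])
      return(list(location = "splice_site", detail = "splice_region"))
    if ((dRight + 1L) >= spliceRegionIntron[1] &&
        (dRight + 1L) <= spliceRegionIntron[2])
      return(list(location = "splice_site", detail = "splice_region"))
    return(list(location = "intron", detail = "intron"))
  }
  # exonic
  ex <- gm@exons
  exIdx <- which(pos >= IRanges::start(ex) & pos <= IRanges::end(ex))
  if (length(exIdx)) {
    inCds <- length(gm@cds) &&
      any(pos >= IRanges::start(gm@cds) & pos <= IRanges::end(gm@cds))
    if (inCds) {
      if (isSnvRec) {
        cc <- .codingChange(gm, pos, ref, alt, genome)
        return(list(location = "exon", detail = cc$detail,
                    proteinChange = cc$proteinChange, note = cc$note))
      }
      # indel in CDS: frame test on length difference
      d <- abs(nchar(ref) - nchar(alt))
      return(list(location = "exon",
                  detail = if (d %% 3L != 0L) "frameshift" else "inframe_indel"))
    }
    # non-coding exon base: exonic splice-region margin, then UTR
    i <- exIdx[1]
    nearIntronLeft <- i > 1L &&
      (pos - IRanges::start(ex)[i]) < spliceRegionExon
    nearIntronRight <- i < length(ex) &&
      (IRanges::end(ex)[i] - pos) < spliceRegionExon
    if (nearIntronLeft || nearIntronRight)
      return(list(location = "splice_site", detail = "splice_region"))
    if (any(pos >= IRanges::start(gm@utr5) & pos <= IRanges::end(gm@utr5)))
      return(list(location = "five_prime_UTR", detail = "five_prime_UTR"))
    return(list(location = "three_prime_UTR", detail = "three_prime_UTR"))
  }
  NULL
}

#' Annotate variants against gene models
#'
#' Lightweight consequence annotation in the style of SnpEff: each variant is
#' located relative to every nearby gene model, yielding one record per
#' (variant, gene) pair — so a variant close to two genes contributes two
#' records. Coding SNVs get a codon-level protein change (silent, missense,
#' nonsense) from the standard nuclear code; variants in the first or last
#' `spliceCore` bases of an intron are splice donor/acceptor (HIGH); intronic
#' bases `spliceRegionIntron[1]..[2]` and the outermost `spliceRegionExon`
#' non-coding exon bases adjacent to an intron are splice-region (location
#' `splice_site`, impact LOW); a variant within `updownWindow` bp of a gene
#' but outside it is upstream/downstream by strand; a variant near no gene
#' yields a single intergenic record.
#'
#' @param calls a [VariantCalls-class] object.
#' @param geneModels list of [GeneModel-class].
#' @param genome named [Biostrings::DNAStringSet].
#' @param updownWindow bp around each gene scanned for upstream/downstream
#'   effects (default 5000, the SnpEff convention).
#' @param spliceCore intron-terminal bases called splice donor/acceptor
#'   (default 2).
#' @param spliceRegionIntron intronic splice-region span in bases from each
#'   intron end (default bases 3 to 8).
#' @param spliceRegionExon exon-terminal bases (adjacent to an intron,
#'   non-coding only) in the splice region (default 3).
#' @return data.frame with one row per annotation record: `key`, `chrom`,
#'   `pos`, `ref`, `alt`, `geneId`, `location`, `proteinChange`, `impact`,
#'   `detail`, `note`.
#' @export
annotateVariants <- function(calls, geneModels, genome,
                             updownWindow = 5000L, spliceCore = 2L,
                             spliceRegionIntron = c(3L, 8L),
                             spliceRegionExon = 3L) {
  if (length(geneModels)) {
    gb <- GRanges(
      vapply(geneModels, function(m) m@chrom, ""),
      IRanges(vapply(geneModels, function(m) IRanges::start(geneBounds(m)), 0L),
              vapply(geneModels, function(m) IRanges::end(geneBounds(m)), 0L)))
    near <- GenomicRanges::resize(gb, GenomicRanges::width(gb) + 2L * updownWindow,
                                  fix = "center")
  }
  sites <- GRanges(variantChrom(calls), IRanges(variantPos(calls), width = 1L))
  hits <- if (length(geneModels))
    GenomicRanges::findOverlaps(sites, near, ignore.strand = TRUE)
  else S4Vectors::Hits()
  hitList <- split(S4Vectors::subjectHits(hits),
                   factor(S4Vectors::queryHits(hits), levels = seq_along(sites)))
  rows <- vector("list", length(calls))
  for (v in seq_len(length(calls))) {
    pos <- variantPos(calls)[v]; chrom <- variantChrom(calls)[v]
    ref <- refAllele(calls)[v]; alt <- altAllele(calls)[v]
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      gbase <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
      if (gbase != ref)
        .stopf("reference allele %s disagrees with genome (%s) at %s:%d",
               ref, gbase, chrom, pos)
    }
    recs <- list()
    for (gi in hitList[[v]]) {
      gm <- geneModels[[gi]]
      b <- geneBounds(gm)
      ann <- if (pos >= IRanges::start(b) && pos <= IRanges::end(b))
        .annotateOneGene(gm, pos, ref, alt, genome, spliceCore,
                         spliceRegionIntron, spliceRegionExon)
      else {
        before <- pos < IRanges::start(b)
        side <- if (before == (gm@strand == "+")) "upstream" else "downstream"
        list(location = side, detail = side)
      }
      if (is.null(ann)) next
      recs[[length(recs) + 1L]] <- data.frame(
        geneId = gm@geneId, location = ann$location,
        proteinChange = if (is.null(ann$proteinChange)) "not_applicable"
                        else ann$proteinChange,
        impact = impactTier(ann$detail), detail = ann$detail,
        note = if (is.null(ann$note)) "" else ann$note,
        stringsAsFactors = FALSE)
    }
    if (length(recs) == 0)
      recs <- list(data.frame(geneId = NA_character_, location = "intergenic",
                              proteinChange = "not_applicable",
                              impact = "MODIFIER", detail = "intergenic",
                              note = "", stringsAsFactors = FALSE))
    df <- do.call(rbind, recs)
    df <- cbind(data.frame(key = variantKeys(calls)[v], chrom = chrom,
                           pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE), df)
    rows[[v]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary of annotation records
#'
#' Per-location, per-protein-change and per-impact counts with the
#' denominators used in location/impact tables: location and impact
#' percentages are over all annotation records (which exceed the variant
#' count, since a variant near several genes yields several records); protein
#' change percentages are over coding exon SNV records only (the
#' silent/missense/nonsense partition).
#'
#' @param records data.frame from [annotateVariants()], or a list of such
#'   data.frames (per family) which are pooled with per-family columns kept.
#' @return A list with data.frames `location`, `proteinChange`, `impact`;
#'   each has per-family counts (when given a list), a `total` and a
#'   one-decimal `percent` column.
#' @export
summarizeAnnotations <- function(records) {
  fams <- if (is.data.frame(records)) list(all = records) else records
  locLevels <- c("exon", "intron", "splice_site", "intergenic",
                 "five_prime_UTR", "three_prime_UTR", "upstream", "downstream")
  pcLevels <- c("missense", "nonsense", "silent")
  impLevels <- c("LOW", "MODERATE", "MODIFIER", "HIGH")
  cnt <- function(values, levels)
    vapply(fams, function(df) as.integer(table(factor(values(df),
                                                      levels = levels))),
           integer(length(levels)))
  loc <- cnt(function(df) df$location, locLevels)
  pc <- cnt(function(df) df$proteinChange[df$proteinChange != "not_applicable"],
            pcLevels)
  imp <- cnt(function(df) df$impact, impLevels)
  asTable <- function(m, levels) {
    m <- matrix(m, nrow = length(levels),
                dimnames = list(NULL, names(fams)))
    total <- rowSums(m)
    data.frame(category = levels, m, total = total,
               percent = roundHalfUp(100 * total / sum(total), 1),
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  list(location = asTable(loc, locLevels),
       proteinChange = asTable(pc, pcLevels),
       impact = asTable(imp, impLevels))
}

#' Annotation summary from pre-tabulated counts
#'
#' Computes the same percentage tables as [summarizeAnnotations()] directly
#' from count vectors (e.g. published per-category totals), using the same
#' denominators: each vector is normalized by its own total.
#'
#' @param location,proteinChange,impact named count vectors.
#' @return A list of data.frames with `count` and one-decimal `percent`.
#' @export
annotationSummaryFromCounts <- function(location = NULL, proteinChange = NULL,
                                        impact = NULL) {
  one <- function(x) {
    if (is.null(x)) return(NULL)
    data.frame(category = names(x), count = as.numeric(x),
               percent = roundHalfUp(100 * as.numeric(x) / sum(x), 1),
               stringsAsFactors = FALSE)
  }
  list(location = one(location), proteinChange = one(proteinChange),
       impact = one(impact))
}
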