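.CTX_OFFSETS <- c("-2", "-1", "+1", "+2")
.BASES <- c("A", "C", "G", "T")

#' Pyrimidine-oriented flanking context of GC>AT mutations
#'
#' For each GC>AT SNV returns the 5-mer centred on the mutated base, oriented
#' so the mutated base reads C: when the reference base is C the forward
#' strand is read directly; when it is G the reverse complement is taken, so
#' offset -1 is always 5' of the mutated C. Variants whose flank extends past
#' a chromosome end or contains an N are returned as `NA` (with a warning
#' giving the tally).
#'
#' @param calls a [VariantCalls-class] object; only records classifying as
#'   `GC>AT` are used.
#' @param genome named [Biostrings::DNAStringSet].
#' @param flank bases on each side (default 2).
#' @return Character vector of oriented contexts (`NA` where skipped), named
#'   by variant key.
#' @export
orientedContext <- function(calls, genome, flank = 2L) {
  cls <- substitutionClass(refAllele(calls), altAllele(calls))
  use <- cls == "GC>AT"
  calls <- calls[use]
  n <- length(calls)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  lens <- Biostrings::width(genome)[match(variantChrom(calls), names(genome))]
  pos <- variantPos(calls)
  inb <- pos - flank >= 1L & pos + flank <= lens
  if (any(inb)) {
    ctx <- as.character(Biostrings::subseq(
      genome[variantChrom(calls)[inb]],
      start = pos[inb] - flank, end = pos[inb] + flank))
    isG <- refAllele(calls)[inb] == "G"
    if (any(isG))
      ctx[isG] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(ctx[isG])))
    ctx[grepl("N", ctx, fixed = TRUE)] <- NA_character_
    out[inb] <- ctx
  }
  nskip <- sum(is.na(out))
  if (nskip > 0)
    warning(sprintf("%d context(s) skipped (chromosome edge or N)", nskip),
            call. = FALSE)
  names(out) <- variantKeys(calls)
  out
}

#' Genome background base frequencies around C
#'
#' Base frequencies at offsets -2, -1, +1, +2 around every C in the genome,
#' counting both strands: forward-strand C sites directly plus the
#' reverse-complemented contexts of every G site, so the background matches
#' the pyrimidine orientation of [orientedContext()]. Computed from 2-mer
#' and 3-mer counts, so windows containing N are excluded automatically.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @return List with `counts` and `freq`: 4 x 4 matrices (offsets x bases),
#'   frequencies normalized per offset.
#' @export
backgroundContext <- function(genome) {
  di <- colSums(Biostrings::oligonucleotideFrequency(genome, 2))
  tri <- colSums(Biostrings::oligonucleotideFrequency(genome, 3))
  comp <- .complementBase
  counts <- matrix(0, 4, 4, dimnames = list(.CTX_OFFSETS, .BASES))
  for (b in .BASES) {
    cb <- comp[[b]]
    counts["-1", b] <- di[paste0(b, "C")] + di[paste0("G", cb)]
    counts["+1", b] <- di[paste0("C", b)] + di[paste0(cb, "G")]
    counts["-2", b] <-
      sum(tri[paste0(b, .BASES, "C")]) + sum(tri[paste0("G", .BASES, cb)])
    counts["+2", b] <-
      sum(tri[paste0("C", .BASES, b)]) + sum(tri[paste0(cb, .BASES, "G")])
  }
  list(counts = counts, freq = counts / rowSums(counts))
}

#' Flanking-context bias profile of GC>AT mutations
#'
#' Compares the base composition at offsets -2, -1, +1 and +2 around the
#' mutated (pyrimidine-oriented) C of a GC>AT variant set against the genome
#' background around C. Per offset, a chi-square goodness-of-fit test of the
#' observed flanking-base counts against the background proportions
#' quantifies the bias.
#'
#' @param calls a [VariantCalls-class] of EMS candidates (non-GC>AT records
#'   are ignored), or a character vector of oriented 5-mer contexts.
#' @param genome named [Biostrings::DNAStringSet].
#' @return List with `background` (frequency matrix), `observedCounts` and
#'   `observedFreq` (offsets x bases), `tests` (data.frame of offset,
#'   statistic, df, p.value), `nUsed` and `nSkipped`.
#' @export
contextProfile <- function(calls, genome) {
  ctx <- if (is.character(calls)) calls
         else suppressWarnings(orientedContext(calls, genome))
  nSkipped <- sum(is.na(ctx))
  ctx <- ctx[!is.na(ctx)]
  if (length(ctx) == 0)
    .stopf("contextProfile needs at least one usable context")
  bg <- backgroundContext(genome)
  slots <- c(`-2` = 1L, `-1` = 2L, `+1` = 4L, `+2` = 5L)
  obs <- matrix(0, 4, 4, dimnames = list(.CTX_OFFSETS, .BASES))
  tests <- data.frame(offset = .CTX_OFFSETS, statistic = NA_real_,
                      df = NA_real_, p.value = NA_real_,
                      stringsAsFactors = FALSE)
  for (k in .CTX_OFFSETS) {
    b <- substr(ctx, slots[[k]], slots[[k]])
    obs[k, ] <- table(factor(b, levels = .BASES))
    p <- bg$freq[k, ]
    ct <- suppressWarnings(stats::chisq.test(obs[k, ], p = p))
    tests[tests$offset == k, c("statistic", "df", "p.value")] <-
      c(unname(ct$statistic), unname(ct$parameter), ct$p.value)
  }
  list(background = bg$freq, observedCounts = obs,
       observedFreq = obs / rowSums(obs), tests = tests,
       nUsed = length(ctx), nSkipped = nSkipped)
}
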