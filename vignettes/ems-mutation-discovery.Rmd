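---
title: "Identifying EMS-induced mutations from pooled whole-genome resequencing"
author: "emsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying EMS-induced mutations from pooled whole-genome resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsight)
```

## The problem

Chemical mutagenesis with ethyl methanesulfonate (EMS) is a standard way to
build mutant platforms in crops: EMS alkylates guanine, which mispairs with
thymine, so the canonical footprint is a genome-wide scatter of G:C→A:T
transitions. Characterizing a platform requires estimating how many
mutations each family carries, their substitution spectrum and sequence
context, and how many are likely to disrupt genes.

With no wild-type resequenced alongside, the mutagenized families themselves
must be disentangled from three confounders:

1. **Coverage artifacts** — positions with too few reads to call a genotype,
   or with excess coverage (collapsed segmental duplications attract
   mis-mapped reads).
2. **Mapping artifacts** — regions where clusters of spurious variants
   appear because repetitive DNA is mis-placed by the aligner.
3. **Background polymorphisms** — residual heterogeneity of the founder
   line, present before the mutagen was applied.

`emsight` implements the comparative two-family strategy: sequence pooled
DNA from segregating progenies of two independent mutant families, restrict
analysis to genome positions reliably covered in *both* families, and
classify each variant by cross-family sharing and zygosity. Variants found
in both families predate the mutagen; variants specific to one family but
homozygous there are spontaneous polymorphisms fixed during selfing (an
induced mutation observed in a pool of ≥10 segregating plants cannot be
homozygous); the **family-specific heterozygous** SNVs are the operational
EMS-induced set.

## Pipeline model and parameters

`runPipeline()` executes the stages in a fixed order; all parameters below
are exposed as arguments with these defaults.

| Stage | Rule | Parameters (default) |
|---|---|---|
| genotype-quality filter | sample calls with GQ ≤ threshold are masked; variants left with no ALT-carrying call are dropped | `minGQ = 20` (phred), strict `GQ > 20` survives |
| depth-reliable regions | a position is kept iff every sample of the family has depth within bounds | `minDepth = 8`, `maxDepth = 100` reads, inclusive |
| hyperpolymorphic windows | sliding windows with more than `maxVariantsPerWindow` variants are discarded (union subtracted, variants inside dropped) | `windowSize = 1000` bp, `step = 500` bp, `maxVariantsPerWindow = 1` |
| intersection | the two families' surviving region sets are intersected into the shared scored genome | — |
| classification | shared / family-specific homozygous / family-specific heterozygous (EMS) by identical (chrom, pos, ref, alt) and the any-het pooled-genotype rule | — |

Design choices the data did not force, and why we made them:

* **Window anchoring.** Windows tile from the start of each chromosome
  (`offset = 0`), step 500 bp, including a final partial window. A position
  is removed when *any* covering window is hyperpolymorphic. An alternative
  reading of the same filter — drop every variant with a neighbor closer
  than 1 kb — is provided as `pairwiseDistanceFilter()`; the two differ on
  edge cases (a pair 900 bp apart straddling a window boundary survives the
  windowed form only), and the windowed form is canonical in the pipeline.
* **Filter order.** The depth filter is evaluated genome-wide (it sizes the
  scored genome, not just variant sites), variants are restricted to
  depth-reliable positions first, and window counting runs on the surviving
  variants. Stage counts are therefore monotone non-increasing, which the
  tests assert.
* **Pooled zygosity.** How to aggregate four pooled samples into one family
  genotype is not dictated by the data model; we use the any-het union rule
  (`familyGenotype()`): at least one heterozygous pool means the variant
  still segregates in the family. With pools of ≥10 plants a segregating
  mutation is essentially never sampled as all-carriers, so this is the
  conservative choice.
* **GQ masking granularity.** The GQ filter masks individual sample calls
  rather than dropping whole sites, so one bad sample does not erase
  evidence carried by the other three pools.
* **Sharing requires the identical ALT allele**, not just the position;
  two different substitutions at one site are two variants.
* **Indels** flow through filtering and classification but are excluded
  from spectrum, Ts/Tv and context computations, which are defined for
  single-base substitutions.

## Spectrum, density and context

Substitutions are collapsed with their reverse complements into six classes
(`GC>AT`, `TA>CG` transitions; `GC>CG`, `GC>TA`, `TA>AT`, `TA>GC`
transversions). `mutationSpectrum()` reports counts, one-decimal shares and
the Ts/Tv ratio (`NA` when there are no transversions).
`mutationDensity()` reports mutations/Mb and kb-per-mutation over the
scored genome, globally and per chromosome, keeping unrounded values
alongside the one-decimal report values. Report-time rounding is
half-away-from-zero (`roundHalfUp()`) to match how such tables are printed;
full precision is kept internally.

`contextProfile()` examines the ±2 flanking bases of the canonical `GC>AT`
mutations only, oriented so the mutated base always reads C (contexts of
mutated G sites are reverse-complemented). The genome background is the base
composition around every C on both strands, computed from 2-mer/3-mer
counts, so windows containing N drop out automatically; variant contexts
with N or running off a chromosome end are skipped and tallied in a
warning. Per offset we test observed flanking-base counts against the
background proportions with a chi-square goodness of fit — the simplest
test for categorical composition; the test is exposed in the returned
`tests` table and can be swapped by operating on the returned counts. Note
that a modest site-selection bias (the default simulation uses weight 2 for
pyrimidine-flanked sites) produces only small marginal frequency shifts at
a hundred mutations, so non-significant per-offset p-values on simulated
EMS sets are expected; the machinery is validated with constructed variant
sets where the enrichment is forced.

## Consequence annotation

`annotateVariants()` is a deliberately small re-implementation of the
SnpEff-style location/impact logic, sufficient to reproduce
location–protein-change–impact tables: one record per (variant, nearby
gene), so location counts exceed variant counts when genes are close
together, and the summary denominators follow the table structure (location
and impact percentages over all records; silent/missense/nonsense over
coding exon SNV records). Conventions:

* up/downstream window 5 kb (`updownWindow`), the SnpEff default;
* splice **core** = first/last 2 intronic bases (`spliceCore`), mapped to
  splice_donor/splice_acceptor with HIGH impact, donor on the
  transcriptionally upstream side;
* splice **region** = intronic bases 3–8 plus the outermost 3 exonic bases
  adjacent to an intron, location `splice_site` with LOW impact. Exonic
  bases inside the CDS always stay `exon` records with a codon-level call,
  which keeps the silent+missense+nonsense partition equal to the coding
  exon record count; the exonic splice-region label therefore applies only
  to non-coding exon edges (UTR exons). This reproduces the coexistence of
  many splice-site *locations* with few HIGH splice records.
* coding SNVs are resolved through the standard nuclear codon table by
  rebuilding the affected codon strand-aware; a change creating a stop is
  nonsense (stop_gained, HIGH), destroying the initiator ATG is start_lost
  (HIGH, counted as missense in the protein-change partition since the
  literal codon change is an amino-acid substitution), synonymous is silent
  (LOW), the rest missense (MODERATE). Tests verify every coding call
  against an independent oracle that rebuilds the entire CDS, substitutes
  the base, translates both sequences literally and diffs them, over
  randomized multi-exon genes on both strands.
* CDS indels get frameshift (HIGH) or inframe_indel (MODERATE) by the
  length-mod-3 rule; they carry no silent/missense/nonsense label.

## Segregation and phenotype statistics

`chiSquareGof()` tests observed phenotype classes against a Mendelian ratio
with the uncorrected Pearson statistic and `df = classes − 1`. No Yates
continuity correction is applied: the published two-class statistics
(0.36, 0.01, 0.28, 0.25, 0.10) are reproduced only without it (with Yates,
34:30 against 1:1 gives 0.14 rather than 0.25). The statistic is invariant
to rescaling the ratio, and its p-value is checked against a numerically
integrated chi-square density in the tests. `phenotypeFrequencies()`
tabulates affected/screened percentages; `phenotypeTotals()` returns both
readings of a total row (distinct affected families vs the sum of category
frequencies), because published tables sometimes print the latter.

## The synthetic data generator

No raw sequencing data accompany the analysis this package reproduces, so
`simulateDataset()` generates ground-truthed inputs for every stage:

* genome: i.i.d. bases, default 10 Mb over 4 chromosomes at GC 0.37
  (cucurbit-like); sizes chosen so a full replicate runs in seconds while
  leaving thousands of windows per family;
* gene models: 200 non-overlapping multi-exon genes on both strands, CDS
  patched into the genome to be complete (ATG…stop, no internal stop,
  length divisible by 3) — a reduced gene density that keeps annotation
  exercise cheap;
* variants: counts scaled from the reported per-Mb rates over a 144.5 Mb
  scored genome — shared homozygous 220, shared segregating 60,
  family-specific homozygous 35/25, EMS 120/60 per 10 Mb — with the EMS
  spectrum defaulting to 0.80 GC>AT, 0.07 TA>CG and the remaining 0.13
  split across the four transversions, and a twofold site-selection weight
  for pyrimidine-flanked GC>AT sites;
* true variants are placed with a hard >1 kb minimum spacing (real EMS
  mutations sit tens of kb apart; sub-kb clusters are the signature of
  mapping artifacts), while injected artifact clusters (default 5 per
  family, 3 variants within ~250 bp) deliberately violate it so the window
  filter has something to remove;
* depth: piecewise-constant per-sample tracks (2 kb chunks, gamma around
  mean 35), with low-depth dropouts in one sample (1% of the genome per
  family) and high-depth duplication-like intervals in all samples (0.5%);
* genotypes: pooled samples are simulated at the genotype level — a
  segregating variant is a heterozygous call in every pool, a fixed variant
  homozygous. GQ is drawn around 70 with a 0.5% rate of spuriously low
  values. Read-level pool sampling (allele-depth deconvolution) is a
  documented extension hook, not implemented, because the pipeline consumes
  genotype calls only.

What the simulation does *not* emulate: real read mapping (mismapping
beyond the injected clusters and depth intervals), sequencing error
profiles, allele-frequency drift within pools, linked selection, and real
genome composition (repeats, GC heterogeneity, gene density). Passing
recovery tests therefore demonstrate that the filtering and classification
logic is correct under the stated error model, not that the thresholds are
optimal for any particular real dataset.

With these defaults the pipeline recovers the EMS set with mean precision
≈ 1 and mean recall ≈ 0.96–0.97 over replicates (losses are EMS mutations
falling in depth-masked regions, measured against the full ledger), and the
recovered GC>AT share stays within ~1–2 points of the configured 0.80.
These are the quantities `scripts/acceptance.R` recomputes.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based closed (`IRanges`/`GRanges`) throughout; BED and
  BedGraph conversion at the file boundary is delegated to `rtracklayer`.
* Ts/Tv with zero transversions returns `NA`, never `Inf`; density with
  zero mutations reports density 0 and spacing `NA`.
* Zero SNVs make `mutationSpectrum()` and `contextProfile()` error rather
  than return empty summaries.
* Multi-allelic VCF records are split per ALT allele and each allele is
  filtered and classified independently.
* Depth bounds are inclusive (`8` and `100` both pass); the GQ threshold is
  strict (`GQ > 20` survives).
* All randomness in the simulator flows from a single `set.seed()` in
  `simulateDataset()`; identical parameters and seed give byte-identical
  outputs.

## Known limitations

* The annotator handles one transcript per gene and no regulatory features,
  canonical-transcript selection or HGVS strings.
* Classification assumes exactly two families; extending the intersection
  and sharing logic to more families is structural, not conceptual.
* Published retained-region sizes and variant counts for the real dataset
  depend on unavailable raw reads; the package reproduces the printed
  arithmetic exactly and validates the pipeline logic on synthetic data
  instead — it cannot re-derive those counts from scratch.

## A worked run

```{r, eval = FALSE}
sim <- simulateDataset(simParams(), seed = 1)
res <- runPipeline(sim$calls, sim$depth,
                   genome = sim$genome, geneModels = sim$models)
res$summary$mbRetained
res$summary$emsCounts
evaluateRecovery(res$classified, sim$truth)
```

The run summary reports per-stage variant counts, Mb retained at each
stage, per-family EMS counts, density, spectrum, Ts/Tv and annotation
tallies; `writeSimulation()` materializes a replicate as
FASTA/GFF3/VCF/BedGraph/TSV for use outside R.
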