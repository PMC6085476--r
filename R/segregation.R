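#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Tests observed phenotype-class counts against an expected Mendelian ratio
#' (e.g. 1:1 for a backcross, 1:2:1 for a selfed heterozygote) with the
#' uncorrected Pearson chi-square statistic (no Yates continuity correction)
#' and `df = classes - 1`. The ratio may be given in any scale (1:1 and 2:2
#' are equivalent).
#'
#' @param observed integer counts per phenotype class (length >= 2).
#' @param ratio expected ratio, same length as `observed`.
#' @return A list with `observed`, `ratio`, `expected`, `chi2`, `chi2Rounded`
#'   (two decimals), `df` and `p.value` (upper tail).
#' @export
chiSquareGof <- function(observed, ratio) {
  if (length(observed) != length(ratio) || length(observed) < 2)
    .stopf("observed and ratio must have equal length >= 2")
  if (sum(observed) <= 0) .stopf("total observed count must be positive")
  if (any(ratio <= 0)) .stopf("expected ratio classes must be positive")
  p <- ratio / sum(ratio)
  ct <- suppressWarnings(stats::chisq.test(observed, p = p))
  list(observed = observed, ratio = ratio,
       expected = sum(observed) * p,
       chi2 = unname(ct$statistic),
       chi2Rounded = roundHalfUp(unname(ct$statistic), 2),
       df = unname(ct$parameter),
       p.value = ct$p.value)
}

#' Phenotype frequency table
#'
#' Per-category frequency of affected families among families screened, as a
#' two-decimal percentage.
#'
#' @param category character vector of phenotype categories.
#' @param affected families showing the phenotype.
#' @param screened families screened per category.
#' @return data.frame with `category`, `affected`, `screened`,
#'   `percent` (two decimals).
#' @export
phenotypeFrequencies <- function(category, affected, screened) {
  if (any(screened <= 0)) .stopf("screened must be positive")
  if (any(affected < 0 | affected > screened))
    .stopf("affected must lie in [0, screened]")
  data.frame(category = as.character(category),
             affected = as.numeric(affected),
             screened = as.numeric(screened),
             percent = roundHalfUp(100 * affected / screened, 2),
             stringsAsFactors = FALSE)
}

#' Two readings of a phenotype-table total row
#'
#' Published mutant-screen tables sometimes print the total row as the sum of
#' the per-category frequencies (families counted once per category they
#' appear in) rather than the fraction of distinct affected families. Both
#' interpretations are returned so either can be compared.
#'
#' @param distinctAffected number of distinct affected families (may be `NA`).
#' @param screened families screened.
#' @param categoryPercents per-category percentage column.
#' @return list with `distinctFamilyPercent` and `summedCategoryPercent`.
#' @export
phenotypeTotals <- function(distinctAffected, screened, categoryPercents) {
  list(
    distinctFamilyPercent = if (is.na(distinctAffected)) NA_real_
      else roundHalfUp(100 * distinctAffected / screened, 2),
    summedCategoryPercent = roundHalfUp(sum(categoryPercents), 2))
}
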