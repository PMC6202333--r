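# Hardy-Weinberg founder arithmetic: carrier fractions, expected
# homozygote counts, genotype-based prevalence. All reporting rounds are
# the package's conventions; unrounded values are always returned too.

#' Expected carrier (heterozygote) fraction under Hardy-Weinberg
#'
#' For a minor allele at frequency `p`, the heterozygote fraction is
#' `2p(1-p)`. The reported "1 in N" form rounds the reciprocal to one
#' significant figure.
#'
#' @param p Minor allele frequency in `[0, 0.5]`.
#' @return List with `fraction` (2pq), `one_in_n` (reciprocal rounded to
#'   one significant figure; NA when the fraction is 0) and
#'   `one_in_n_unrounded`.
#' @export
expected_carrier_fraction <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 0.5)
    stop("allele frequency must be a single value in [0, 0.5]")
  frac <- 2 * p * (1 - p)
  list(fraction = frac,
       one_in_n = if (frac > 0) signif(1 / frac, 1) else NA_real_,
       one_in_n_unrounded = if (frac > 0) 1 / frac else NA_real_)
}

#' Expected homozygote count under Hardy-Weinberg
#'
#' Expected number of minor-allele homozygotes in a population of size
#' `n`: `p^2 * n`.
#'
#' @param p Minor allele frequency in `[0, 0.5]`.
#' @param n Population size (non-negative).
#' @return List with `expected` (unrounded p^2 n) and `reported`
#'   (rounded to an integer).
#' @export
expected_homozygote_count <- function(p, n) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 0.5)
    stop("allele frequency must be a single value in [0, 0.5]")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("population size must be non-negative")
  e <- p^2 * n
  list(expected = e, reported = round(e))
}

#' Genotype-based disease prevalence
#'
#' Prevalence estimated directly from genotype carriage in a genotyped
#' set: positives / n_genotyped. The "1 in N" report rounds the
#' reciprocal to the nearest 1,000 when it is at least 10,000, the
#' nearest 100 when at least 1,000, the nearest 10 when at least 10, and
#' the nearest integer below that.
#'
#' @param positives Count of genotype-positive individuals.
#' @param n_genotyped Size of the genotyped set (> 0).
#' @return List with `positives`, `n_genotyped`, `rate`, `one_in_n`
#'   (reported rounding; NA when positives = 0) and `one_in_n_unrounded`.
#' @export
genotype_based_prevalence <- function(positives, n_genotyped) {
  if (n_genotyped <= 0) stop("n_genotyped must be positive")
  if (positives < 0 || positives > n_genotyped)
    stop("positives must lie in [0, n_genotyped]")
  rate <- positives / n_genotyped
  if (positives == 0)
    return(list(positives = positives, n_genotyped = n_genotyped,
                rate = 0, one_in_n = NA_real_, one_in_n_unrounded = NA_real_))
  recip <- n_genotyped / positives
  unit <- if (recip >= 10000) 1000 else if (recip >= 1000) 100
          else if (recip >= 10) 10 else 1
  list(positives = positives, n_genotyped = n_genotyped, rate = rate,
       one_in_n = round(recip / unit) * unit,
       one_in_n_unrounded = recip)
}
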