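## Auxiliary founder-population statistics: binomial simulation of founder
## allele observation counts in a pseudo-haploid ancient sample, exact
## two-tailed binomial and Fisher tests, and the continuous gene-flow bound.

#' Binomial simulation of founder-allele observation counts
#'
#' Simulates how many founder alleles would be observed in an ancient
#' cohort, given the allele frequencies in the modern founder population.
#' Per run and per allele \code{i}, the ancient allele count is drawn as
#' \code{Binomial(n_i, p_i)} — \code{n_i} haploid draws, the pseudo-haploid
#' convention where each of the \code{n_i} genotyped individuals contributes
#' one allele — and the statistic is the number of alleles observed in at
#' least one individual.
#'
#' @param table data.frame with columns \code{p} (modern-population allele
#'   frequency) and \code{n} (ancient individuals genotyped at that site);
#'   an optional \code{allele} id column is ignored.
#' @param nRuns number of simulation runs (default 10000).
#' @param seed integer seed.
#' @return A list with \code{distribution} (the statistic across runs),
#'   \code{interval} (its [2.5, 97.5] percentiles, inverse-ECDF quantiles so
#'   the bounds are attained counts), \code{mean}, and
#'   \code{expected} (the closed-form expectation
#'   \code{sum_i [1 - (1 - p_i)^{n_i}]}).
#' @examples
#' tab <- data.frame(p = rep(0.05, 20), n = rep(10, 20))
#' simulateObservedAlleleCount(tab, nRuns = 1000, seed = 1)$interval
#' @export
simulateObservedAlleleCount <- function(table, nRuns = 10000, seed = 1) {
  stopifnot(all(c("p", "n") %in% names(table)), nRuns >= 1)
  p <- table$p; n <- table$n
  if (any(p < 0 | p > 1)) stop("allele frequencies p must be in [0, 1]")
  if (any(n < 0)) stop("genotyped counts n must be >= 0")
  m <- length(p)
  stat <- .withSeed(seed, {
    draws <- matrix(stats::rbinom(m * nRuns, size = n, prob = p), nrow = m)
    colSums(draws >= 1L)
  })
  list(distribution = stat,
       interval = stats::quantile(stat, c(0.025, 0.975), type = 1),
       mean = mean(stat),
       expected = sum(1 - (1 - p)^n))
}

#' Exact two-tailed binomial test
#'
#' Exact two-sided p-value for \code{k} successes in \code{n} trials under
#' null proportion \code{p0}, by the method of small p-values: the sum of
#' \code{Binomial(n, p0)} probabilities over all outcomes no more probable
#' than the observed one (within a 1e-7 relative tolerance for ties).
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null proportion, in (0, 1).
#' @return The two-sided p-value.
#' @examples
#' binomialTestTwoTailed(11, 31, 0.20)  # ~0.04
#' @export
binomialTestTwoTailed <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

#' Exact two-tailed Fisher test on a 2x2 table
#'
#' Two-sided p-value for the 2x2 table \code{(a, b; c, d)} with all margins
#' fixed: the sum of hypergeometric probabilities of all tables no more
#' probable than the observed one (1e-7 relative tolerance for ties).
#'
#' @param a,b,c,d non-negative integer cell counts (rows are groups,
#'   columns are carrier status).
#' @return The two-sided p-value.
#' @examples
#' fisherExactTwoTailed(7, 6, 2, 8)  # ~0.20
#' @export
fisherExactTwoTailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Per-generation bound on continuous gene flow
#'
#' Converts a bound \code{X} on the total fraction of a gene pool replaced
#' by admixture over \code{G} generations into the equivalent constant
#' per-generation replacement rate \code{m}: continuous gene flow at rate
#' \code{m} replaces \code{1 - (1 - m)^G} of the gene pool, so
#' \code{m = 1 - (1 - X)^{1/G}}.
#'
#' @param totalFraction total replaced fraction \code{X}, in [0, 1).
#' @param generations number of generations \code{G} (>= 1).
#' @return The per-generation replacement rate \code{m}.
#' @examples
#' perGenerationReplacementBound(0.04, 20)  # ~0.002, i.e. 0.2% per generation
#' @export
perGenerationReplacementBound <- function(totalFraction, generations) {
  stopifnot(totalFraction >= 0, totalFraction < 1, generations >= 1)
  1 - (1 - totalFraction)^(1 / generations)
}

#' Carrier frequency of a lineage
#'
#' @param carriers number of carriers \code{k}.
#' @param total sample size \code{n} (>= 1).
#' @param percent if \code{TRUE}, return the percentage rounded to the
#'   nearest integer (the reporting convention); otherwise the proportion.
#' @return \code{k / n}, or \code{round(100 k / n)} with
#'   \code{percent = TRUE}.
#' @examples
#' lineageFrequency(11, 31, percent = TRUE)  # 35
#' @export
lineageFrequency <- function(carriers, total, percent = FALSE) {
  stopifnot(total >= 1, carriers >= 0, carriers <= total)
  if (percent) round(100 * carriers / total) else carriers / total
}

#' Founder-allele definition predicate
#'
#' Applies the configurable filters that define a founder allele over a
#' user-supplied frequency table: minor-allele frequency above
#' \code{minFounderFreq} in the founder population, below
#' \code{maxOutgroupFreq} in the reference outgroup, at most
#' \code{maxRegionalCarriers} carriers among regional reference individuals,
#' and at least \code{minGenotyped} genotyped ancient individuals.  Columns
#' not present in \code{table} are skipped (that filter is not applied).
#'
#' @param table data.frame with (any of) columns \code{p_founder},
#'   \code{p_outgroup}, \code{regional_carriers}, \code{n_genotyped}.
#' @param minFounderFreq,maxOutgroupFreq,maxRegionalCarriers,minGenotyped
#'   filter thresholds (defaults 0.005, 1e-4, 1, 3).
#' @return Logical vector: which rows qualify as founder alleles.
#' @export
founderAllelePredicate <- function(table, minFounderFreq = 0.005,
                                   maxOutgroupFreq = 1e-4,
                                   maxRegionalCarriers = 1,
                                   minGenotyped = 3) {
  keep <- rep(TRUE, nrow(table))
  if ("p_founder" %in% names(table))
    keep <- keep & table$p_founder > minFounderFreq
  if ("p_outgroup" %in% names(table))
    keep <- keep & table$p_outgroup < maxOutgroupFreq
  if ("regional_carriers" %in% names(table))
    keep <- keep & table$regional_carriers <= maxRegionalCarriers
  if ("n_genotyped" %in% names(table))
    keep <- keep & table$n_genotyped >= minGenotyped
  keep
}
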