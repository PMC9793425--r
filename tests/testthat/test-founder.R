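# Founder-population statistics: exact tests, binomial simulations, and the
# gene-flow bound.

test_that("exact binomial test agrees with the enumeration oracle", {
  # worked example: 11/31 carriers against a null frequency of 20%
  expect_equal(round(binomialTestTwoTailed(11, 31, 0.20), 2), 0.04)
  # independent implementation as oracle
  expect_equal(binomialTestTwoTailed(11, 31, 0.20),
               binom.test(11, 31, 0.20)$p.value, tolerance = 1e-12)
  # at the mode the test cannot reject
  expect_equal(binomialTestTwoTailed(10, 20, 0.5), 1, tolerance = 1e-9)
  set.seed(51)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomialTestTwoTailed(k, n, p0),
                 binom.test(k, n, p0)$p.value, tolerance = 1e-9)
  }
})

test_that("exact Fisher test agrees with the enumeration oracle", {
  # worked example: K1a1b1a carriers 7/13 vs 2/10 between the two subgroups
  expect_equal(round(fisherExactTwoTailed(7, 6, 2, 8), 2), 0.20)
  expect_equal(fisherExactTwoTailed(7, 6, 2, 8),
               fisher.test(matrix(c(7, 2, 6, 8), 2))$p.value,
               tolerance = 1e-12)
  # a zero row makes every table equally extreme
  expect_equal(fisherExactTwoTailed(0, 0, 3, 7), 1)
  set.seed(52)
  for (i in 1:25) {
    x <- sample(0:12, 4, replace = TRUE)
    expect_equal(fisherExactTwoTailed(x[1], x[2], x[3], x[4]),
                 fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the per-generation replacement bound inverts cumulative gene flow", {
  m <- perGenerationReplacementBound(0.04, 20)
  expect_equal(m, 1 - 0.96^(1 / 20), tolerance = 1e-12)
  expect_equal(round(100 * m, 1), 0.2)    # reported as 0.2% per generation
  expect_equal(perGenerationReplacementBound(0, 13), 0)
  expect_equal(perGenerationReplacementBound(0.3, 1), 0.3)
  set.seed(53)
  for (i in 1:20) {
    X <- runif(1, 0, 0.99); G <- sample(1:50, 1)
    m <- perGenerationReplacementBound(X, G)
    expect_equal(1 - (1 - m)^G, X, tolerance = 1e-12)
  }
  expect_error(perGenerationReplacementBound(1, 10))
})

test_that("lineage frequencies report the conventional rounded percents", {
  expect_equal(lineageFrequency(11, 31, percent = TRUE), 35)
  expect_equal(lineageFrequency(7, 13, percent = TRUE), 54)
  expect_equal(lineageFrequency(0, 10, percent = TRUE), 0)
  expect_equal(lineageFrequency(11, 31), 11 / 31)
  expect_error(lineageFrequency(1, 0))
})

test_that("founder-allele simulations match the closed-form expectation", {
  # degenerate inputs
  zero <- simulateObservedAlleleCount(data.frame(p = rep(0, 5), n = 2:6),
                                      nRuns = 50, seed = 1)
  expect_true(all(zero$distribution == 0))
  one <- simulateObservedAlleleCount(data.frame(p = rep(1, 5), n = rep(2, 5)),
                                     nRuns = 50, seed = 1)
  expect_true(all(one$distribution == 5))

  set.seed(54)
  tab <- data.frame(p = runif(40, 0.005, 0.2), n = sample(3:29, 40, TRUE))
  res <- simulateObservedAlleleCount(tab, nRuns = 10000, seed = 9)
  se <- sd(res$distribution) / sqrt(10000)
  expect_lt(abs(res$mean - res$expected), 3 * se)
  expect_true(all(res$distribution >= 0 & res$distribution <= 40))
  expect_true(all(res$interval == round(res$interval)))

  # determinism
  res2 <- simulateObservedAlleleCount(tab, nRuns = 10000, seed = 9)
  expect_identical(res$distribution, res2$distribution)
})

test_that("the founder-allele predicate applies each configured filter", {
  tab <- data.frame(p_founder = c(0.01, 0.002, 0.01, 0.01, 0.01),
                    p_outgroup = c(0, 0, 5e-4, 0, 0),
                    regional_carriers = c(0, 0, 0, 2, 1),
                    n_genotyped = c(5, 5, 5, 5, 2))
  expect_equal(founderAllelePredicate(tab),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # absent columns mean the corresponding filter is skipped
  expect_true(all(founderAllelePredicate(tab["p_founder"])[c(1, 3, 4)]))
})
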