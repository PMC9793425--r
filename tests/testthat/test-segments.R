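# Closed-form expected counts per length bin and the segment-table
# post-processing rules.

test_that("conditional expected counts match hand-derived values", {
  # one 1-Morgan chromosome, t = 10, bin [4, 15) cM:
  # F(0.15) - F(0.04) = e^-3 (-18) - e^-0.8 (-20.2) = 8.18028
  E <- expectedCountsGivenTmrca(10, oneChromGenome(100), LengthBins(c(4, 15)))
  expect_equal(unname(E), exp(-3) * (-18) - exp(-0.8) * (-20.2),
               tolerance = 1e-12)
  expect_equal(unname(E), 8.18028, tolerance = 1e-5)

  # 5-cM chromosome: includes the whole-chromosome term e^-1
  E2 <- expectedCountsGivenTmrca(10, oneChromGenome(5), LengthBins(c(4, 15)))
  expect_equal(unname(E2), 0.539195, tolerance = 1e-5)

  # chromosome shorter than the lower bin edge contributes nothing
  expect_equal(unname(expectedCountsGivenTmrca(10, oneChromGenome(3),
                                               LengthBins(c(4, 15)))), 0)
  expect_error(expectedCountsGivenTmrca(0.5, oneChromGenome(100),
                                        LengthBins(c(4, 15))), "tSep")
})

test_that("bin integrals agree with adaptive quadrature", {
  set.seed(31)
  for (i in 1:12) {
    t <- runif(1, 1, 200)
    L <- runif(1, 0.05, 3)            # Morgans
    a <- 2 * t
    edges <- sort(runif(4, 0, 1.2 * L))
    E <- expectedCountsGivenTmrca(t, GenomeMap(c(c1 = L * 100)),
                                  LengthBins(edges * 100))
    dens <- function(l) (a^2 * (L - l) + 2 * a) * exp(-a * l)
    for (b in 1:3) {
      lo <- edges[b]; hi <- edges[b + 1]
      ref <- 0
      if (lo < L)
        ref <- stats::integrate(dens, lo, min(hi, L),
                                rel.tol = 1e-12)$value
      if (lo <= L && L < hi) ref <- ref + exp(-a * L)
      expect_equal(unname(E[b]), ref, tolerance = 1e-8)
    }
  }
})

test_that("expected counts over all lengths sum to 1 + a L", {
  # breakpoints are Poisson(a L), intervals = breakpoints + 1
  for (t in c(3, 17, 60)) {
    L <- 1.4  # Morgans
    # the top edge must exceed L so the whole-chromosome event is counted
    fine <- LengthBins(seq(0, L * 100 + 1, length.out = 400))
    tot <- sum(expectedCountsGivenTmrca(t, GenomeMap(c(c1 = L * 100)), fine))
    expect_equal(tot, 1 + 2 * t * L, tolerance = 1e-10)
  }
})

test_that("expected counts in long-segment bins decay with separation time", {
  # the per-bin expectation peaks near t = 1/edge (25 for a 4-cM edge) and
  # decays beyond it
  g <- defaultGenomeMap()
  bins <- defaultIBDBins()
  prev <- expectedCountsGivenTmrca(30, g, bins)
  for (t in c(45, 80, 150, 300)) {
    cur <- expectedCountsGivenTmrca(t, g, bins)
    expect_true(all(cur < prev))
    prev <- cur
  }
})

test_that("pairCount matches the haplotype-pair formulas", {
  expect_equal(pairCount(637, "IBD"), 810264)
  expect_equal(pairCount(1, "IBD"), 0)
  expect_equal(pairCount(1, "ROH"), 1)
  expect_equal(pairCount(574, "ROH"), 574)
  expect_error(pairCount(0, "IBD"), ">= 1")
})

test_that("expectedBinCounts is linear in the pair count", {
  m <- SinglePopModel(Na = 1000, Nb = 150, Tb = 30, d = 10, Nc = 5e4)
  g <- oneChromGenome(150)
  l1 <- expectedBinCounts(m, SamplingSpec(), g, defaultIBDBins(), P = 1)
  l2 <- expectedBinCounts(m, SamplingSpec(), g, defaultIBDBins(), P = 2)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  expect_true(all(l1 > 0))
})

test_that("gap merging follows the three-condition rule, iteratively", {
  # 4-cM and 2.5-cM segments with a 0.4-cM gap merge into one record
  m <- mergeRohGaps(rohRecords(c(3, 7.4), c(7, 9.9)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_cM, 3)
  expect_equal(m$end_cM, 9.9)
  expect_equal(m$length_cM, 6.9)

  # neither segment reaches 4 cM: no merge
  expect_equal(nrow(mergeRohGaps(rohRecords(c(0, 2.3), c(2, 4.8)))), 2L)
  # gap above 0.5 cM: no merge
  expect_equal(nrow(mergeRohGaps(rohRecords(c(3, 7.6), c(7, 10)))), 2L)
  # a segment below the 2-cM floor blocks the merge
  expect_equal(nrow(mergeRohGaps(rohRecords(c(3, 7.4), c(7, 9.3)))), 2L)

  # chain: the merged record participates in the next merge
  chain <- mergeRohGaps(rohRecords(c(0, 4.3, 7.0), c(4, 6.8, 9.5)))
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$end_cM, 9.5)

  # idempotence
  expect_identical(mergeRohGaps(m), m)

  expect_error(mergeRohGaps(rohRecords(c(0, 3), c(4, 6))), "overlap")
})

test_that("high-ROH individuals are excluded by the long-segment total", {
  one51 <- rohRecords(0, 51, sample = "a")
  many39 <- do.call(rbind, lapply(1:14, function(i)
    rohRecords(10 * i, 10 * i + 3.9, sample = "b", chrom = paste0("chr", i))))
  at50 <- rohRecords(c(0, 100), c(25, 125), sample = "c")  # exactly 50
  segs <- rbind(one51, many39, at50)
  res <- filterHighRohIndividuals(segs)
  expect_equal(res$excluded$sample, "a")
  expect_equal(res$excluded$total_cM, 51)
  # b has 54.6 cM total but no segment above 4 cM; c sits exactly at the
  # threshold: both retained (strict inequality)
  expect_setequal(unique(res$retained$sample), c("b", "c"))
})

test_that("binning is half-open and conserves segments", {
  b <- binSegments(c(4.2, 4.9, 14.99, 15.0), defaultIBDBins())
  expect_equal(unname(b$counts), c(2, rep(0, 9), 1))
  expect_equal(b$dropped, 1L)

  expect_equal(unname(binSegments(numeric(), defaultIBDBins())$counts),
               rep(0, 11))

  # lower edge belongs to its bin
  expect_equal(unname(binSegments(4, LengthBins(c(4, 5)))$counts), 1)

  set.seed(32)
  lens <- runif(500, 0, 50)
  b2 <- binSegments(lens, defaultAncientROHBins())
  expect_equal(sum(b2$counts) + b2$dropped, 500L)
})

test_that("the packaged genome map covers the 22 autosomes", {
  g <- defaultGenomeMap()
  expect_length(chromLengths(g), 22L)
  expect_true(all(chromLengths(g) > 0))
  expect_gt(sum(chromLengths(g)), 3000)  # ~35 Morgans in total
})
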