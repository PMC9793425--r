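# Maximum-likelihood fitting, constrained refits, bootstrap intervals and
# model selection.  Optimizer settings are reduced where the check is about
# behaviour rather than search power.

coarse <- list(NP = 16, itermax = 80, window = 25, nStarts = 1,
               polishMaxit = 40)

noiselessStudy <- function(model = studyModel(), P = 810264) {
  spec <- SamplingSpec(mode = "IBD")
  lam <- expectedBinCounts(model, spec, defaultGenomeMap(),
                           defaultIBDBins(), P = P)
  SegmentCountTable(lam, defaultIBDBins(), nPairs = P, sampling = spec)
}

test_that("a fully fixed space returns the fixed point without a search", {
  ds <- noiselessStudy()
  p <- c(Na = 10000, Nb = 1563, Tb = 41, d = 20, Nc = 1e6)
  sp <- defaultParameterSpace("single", fixed = p)
  fit <- fitModel(ds, "single", space = sp)
  expect_identical(fit@diagnostics$iterations, 0L)
  expect_equal(estimates(fit), p[names(estimates(fit))])
  expect_true(is.finite(fit@loglik))
})

test_that("fits are deterministic under a fixed seed", {
  ds <- noiselessStudy(P = 1000)
  f1 <- fitModel(ds, "single", seed = 5, control = coarse)
  f2 <- fitModel(ds, "single", seed = 5, control = coarse)
  expect_identical(estimates(f1), estimates(f2))
  expect_identical(f1@loglik, f2@loglik)
  expect_identical(f1@diagnostics$nEval, f2@diagnostics$nEval)
})

test_that("noiseless counts are recovered to within 5% sizes / 1 generation", {
  ds <- noiselessStudy()
  fit <- fitModel(ds, "single", seed = 1, control = list(nStarts = 3))
  e <- estimates(fit)
  truth <- c(Na = 10000, Nb = 1563, Tb = 41, d = 20, Nc = 1e6)
  expect_lt(abs(e["Nb"] / truth["Nb"] - 1), 0.05)
  expect_lt(abs(e["Tb"] - truth["Tb"]), 1)
  expect_lt(abs(e["d"] - truth["d"]), 1)
  # loglik at the optimum cannot be below the generating model's
  sp <- defaultParameterSpace("single", fixed = truth)
  atTruth <- fitModel(ds, "single", space = sp)@loglik
  expect_gte(fit@loglik + 1e-9, atTruth)
})

test_that("refitting a 1-D subset recovers a doubled bottleneck onset", {
  gen <- SinglePopModel(Na = 10000, Nb = 1563, Tb = 82, d = 20, Nc = 1e6)
  ds <- noiselessStudy(gen)
  # prior fit holds every parameter at the original study values
  prior <- fitModel(ds, "single",
                    space = defaultParameterSpace("single",
                      fixed = c(Na = 10000, Nb = 1563, Tb = 41, d = 20,
                                Nc = 1e6)))
  refit <- refitFixedSubset(prior, "Tb", ds, seed = 2, control = coarse)
  expect_lt(abs(estimates(refit)["Tb"] - 82), 1)
  expect_equal(estimates(refit)["Nb"], c(Nb = 1563))  # still fixed
  expect_error(refitFixedSubset(prior, character(), ds), "free")
})

test_that("the 1-D profile over the bottleneck onset is unimodal", {
  ds <- noiselessStudy()
  grid <- seq(30, 55, by = 2.5)
  prof <- vapply(grid, function(Tb) {
    sp <- defaultParameterSpace("single",
      fixed = c(Na = 10000, Nb = 1563, Tb = Tb, d = 20, Nc = 1e6))
    fitModel(ds, "single", space = sp)@loglik
  }, numeric(1))
  peak <- which.max(prof)
  expect_true(all(diff(prof[seq_len(peak)]) > 0))
  expect_true(all(diff(prof[peak:length(prof)]) < 0))
  expect_equal(grid[peak], 40, tolerance = 3)
})

test_that("freeing the full set is equivalent to a fresh fit", {
  ds <- noiselessStudy(P = 1000)
  prior <- fitModel(ds, "single", seed = 3, control = coarse)
  re <- refitFixedSubset(prior, c("Na", "Nb", "Tb", "d", "Nc"), ds,
                         seed = 3, control = coarse)
  expect_identical(freeParameters(re@space),
                   freeParameters(defaultParameterSpace("single")))
  expect_gte(re@loglik + 1e-6, prior@loglik)  # warm-started refit
})

test_that("bootstrap intervals are deterministic and cover a generating value", {
  truth <- studyModel()
  spec <- SamplingSpec(mode = "IBD")
  ds <- sampleCounts(truth, spec, defaultGenomeMap(), defaultIBDBins(),
                     P = 810264, seed = 61)
  fit <- fitModel(ds, "single", seed = 6, control = coarse)
  b1 <- bootstrapCI(fit, ds, nReplicates = 8, seed = 6, control = coarse)
  b2 <- bootstrapCI(fit, ds, nReplicates = 8, seed = 6, control = coarse)
  expect_identical(b1@ci, b2@ci)
  expect_equal(rownames(b1@ci), freeParameters(fit@space))
  expect_true(all(b1@ci[, 1] <= b1@ci[, 2]))
  # with Poisson noise this small, the short interval should still cover Nb
  expect_gt(truth@Nb, b1@ci["Nb", 1] * 0.8)
  expect_lt(truth@Nb, b1@ci["Nb", 2] * 1.2)
})

test_that("bootstrap replicates redraw zero counts as zero", {
  # Poisson(0) is degenerate at 0: a table with an empty top bin keeps it
  # empty in every replicate, so the replicate estimates stay finite
  m <- SinglePopModel(Na = 2000, Nb = 200, Tb = 30, d = 10, Nc = 1e5)
  spec <- SamplingSpec(mode = "IBD")
  lam <- expectedBinCounts(m, spec, oneChromGenome(150), defaultIBDBins(),
                           P = 50)
  K <- round(lam); K[11] <- 0
  ds <- SegmentCountTable(K, defaultIBDBins(), nPairs = 50, sampling = spec)
  fit <- fitModel(ds, "single", seed = 7, control = coarse)
  b <- bootstrapCI(fit, ds, nReplicates = 4, seed = 7, control = coarse)
  expect_equal(nrow(b@diagnostics$bootstrapEstimates), 4L)
})

test_that("model selection is nested, deterministic, and powers up", {
  # strong two-population truth: a narrow subgroup bottleneck feeding half
  # the merged pool
  truth <- TwoPopModel(Na = 20000, Nb = 300, Tb = 46, d = 22, Nc = 1e6,
                       f = 0.5)
  ds <- sampleCounts(truth, SamplingSpec(mode = "IBD"), defaultGenomeMap(),
                     defaultIBDBins(), P = 810264, seed = 71)
  sel <- modelSelectionBootstrap(ds, nReplicates = 9, seed = 8,
                                 control = coarse)
  expect_gte(sel$delta, -1e-6)               # nesting, up to optimizer noise
  expect_equal(sel$p, 1 / 10)                # minimum attainable p
  expect_length(sel$deltaNull, 9L)

  sel2 <- modelSelectionBootstrap(ds, nReplicates = 9, seed = 8,
                                  control = coarse)
  expect_identical(sel$deltaNull, sel2$deltaNull)
})
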