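# Piecewise size histories and discrete-generation coalescence PMFs.

test_that("sizeAt follows the epoch boundaries and exponential interpolation", {
  m <- studyModel()
  expect_equal(sizeAt(m, m@Tb), m@Na)        # boundary belongs to ancestral
  expect_equal(sizeAt(m, 30), 1563)
  expect_equal(sizeAt(m, m@Tb - m@d), 1563)  # boundary belongs to bottleneck
  expect_equal(sizeAt(m, 0), m@Nc)
  # closed-form midpoint of the exponential epoch
  m2 <- SinglePopModel(Na = 10000, Nb = 100, Tb = 41, d = 20, Nc = 10000)
  expect_equal(sizeAt(m2, 10.5), 1000)
  expect_error(sizeAt(m, -1), "t must be")
})

test_that("two-population sizeAt needs a subgroup inside the split epoch", {
  m <- splitModel()
  expect_equal(sizeAt(m, m@Tb + 1), m@Na)
  expect_equal(sizeAt(m, 30, subpop = "bottleneck"), m@Nb)
  expect_equal(sizeAt(m, 30, subpop = "other"), m@Na - m@Nb)
  expect_error(sizeAt(m, 30), "subpop")
  expect_equal(sizeAt(m, 0), m@Nc)           # merged epoch needs no subpop
})

test_that("constant-size PMF is exactly geometric", {
  pmf <- coalescentPMF(constModel(N = 500),
                       SamplingSpec(mode = "IBD"), Umax = 200)
  q <- pmfMasses(pmf)
  expect_equal(q, dgeom(0:199, 1 / 1000), tolerance = 1e-14)
  expect_equal(tailMass(pmf), (1 - 1 / 1000)^200, tolerance = 1e-12)
})

test_that("the no-recent-coalescence constraint zeroes the first hazards", {
  pmf <- coalescentPMF(constModel(N = 500), SamplingSpec(mode = "ROH"))
  q <- pmfMasses(pmf)
  expect_identical(q[1:2], c(0, 0))
  expect_equal(q[3], 1 / 1000)
})

test_that("PMF normalization holds across random models and samplings", {
  set.seed(11)
  for (i in 1:20) {
    m <- randomModel()
    spec <- if (i %% 2 == 0) SamplingSpec(mode = "IBD")
            else SamplingSpec(sampleTime = sample(0:30, 1), mode = "ROH",
                              kappa = runif(1, 0, 0.5))
    pmf <- coalescentPMF(m, spec, Umax = ceiling(m@Tb + 3 * m@Na))
    expect_lt(abs(sum(pmfMasses(pmf)) + tailMass(pmf) - 1), 1e-10)
  }
})

test_that("halving the bottleneck size never decreases bottleneck-epoch mass", {
  set.seed(12)
  for (i in 1:10) {
    m <- randomModel()
    m2 <- SinglePopModel(Na = m@Na, Nb = m@Nb / 2, Tb = m@Tb, d = m@d,
                         Nc = max(m@Nc, m@Nb))
    spec <- SamplingSpec(mode = "IBD")
    epoch <- function(mm) {
      pmf <- coalescentPMF(mm, spec, Umax = ceiling(mm@Tb + 10))
      u <- seq_along(pmfMasses(pmf))
      sum(pmfMasses(pmf)[u > mm@Tb - mm@d & u <= mm@Tb])
    }
    expect_gte(epoch(m2), epoch(m))
  }
})

test_that("degenerate merge (f = 1, Ng = Nb) reproduces the single-population PMF", {
  tp <- TwoPopModel(Na = 2000, Nb = 300, Tb = 30, d = 10, Nc = 5e4, f = 1,
                    Ng = 300)
  sp <- SinglePopModel(Na = 2000, Nb = 300, Tb = 30, d = 10, Nc = 5e4)
  for (spec in list(SamplingSpec(mode = "IBD"),
                    SamplingSpec(sampleTime = 5, mode = "ROH",
                                 subpop = "bottleneck"))) {
    p1 <- twoPopCoalescentPMF(tp, spec, Umax = 500)
    p2 <- coalescentPMF(sp, spec, Umax = 500)
    expect_equal(pmfMasses(p1), pmfMasses(p2), tolerance = 1e-12)
    expect_equal(tailMass(p1), tailMass(p2), tolerance = 1e-12)
  }
})

test_that("split-state mass approaches f^2 scaling as the other group grows", {
  # with Na -> inf, coalescence during the split epoch comes only from the
  # both-in-Nb state entered with probability f^2
  f <- 0.6; Nb <- 100; Tb <- 30; d <- 10
  # huge Na, Ng and Nc make every hazard outside the both-in-Nb state
  # negligible
  big <- TwoPopModel(Na = 1e7, Nb = Nb, Tb = Tb, d = d, Nc = 1e7, f = f,
                     Ng = 1e7)
  spec <- SamplingSpec(mode = "IBD")
  pmf <- twoPopCoalescentPMF(big, spec, Umax = Tb + 5)
  # generation u is evaluated at t = u; split-epoch generations are
  # Tb - d <= u < Tb (t = Tb already belongs to the ancestral epoch)
  u <- seq_len(Tb + 5)
  splitMass <- sum(pmfMasses(pmf)[u >= Tb - d & u < Tb])
  # epoch mass under hazard 1/(2 Nb) alone, discounted by recent-epoch
  # survival (negligible here)
  h <- 1 / (2 * Nb)
  expect_equal(splitMass, f^2 * (1 - (1 - h)^d), tolerance = 1e-4)
})

test_that("per-generation lineage simulation matches both PMFs", {
  set.seed(21)
  nReps <- 2e5
  m <- SinglePopModel(Na = 200, Nb = 60, Tb = 12, d = 6, Nc = 1000)
  spec <- SamplingSpec(mode = "IBD")
  mc <- lineageMC(m, spec, Umax = 60, nReps = nReps)
  q <- pmfMasses(coalescentPMF(m, spec, Umax = 60))
  z <- (mc$freq - q) / pmax(sqrt(q * (1 - q) / nReps), 1e-12)
  expect_lt(max(abs(z)), 4.5)

  tp <- TwoPopModel(Na = 200, Nb = 50, Tb = 12, d = 6, Nc = 400, f = 0.6,
                    Ng = 70)
  mc2 <- lineageMC(tp, spec, Umax = 60, nReps = nReps)
  q2 <- pmfMasses(twoPopCoalescentPMF(tp, spec, Umax = 60))
  z2 <- (mc2$freq - q2) / pmax(sqrt(q2 * (1 - q2) / nReps), 1e-12)
  expect_lt(max(abs(z2)), 4.5)
})

test_that("ancient sampling inside the split epoch is handled", {
  # sampled at 26 with split epoch [24, 46): the remaining split-epoch
  # generations before the ancestral epoch are 1..19 at the subgroup hazard
  tp <- TwoPopModel(Na = 1000, Nb = 100, Tb = 46, d = 22, Nc = 1e5,
                    f = 0.52, Ng = 100)
  spec <- SamplingSpec(sampleTime = 26, mode = "ROH", subpop = "bottleneck")
  q <- pmfMasses(twoPopCoalescentPMF(tp, spec, Umax = 100))
  h <- 1 / 200
  expect_identical(q[1:2], c(0, 0))
  expect_equal(q[3], h)
  expect_equal(q[19], h * (1 - h)^16)          # last split-epoch generation
  expect_equal(q[20], (1 / 2000) * (1 - h)^17) # first ancestral generation
})

test_that("consanguinity mixes a pedigree point mass into the PMF", {
  m <- constModel(N = 500)
  base <- coalescentPMF(m, SamplingSpec(mode = "ROH"))
  same <- applyConsanguinity(base, SamplingSpec(mode = "ROH", kappa = 0))
  expect_identical(pmfMasses(same), pmfMasses(base))

  full <- applyConsanguinity(base, SamplingSpec(mode = "ROH", kappa = 1))
  expect_equal(pmfMasses(full)[3], pmfMasses(base)[3] * 15 / 16 + 1 / 16)
  expect_equal(pmfMasses(full)[-3], pmfMasses(base)[-3] * 15 / 16)

  half <- applyConsanguinity(base, SamplingSpec(mode = "ROH", kappa = 0.5))
  expect_lt(abs(sum(pmfMasses(half)) + tailMass(half) - 1), 1e-10)
  expect_error(applyConsanguinity(base, SamplingSpec(mode = "IBD")),
               "ROH")
})

test_that("degenerate inputs are rejected", {
  expect_error(SinglePopModel(Na = 100, Nb = 200, Tb = 10, d = 5, Nc = 300))
  expect_error(SinglePopModel(Na = 100, Nb = 50, Tb = 10, d = 12, Nc = 100))
  expect_error(TwoPopModel(Na = 100, Nb = 100, Tb = 10, d = 5, Nc = 100,
                           f = 0.5))
  # sizes below one diploid individual imply hazards above 0.5
  tiny <- SinglePopModel(Na = 10, Nb = 0.5, Tb = 10, d = 5, Nc = 10)
  expect_error(coalescentPMF(tiny, SamplingSpec(), Umax = 100), "N\\(t\\) < 1")
  # ROH under a two-population model needs a subgroup
  expect_error(twoPopCoalescentPMF(splitModel(),
                                   SamplingSpec(sampleTime = 26,
                                                mode = "ROH"), Umax = 200),
               "subpop")
  expect_error(SamplingSpec(mode = "IBD", kappa = 0.1), "ROH")
})
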