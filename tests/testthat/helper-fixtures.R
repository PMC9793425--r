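# Shared fixtures: small models and maps used across the suite.

constModel <- function(N = 500, Tb = 10, d = 5)
  SinglePopModel(Na = N, Nb = N, Tb = Tb, d = d, Nc = N)

studyModel <- function()
  SinglePopModel(Na = 10000, Nb = 1563, Tb = 41, d = 20, Nc = 1e6)

splitModel <- function()
  TwoPopModel(Na = 10000, Nb = 627, Tb = 46, d = 22, Nc = 1e6, f = 0.52)

oneChromGenome <- function(L_cM = 100) GenomeMap(c(chr1 = L_cM))

# random valid single-population model under a seeded stream
randomModel <- function() {
  Na <- runif(1, 200, 5000)
  Nb <- runif(1, 50, Na)
  Tb <- runif(1, 10, 60)
  d <- runif(1, 1, Tb - 1)
  Nc <- runif(1, Nb, 1e6)
  SinglePopModel(Na = Na, Nb = Nb, Tb = Tb, d = d, Nc = Nc)
}

# per-generation Bernoulli lineage simulation: the independent oracle for
# the coalescent PMFs.  Explicit subpopulation states for two-pop models.
lineageMC <- function(model, sampling, Umax, nReps) {
  ts <- sampling@sampleTime
  TbD <- model@Tb - model@d
  twoPop <- is(model, "TwoPopModel")
  if (twoPop && sampling@mode == "IBD") {
    g1 <- runif(nReps) < model@f
    g2 <- runif(nReps) < model@f
  } else if (twoPop) {
    inB <- identical(sampling@subpop, "bottleneck")
    g1 <- g2 <- rep(inB, nReps)
  }
  coalAt <- rep(NA_integer_, nReps)
  alive <- rep(TRUE, nReps)
  for (u in seq_len(Umax)) {
    t <- ts + u
    h <- if (u <= sampling@noRecentCoalescence) {
      rep(0, nReps)
    } else if (t >= model@Tb) {
      rep(1 / (2 * model@Na), nReps)
    } else if (t >= TbD) {
      if (twoPop)
        ifelse(g1 == g2,
               ifelse(g1, 1 / (2 * model@Nb),
                      1 / (2 * (model@Na - model@Nb))), 0)
      else rep(1 / (2 * model@Nb), nReps)
    } else {
      Nstart <- if (twoPop) model@Ng else model@Nb
      rep(1 / (2 * model@Nc * (Nstart / model@Nc)^(t / TbD)), nReps)
    }
    co <- alive & (runif(nReps) < h)
    coalAt[co] <- u
    alive <- alive & !co
  }
  list(freq = tabulate(coalAt, nbins = Umax) / nReps,
       tail = mean(is.na(coalAt)))
}

rohRecords <- function(starts, ends, sample = "s1", chrom = "chr1")
  data.frame(sample = sample, chromosome = chrom, start_cM = starts,
             end_cM = ends, length_cM = ends - starts)
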