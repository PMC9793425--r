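## Synthetic data with the statistical structure the analysis assumes:
## Poisson binned counts from any model (the generative convention used by
## the parametric bootstrap), and a segment-level Monte-Carlo simulator that
## serves as the independent oracle for the closed-form expectations.

#' Draw a synthetic binned count table from a model
#'
#' \code{K_b ~ Poisson(lambda_b)} independently per bin, with
#' \code{lambda_b} from [expectedBinCounts()].
#'
#' @param model a [SinglePopModel-class] or [TwoPopModel-class].
#' @param sampling a [SamplingSpec-class].
#' @param genome a [GenomeMap-class].
#' @param bins a [LengthBins-class].
#' @param P number of haplotype pairs.
#' @param seed integer seed.
#' @param nIndividuals optional cohort size recorded in the table.
#' @param label cohort label.
#' @return A [SegmentCountTable-class].
#' @export
sampleCounts <- function(model, sampling, genome, bins, P, seed,
                         nIndividuals = NA_real_, label = "") {
  lambda <- expectedBinCounts(model, sampling, genome, bins, P)
  K <- .withSeed(seed, stats::rpois(length(lambda), lambda))
  SegmentCountTable(counts = K, bins = bins, nIndividuals = nIndividuals,
                    nPairs = P, sampling = sampling, label = label)
}

#' Monte-Carlo segment-level simulator (independent oracle)
#'
#' For each haplotype pair, draws a TMRCA \code{u} from the model's
#' coalescence-time distribution (tail included, by inverse transform on the
#' geometric tail), then, per chromosome, places \code{Poisson(2 u L)}
#' recombination breakpoints uniformly and emits every inter-breakpoint
#' interval — terminal intervals and the whole chromosome when no breakpoint
#' falls — as a segment.  The TMRCA is held constant along the genome of a
#' pair, which is exactly the approximation the closed-form expectation
#' makes, so the two must agree.
#'
#' Pairs whose TMRCA is so old that the probability of any segment reaching
#' \code{minLengthCM} is below ~1e-12 are emitted with no records (they
#' still count towards \code{nPairs}); with \code{minLengthCM = 0} every
#' segment of every pair is emitted.
#'
#' @param model a [SinglePopModel-class] or [TwoPopModel-class].
#' @param sampling a [SamplingSpec-class].
#' @param genome a [GenomeMap-class].
#' @param nPairs number of haplotype pairs to simulate.
#' @param seed integer seed.
#' @param minLengthCM emit only segments at least this long (cM); 0 emits
#'   everything.
#' @return Segment records (data.frame with \code{sample} = pair id,
#'   \code{chromosome}, \code{start_cM}, \code{end_cM}, \code{length_cM})
#'   with attribute \code{nPairs}.
#' @examples
#' g <- GenomeMap(c(chr1 = 100))
#' m <- SinglePopModel(Na = 100, Nb = 100, Tb = 10, d = 5, Nc = 100)
#' segs <- simulateSegmentsMC(m, SamplingSpec(), g, nPairs = 10, seed = 1)
#' @export
simulateSegmentsMC <- function(model, sampling, genome, nPairs, seed,
                               minLengthCM = 0) {
  stopifnot(nPairs >= 1)
  pmf <- coalescentPMF(model, sampling)
  .withSeed(seed, {
    u <- .drawTmrca(pmf, nPairs)
    .segmentsForTmrca(u, genome, minLengthCM)
  })
}

## inverse-transform draw of TMRCAs from a CoalescentPMF (tail geometric)
.drawTmrca <- function(pmf, n) {
  U <- length(pmf@q)
  probs <- c(pmf@q, pmf@tailMass)
  u <- sample.int(U + 1L, n, replace = TRUE, prob = probs)
  inTail <- u == U + 1L
  if (any(inTail))
    u[inTail] <- U + 1L + stats::rgeom(sum(inTail), pmf@tailRate)
  u
}

## breakpoint simulation for given per-pair TMRCAs; uses the fact that the
## spacings of n uniform points on (0, L) are L times n+1 normalized
## exponentials, avoiding any per-pair sorting
.segmentsForTmrca <- function(u, genome, minLengthCM = 0) {
  genomeM <- chromLengths(genome) / .CM_PER_MORGAN
  chromNames <- names(genomeM)
  if (is.null(chromNames)) chromNames <- paste0("chr", seq_along(genomeM))
  a <- 2 * u
  ## skip pairs that cannot plausibly yield a segment >= minLengthCM:
  ## P(any) <= sum_c (1 + a L_c) e^{-a lmin} < 1e-12
  active <- rep(TRUE, length(u))
  if (minLengthCM > 0) {
    lmin <- minLengthCM / .CM_PER_MORGAN
    bound <- exp(-a * lmin) * (length(genomeM) + a * max(genomeM))
    active <- bound > 1e-12
  }
  idx <- which(active)
  out <- vector("list", length(genomeM))
  for (ci in seq_along(genomeM)) {
    L <- genomeM[ci]
    nb <- stats::rpois(length(idx), a[idx] * L)
    k <- nb + 1L                      # segments = breakpoints + 1
    grp <- rep.int(seq_along(idx), k)
    e <- stats::rexp(sum(k))
    tot <- as.numeric(rowsum(e, grp))
    len <- e / tot[grp] * L
    endM <- stats::ave(len, grp, FUN = cumsum)
    keep <- len * .CM_PER_MORGAN >= minLengthCM
    if (!any(keep)) next
    out[[ci]] <- data.frame(
      sample = paste0("pair", idx[grp[keep]]),
      chromosome = chromNames[ci],
      start_cM = (endM[keep] - len[keep]) * .CM_PER_MORGAN,
      end_cM = endM[keep] * .CM_PER_MORGAN,
      length_cM = len[keep] * .CM_PER_MORGAN)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(sample = character(), chromosome = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      length_cM = numeric())
  rownames(res) <- NULL
  attr(res, "nPairs") <- length(u)
  res
}

#' Binned Monte-Carlo segment counts with standard errors
#'
#' Runs [simulateSegmentsMC()] in chunks, bins every chunk, and accumulates
#' the per-pair mean count and its standard error per bin — the quantities
#' needed to compare the simulator against [expectedBinCounts()].
#'
#' @param model,sampling,genome,seed as in [simulateSegmentsMC()].
#' @param bins a [LengthBins-class].
#' @param nPairs total number of simulated pairs.
#' @param chunk pairs per chunk (memory bound).
#' @param tmrca optional fixed TMRCA (point mass) instead of drawing from
#'   the model's PMF.
#' @return A list with \code{meanPerPair}, \code{se} (per bin) and
#'   \code{nPairs}.
#' @export
mcBinnedCounts <- function(model, sampling, genome, bins, nPairs, seed,
                           chunk = 2000L, tmrca = NULL) {
  edges <- binEdges(bins)
  nb <- length(edges) - 1L
  pmf <- if (is.null(tmrca)) coalescentPMF(model, sampling) else NULL
  sums <- numeric(nb); sqs <- numeric(nb)
  done <- 0L
  .withSeed(seed, {
    while (done < nPairs) {
      m <- min(chunk, nPairs - done)
      u <- if (is.null(tmrca)) .drawTmrca(pmf, m) else rep(tmrca, m)
      segs <- .segmentsForTmrca(u, genome, minLengthCM = edges[1])
      counts <- matrix(0, m, nb)
      if (nrow(segs) > 0) {
        pair <- as.integer(sub("^pair", "", segs$sample))
        bin <- findInterval(segs$length_cM, edges)
        ok <- bin >= 1L & bin <= nb
        tab <- tabulate((bin[ok] - 1L) * m + pair[ok], nbins = m * nb)
        counts <- matrix(tab, m, nb)
      }
      sums <- sums + colSums(counts)
      sqs <- sqs + colSums(counts^2)
      done <- done + m
    }
  })
  mean <- sums / nPairs
  se <- sqrt(pmax(sqs / nPairs - mean^2, 0) / nPairs)
  list(meanPerPair = stats::setNames(mean, .binLabels(bins)),
       se = stats::setNames(se, .binLabels(bins)), nPairs = nPairs)
}

#' Generate a matched modern-IBD + ancient-ROH synthetic study
#'
#' Emits a modern IBD count table (sampled at present) and an ancient ROH
#' count table (sampled \code{tsAncient} generations ago, with no
#' coalescence allowed in the two generations before sampling), both drawn
#' from the same demographic model with full metadata.  The default
#' configuration is shaped like the study the package targets: a
#' two-subpopulation split/merge bottleneck (split 46 generations ago for 22
#' generations, ancient subgroup size 627, merge fraction 0.52), a modern
#' cohort of 637 diploid individuals (810,264 IBD haplotype pairs) and an
#' ancient cohort of 16 individuals sampled 26 generations ago.
#'
#' @param config optional list overriding any of: \code{model} (a
#'   [DemographicModel-class]), \code{nModern}, \code{nAncient},
#'   \code{tsAncient}, \code{ibdBins}, \code{rohBins}, \code{kappa}
#'   (ancient-cohort consanguinity fraction), \code{rohSubpop}.
#' @param seed integer seed.
#' @param genome a [GenomeMap-class].
#' @return A [SyntheticStudy-class].
#' @examples
#' study <- generateStudy(seed = 1)
#' nPairs(study@ibd)  # 810264
#' @export
generateStudy <- function(config = list(), seed = 1,
                          genome = defaultGenomeMap()) {
  cfg <- utils::modifyList(list(
    model = TwoPopModel(Na = 10000, Nb = 627, Tb = 46, d = 22, Nc = 1e6,
                        f = 0.52),
    nModern = 637, nAncient = 16, tsAncient = 26,
    ibdBins = defaultIBDBins(), rohBins = defaultAncientROHBins(),
    kappa = 0, rohSubpop = "bottleneck"), config)
  ibdSpec <- SamplingSpec(sampleTime = 0, mode = "IBD")
  rohSpec <- SamplingSpec(sampleTime = cfg$tsAncient, mode = "ROH",
                          kappa = cfg$kappa,
                          subpop = if (is(cfg$model, "TwoPopModel"))
                            cfg$rohSubpop else NA_character_)
  ibd <- sampleCounts(cfg$model, ibdSpec, genome, cfg$ibdBins,
                      P = pairCount(cfg$nModern, "IBD"),
                      seed = as.integer(seed),
                      nIndividuals = cfg$nModern, label = "modern IBD")
  roh <- sampleCounts(cfg$model, rohSpec, genome, cfg$rohBins,
                      P = pairCount(cfg$nAncient, "ROH"),
                      seed = as.integer(seed) + 1L,
                      nIndividuals = cfg$nAncient, label = "ancient ROH")
  new("SyntheticStudy", ibd = ibd, roh = roh, model = cfg$model,
      genome = genome, seed = as.integer(seed))
}
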