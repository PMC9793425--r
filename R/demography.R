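## Discrete-generation coalescence machinery.
##
## Conventions (used consistently everywhere):
##  * time t is measured in generations before present; epoch boundaries are
##    half-open and closed on the older side, so t = Tb belongs to the
##    ancestral epoch and t = Tb - d to the bottleneck/split epoch;
##  * generation u (counted before the sampling time ts) spans (u-1, u] and
##    its hazard is evaluated at the integer time ts + u;
##  * hazards above 0.5 (sizes below 1) are rejected as degenerate.

## ---- sizeAt ----------------------------------------------------------------

#' @rdname sizeAt
setMethod("sizeAt", "SinglePopModel", function(model, t, subpop = NA_character_) {
  if (any(t < 0)) stop("t must be >= 0 (generations before present)")
  TbD <- model@Tb - model@d
  n <- numeric(length(t))
  n[t >= model@Tb] <- model@Na
  n[t >= TbD & t < model@Tb] <- model@Nb
  recent <- t < TbD
  ## exponential interpolation: Nc at t = 0, Nb at t = Tb - d
  n[recent] <- model@Nc * (model@Nb / model@Nc)^(t[recent] / TbD)
  n
})

#' @rdname sizeAt
setMethod("sizeAt", "TwoPopModel", function(model, t, subpop = NA_character_) {
  if (any(t < 0)) stop("t must be >= 0 (generations before present)")
  TbD <- model@Tb - model@d
  inSplit <- t >= TbD & t < model@Tb
  if (any(inSplit) && is.na(subpop))
    stop("subpop ('bottleneck' or 'other') is required inside the split epoch")
  n <- numeric(length(t))
  n[t >= model@Tb] <- model@Na
  n[inSplit] <- if (identical(subpop, "other")) model@Na - model@Nb else model@Nb
  recent <- t < TbD
  ## merged epoch: Nc at t = 0, Ng at t = Tb - d
  n[recent] <- model@Nc * (model@Ng / model@Nc)^(t[recent] / TbD)
  n
})

## ---- hazards and PMFs ------------------------------------------------------

## Per-generation masses for a single-population model; plain numeric hot
## path shared by the S4 constructors and the likelihood machinery.
## Returns list(q, tail, tailRate).
.pmfSingle <- function(Na, Nb, Tb, d, Nc, ts, noRecent, Umax) {
  if (Umax + ts <= Tb)
    stop("Umax + sampleTime must exceed Tb (reach the ancestral epoch)")
  t <- ts + seq_len(Umax)
  TbD <- Tb - d
  N <- numeric(Umax)
  N[t >= Tb] <- Na
  mid <- t >= TbD & t < Tb
  N[mid] <- Nb
  recent <- t < TbD
  if (any(recent)) N[recent] <- Nc * (Nb / Nc)^(t[recent] / TbD)
  if (any(N < 1))
    stop("model implies N(t) < 1 (hazard > 0.5): degenerate size history")
  h <- 1 / (2 * N)
  if (noRecent > 0) h[seq_len(min(noRecent, Umax))] <- 0
  surv <- cumprod(1 - h)
  q <- h * c(1, surv[-Umax])
  list(q = q, tail = surv[Umax], tailRate = 1 / (2 * Na))
}

## Two-population split/merge masses.  The two lineages are tracked through
## three states during the split epoch: both in the Nb subgroup (hazard
## 1/(2 Nb)), both in the other subgroup (hazard 1/(2 (Na - Nb))), or split
## across subgroups (hazard 0).  State weights are fixed at entry -- (f^2,
## (1-f)^2, 2 f (1-f)) for IBD, or a point mass for ROH with a declared
## subgroup -- and because all three states share identical hazards outside
## the split epoch, weighting from generation 1 is exact.
.pmfTwoPop <- function(Na, Nb, Tb, d, Nc, f, Ng, ts, noRecent, mode, subpop,
                       Umax) {
  if (Umax + ts <= Tb)
    stop("Umax + sampleTime must exceed Tb (reach the ancestral epoch)")
  if (mode == "ROH" && ts < Tb && is.na(subpop))
    stop("ROH mode under a two-population model requires a subpop assignment")
  No <- Na - Nb
  if (No <= 0) stop("two-population model requires Nb < Na")
  t <- ts + seq_len(Umax)
  TbD <- Tb - d
  anc <- t >= Tb
  split <- t >= TbD & t < Tb
  recent <- t < TbD
  Nmerged <- numeric(Umax)
  if (any(recent)) Nmerged[recent] <- Nc * (Ng / Nc)^(t[recent] / TbD)
  if (any(c(Na, Nb, No, Ng, Nc, Nmerged[recent]) < 1))
    stop("model implies N(t) < 1 (hazard > 0.5): degenerate size history")

  base <- numeric(Umax)                  # shared hazard outside split epoch
  base[anc] <- 1 / (2 * Na)
  base[recent] <- 1 / (2 * Nmerged[recent])
  hB <- base; hB[split] <- 1 / (2 * Nb)  # both lineages in the Nb subgroup
  hO <- base; hO[split] <- 1 / (2 * No)  # both in the other subgroup
  hS <- base; hS[split] <- 0             # split across subgroups
  if (noRecent > 0) {
    idx <- seq_len(min(noRecent, Umax))
    hB[idx] <- 0; hO[idx] <- 0; hS[idx] <- 0
  }

  w <- if (mode == "ROH" && !is.na(subpop)) {
    if (subpop == "bottleneck") c(1, 0, 0) else c(0, 1, 0)
  } else {
    c(f^2, (1 - f)^2, 2 * f * (1 - f))
  }

  comp <- function(h) {
    surv <- cumprod(1 - h)
    list(q = h * c(1, surv[-Umax]), tail = surv[Umax])
  }
  cB <- comp(hB); cO <- comp(hO); cS <- comp(hS)
  list(q = w[1] * cB$q + w[2] * cO$q + w[3] * cS$q,
       tail = w[1] * cB$tail + w[2] * cO$tail + w[3] * cS$tail,
       tailRate = 1 / (2 * Na))
}

## Dispatch on a named parameter vector + SamplingSpec; used by likelihoods.
.pmfRaw <- function(params, type, sampling, Umax) {
  if (type == "single")
    raw <- .pmfSingle(params[["Na"]], params[["Nb"]], params[["Tb"]],
                      params[["d"]], params[["Nc"]], sampling@sampleTime,
                      sampling@noRecentCoalescence, Umax)
  else
    raw <- .pmfTwoPop(params[["Na"]], params[["Nb"]], params[["Tb"]],
                      params[["d"]], params[["Nc"]], params[["f"]],
                      if ("Ng" %in% names(params)) params[["Ng"]] else params[["Nb"]],
                      sampling@sampleTime, sampling@noRecentCoalescence,
                      sampling@mode, sampling@subpop, Umax)
  if (sampling@kappa > 0) raw <- .mixConsanguinity(raw, sampling)
  raw
}

## kappa-weighted pedigree-loop mixture on the raw (q, tail) representation.
.mixConsanguinity <- function(raw, sampling) {
  k <- sampling@kappa * sampling@pedigreeLoopProb
  lt <- sampling@pedigreeLoopTime
  if (lt > length(raw$q))
    stop("pedigreeLoopTime exceeds the PMF support")
  q <- (1 - k) * raw$q
  q[lt] <- q[lt] + k
  list(q = q, tail = (1 - k) * raw$tail, tailRate = raw$tailRate)
}

#' Pairwise coalescence-time distribution under a demographic model
#'
#' Computes the discrete-generation probability mass function of the TMRCA
#' of two lineages sampled according to \code{sampling}, under a
#' single-population ([coalescentPMF()]) or two-subpopulation
#' ([twoPopCoalescentPMF()]) size history.  The per-generation coalescence
#' hazard is \code{1/(2 N(t))}; mass beyond \code{Umax} is carried
#' analytically as a geometric tail at rate \code{1/(2 Na)} in the constant
#' ancestral epoch.  If the sampling spec has \code{kappa > 0} (ROH mode),
#' the returned PMF is the consanguinity mixture of [applyConsanguinity()].
#'
#' @param model a [SinglePopModel-class] (or, for
#'   \code{twoPopCoalescentPMF}, a [TwoPopModel-class]).
#' @param sampling a [SamplingSpec-class].
#' @param Umax truncation point in generations before sampling; default
#'   \code{Tb + 5 Na - sampleTime}, i.e. five ancestral sizes past the
#'   bottleneck onset.
#' @return A [CoalescentPMF-class].
#' @examples
#' m <- SinglePopModel(Na = 500, Nb = 500, Tb = 10, d = 5, Nc = 500)
#' pmf <- coalescentPMF(m, SamplingSpec(mode = "ROH"))
#' pmfMasses(pmf)[1:4]  # 0, 0, 1/1000, ...
#' @rdname coalescentPMF
setMethod("coalescentPMF", "SinglePopModel",
          function(model, sampling, Umax = NULL) {
  Umax <- .defaultUmax(model, sampling, Umax)
  raw <- .pmfRaw(c(Na = model@Na, Nb = model@Nb, Tb = model@Tb, d = model@d,
                   Nc = model@Nc), "single", sampling, Umax)
  new("CoalescentPMF", q = raw$q, tailMass = raw$tail,
      tailRate = raw$tailRate, sampleTime = sampling@sampleTime)
})

#' @rdname coalescentPMF
setMethod("coalescentPMF", "TwoPopModel",
          function(model, sampling, Umax = NULL)
  twoPopCoalescentPMF(model, sampling, Umax))

#' @rdname coalescentPMF
#' @export
twoPopCoalescentPMF <- function(model, sampling, Umax = NULL) {
  stopifnot(is(model, "TwoPopModel"))
  Umax <- .defaultUmax(model, sampling, Umax)
  raw <- .pmfRaw(c(Na = model@Na, Nb = model@Nb, Tb = model@Tb, d = model@d,
                   Nc = model@Nc, f = model@f, Ng = model@Ng),
                 "two_pop", sampling, Umax)
  new("CoalescentPMF", q = raw$q, tailMass = raw$tail,
      tailRate = raw$tailRate, sampleTime = sampling@sampleTime)
}

.defaultUmax <- function(model, sampling, Umax) {
  if (is.null(Umax))
    Umax <- ceiling(model@Tb + 5 * model@Na - sampling@sampleTime)
  as.integer(Umax)
}

#' Consanguinity mixture of a coalescence-time distribution
#'
#' Models a fraction \code{kappa} of individuals as children of first-cousin
#' couples: with probability \code{pedigreeLoopProb} (1/16 for first
#' cousins) such an individual's two lineages coalesce through the pedigree
#' loop exactly \code{pedigreeLoopTime} generations before sampling;
#' otherwise (and for the non-consanguineous fraction) the population PMF
#' applies.  ROH mode only.
#'
#' @param pmf a [CoalescentPMF-class].
#' @param sampling a [SamplingSpec-class] with \code{mode = "ROH"}.
#' @return The mixed [CoalescentPMF-class].
#' @examples
#' m <- SinglePopModel(Na = 500, Nb = 500, Tb = 10, d = 5, Nc = 500)
#' pmf <- coalescentPMF(m, SamplingSpec(mode = "ROH"))
#' mixed <- applyConsanguinity(pmf, SamplingSpec(mode = "ROH", kappa = 1))
#' @export
applyConsanguinity <- function(pmf, sampling) {
  stopifnot(is(pmf, "CoalescentPMF"), is(sampling, "SamplingSpec"))
  if (sampling@mode != "ROH")
    stop("consanguinity applies to ROH mode only")
  if (sampling@kappa == 0) return(pmf)
  raw <- .mixConsanguinity(list(q = pmf@q, tail = pmf@tailMass,
                                tailRate = pmf@tailRate), sampling)
  new("CoalescentPMF", q = raw$q, tailMass = raw$tail,
      tailRate = raw$tailRate, sampleTime = pmf@sampleTime)
}
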