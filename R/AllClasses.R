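#' @import methods
NULL

## ---------------------------------------------------------------------------
## Demographic models
## ---------------------------------------------------------------------------

#' Virtual parent of the demographic model classes
#'
#' @seealso [SinglePopModel()], [TwoPopModel()]
#' @exportClass DemographicModel
setClass("DemographicModel", representation("VIRTUAL"))

#' Single-population bottleneck-then-expansion demography
#'
#' A piecewise size history of diploid effective sizes: a constant ancestral
#' population of size \code{Na}, a bottleneck of size \code{Nb} starting
#' \code{Tb} generations before present and lasting \code{d} generations, and
#' an exponential expansion from \code{Nb} at the end of the bottleneck to
#' \code{Nc} at present.  Epoch boundaries are half-open and closed on the
#' older side: time \code{t = Tb} belongs to the ancestral epoch and
#' \code{t = Tb - d} to the bottleneck.
#'
#' @slot Na ancestral diploid effective size.
#' @slot Nb bottleneck diploid effective size.
#' @slot Tb onset of the bottleneck, generations before present.
#' @slot d duration of the bottleneck, generations.
#' @slot Nc present-day diploid effective size.
#'
#' @param Na,Nb,Tb,d,Nc model parameters, see slots.
#' @return A \code{SinglePopModel} object.
#' @examples
#' m <- SinglePopModel(Na = 10000, Nb = 1563, Tb = 41, d = 20, Nc = 1e6)
#' sizeAt(m, 30)
#' @export SinglePopModel
#' @exportClass SinglePopModel
SinglePopModel <- function(Na, Nb, Tb, d, Nc) {
  new("SinglePopModel", Na = Na, Nb = Nb, Tb = Tb, d = d, Nc = Nc)
}

setClass("SinglePopModel",
  contains = "DemographicModel",
  representation(Na = "numeric", Nb = "numeric", Tb = "numeric",
                 d = "numeric", Nc = "numeric"))

setValidity("SinglePopModel", function(object) {
  p <- c(Na = object@Na, Nb = object@Nb, Tb = object@Tb,
         d = object@d, Nc = object@Nc)
  if (any(lengths(list(object@Na, object@Nb, object@Tb, object@d,
                       object@Nc)) != 1L) || any(!is.finite(p)))
    return("all parameters must be finite scalars")
  msg <- character()
  if (p["Na"] <= 0) msg <- c(msg, "Na must be positive")
  if (p["Nb"] <= 0 || p["Nb"] > p["Na"])
    msg <- c(msg, "Nb must satisfy 0 < Nb <= Na")
  if (p["d"] <= 0 || p["d"] >= p["Tb"])
    msg <- c(msg, "d must satisfy 0 < d < Tb")
  if (p["Nc"] < p["Nb"]) msg <- c(msg, "Nc must be >= Nb")
  if (length(msg)) msg else TRUE
})

#' Two-subpopulation split/merge bottleneck demography
#'
#' Extends [SinglePopModel-class]: at the onset of the bottleneck,
#' \code{Tb} generations ago, the ancestral population of size \code{Na}
#' splits into a subgroup of size \code{Nb} (the one represented by the
#' ancient sample) and another of size \code{Na - Nb}.  At the end of the
#' bottleneck the two merge with proportions \code{f} and \code{1 - f},
#' and the merged population expands exponentially from \code{Ng} to
#' \code{Nc} at present.
#'
#' @slot f proportion of the merged gene pool contributed by the
#'   \code{Nb} subgroup.
#' @slot Ng diploid effective size of the merged population at the onset of
#'   the post-merge expansion (defaults to \code{Nb}).
#'
#' @param Na,Nb,Tb,d,Nc as in [SinglePopModel()].
#' @param f merge proportion, in (0, 1).
#' @param Ng merged-epoch starting size; defaults to \code{Nb}.
#' @return A \code{TwoPopModel} object.
#' @examples
#' TwoPopModel(Na = 10000, Nb = 627, Tb = 46, d = 22, Nc = 1e6, f = 0.52)
#' @export TwoPopModel
#' @exportClass TwoPopModel
TwoPopModel <- function(Na, Nb, Tb, d, Nc, f, Ng = Nb) {
  new("TwoPopModel", Na = Na, Nb = Nb, Tb = Tb, d = d, Nc = Nc,
      f = f, Ng = Ng)
}

setClass("TwoPopModel",
  contains = "SinglePopModel",
  representation(f = "numeric", Ng = "numeric"))

setValidity("TwoPopModel", function(object) {
  msg <- character()
  ## f = 1 is allowed as the degenerate merge that reduces to the
  ## single-population model
  if (length(object@f) != 1L || !is.finite(object@f) ||
      object@f <= 0 || object@f > 1)
    msg <- c(msg, "f must be a scalar in (0, 1]")
  if (object@Nb >= object@Na)
    msg <- c(msg, "Nb must be < Na (the other subgroup has size Na - Nb)")
  if (length(object@Ng) != 1L || !is.finite(object@Ng) || object@Ng <= 0)
    msg <- c(msg, "Ng must be a positive scalar")
  if (object@Nc < object@Ng) msg <- c(msg, "Nc must be >= Ng")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SinglePopModel", function(object) {
  cat("SinglePopModel (diploid effective sizes)\n")
  cat(sprintf("  Na = %g, Nb = %g, Nc = %g\n", object@Na, object@Nb, object@Nc))
  cat(sprintf("  bottleneck: starts %g generations ago, lasts %g\n",
              object@Tb, object@d))
})

setMethod("show", "TwoPopModel", function(object) {
  cat("TwoPopModel (split/merge bottleneck)\n")
  cat(sprintf("  Na = %g, Nb = %g (other subgroup %g), Nc = %g, Ng = %g\n",
              object@Na, object@Nb, object@Na - object@Nb, object@Nc,
              object@Ng))
  cat(sprintf("  split %g generations ago for %g generations; merge fraction f = %g\n",
              object@Tb, object@d, object@f))
})

## ---------------------------------------------------------------------------
## Sampling configuration
## ---------------------------------------------------------------------------

#' Sampling configuration for a pair of lineages
#'
#' Describes when and how a pair of haplotypes was sampled: modern or
#' ancient sampling time, IBD (between-individual) or ROH (within-individual)
#' mode, a no-recent-coalescence constraint (no sib mating), and an optional
#' consanguinity mixture for ROH.
#'
#' @slot sampleTime generations before present at which the genomes were
#'   sampled (0 = modern).
#' @slot mode \code{"IBD"} or \code{"ROH"}.
#' @slot noRecentCoalescence number of generations immediately before
#'   sampling with forced zero coalescence hazard (2 for ROH by default,
#'   reflecting no sib mating; 0 for IBD).
#' @slot kappa fraction of individuals whose parents are first cousins
#'   (ROH mode only).
#' @slot pedigreeLoopTime generations before sampling at which pedigree
#'   coalescence occurs for a consanguineous individual.
#' @slot pedigreeLoopProb probability of pedigree coalescence for a
#'   consanguineous individual (1/16 for first-cousin parents).
#' @slot subpop for [TwoPopModel-class] ROH computations, the subgroup both
#'   lineages occupy during the split epoch: \code{"bottleneck"} or
#'   \code{"other"}; \code{NA} otherwise.
#'
#' @param sampleTime,mode,noRecentCoalescence,kappa,pedigreeLoopTime,pedigreeLoopProb,subpop
#'   see slots.
#' @return A \code{SamplingSpec} object.
#' @examples
#' SamplingSpec(sampleTime = 26, mode = "ROH")
#' @export SamplingSpec
#' @exportClass SamplingSpec
SamplingSpec <- function(sampleTime = 0, mode = c("IBD", "ROH"),
                         noRecentCoalescence = NULL, kappa = 0,
                         pedigreeLoopTime = 3, pedigreeLoopProb = 1 / 16,
                         subpop = NA_character_) {
  mode <- match.arg(mode)
  if (is.null(noRecentCoalescence))
    noRecentCoalescence <- if (mode == "ROH") 2L else 0L
  new("SamplingSpec", sampleTime = as.numeric(sampleTime), mode = mode,
      noRecentCoalescence = as.integer(noRecentCoalescence),
      kappa = kappa, pedigreeLoopTime = as.integer(pedigreeLoopTime),
      pedigreeLoopProb = pedigreeLoopProb, subpop = subpop)
}

setClass("SamplingSpec",
  representation(sampleTime = "numeric", mode = "character",
                 noRecentCoalescence = "integer", kappa = "numeric",
                 pedigreeLoopTime = "integer", pedigreeLoopProb = "numeric",
                 subpop = "character"))

setValidity("SamplingSpec", function(object) {
  msg <- character()
  if (object@sampleTime < 0) msg <- c(msg, "sampleTime must be >= 0")
  if (!object@mode %in% c("IBD", "ROH")) msg <- c(msg, "mode must be IBD or ROH")
  if (object@noRecentCoalescence < 0L)
    msg <- c(msg, "noRecentCoalescence must be >= 0")
  if (object@kappa < 0 || object@kappa > 1) msg <- c(msg, "kappa must be in [0, 1]")
  if (object@kappa > 0 && object@mode == "IBD")
    msg <- c(msg, "consanguinity (kappa > 0) applies to ROH mode only")
  if (object@pedigreeLoopProb < 0 || object@pedigreeLoopProb > 1)
    msg <- c(msg, "pedigreeLoopProb must be in [0, 1]")
  if (object@pedigreeLoopTime < 1L) msg <- c(msg, "pedigreeLoopTime must be >= 1")
  if (!is.na(object@subpop) && !object@subpop %in% c("bottleneck", "other"))
    msg <- c(msg, "subpop must be 'bottleneck', 'other' or NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SamplingSpec", function(object) {
  cat(sprintf("SamplingSpec: mode %s, sampled %g generations before present\n",
              object@mode, object@sampleTime))
  cat(sprintf("  no coalescence in first %d generation(s)", object@noRecentCoalescence))
  if (object@kappa > 0)
    cat(sprintf("; consanguinity kappa = %g (loop at %d gen, prob %g)",
                object@kappa, object@pedigreeLoopTime, object@pedigreeLoopProb))
  if (!is.na(object@subpop)) cat(sprintf("; split-epoch subgroup: %s", object@subpop))
  cat("\n")
})

## ---------------------------------------------------------------------------
## Coalescent PMF
## ---------------------------------------------------------------------------

#' Discrete-generation pairwise coalescence-time distribution
#'
#' Probability masses \code{q(u)} that the pair's TMRCA is \code{u}
#' generations before sampling, for \code{u = 1..Umax}, plus the analytic
#' tail: beyond \code{Umax} the remaining mass coalesces geometrically at
#' rate \code{1/(2 Na)} in the constant ancestral epoch.
#'
#' @slot q numeric vector of masses, \code{q[u]} for \code{u = 1..Umax}.
#' @slot tailMass probability of coalescence beyond \code{Umax}.
#' @slot tailRate per-generation coalescence rate of the geometric tail.
#' @slot sampleTime sampling time the masses are relative to.
#'
#' @seealso [coalescentPMF()], [twoPopCoalescentPMF()]
#' @exportClass CoalescentPMF
setClass("CoalescentPMF",
  representation(q = "numeric", tailMass = "numeric", tailRate = "numeric",
                 sampleTime = "numeric"))

setValidity("CoalescentPMF", function(object) {
  msg <- character()
  if (any(object@q < 0)) msg <- c(msg, "all masses q(u) must be >= 0")
  if (object@tailMass < 0) msg <- c(msg, "tailMass must be >= 0")
  if (object@tailRate <= 0 || object@tailRate > 0.5)
    msg <- c(msg, "tailRate must be in (0, 0.5]")
  tot <- sum(object@q) + object@tailMass
  if (abs(tot - 1) > 1e-10)
    msg <- c(msg, sprintf("masses + tail must sum to 1 (got %.12f)", tot))
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoalescentPMF", function(object) {
  cat(sprintf("CoalescentPMF over %d generations (+ geometric tail)\n",
              length(object@q)))
  cat(sprintf("  tail mass %.4g at rate %.4g; mean TMRCA %.1f generations before sampling\n",
              object@tailMass, object@tailRate, pmfMean(object)))
})

## ---------------------------------------------------------------------------
## Genome map and length bins
## ---------------------------------------------------------------------------

#' Genetic lengths of the autosomes
#'
#' @slot lengthsCM named numeric vector of per-autosome genetic lengths in
#'   centimorgans.
#'
#' @param lengthsCM per-chromosome genetic lengths in cM.
#' @return A \code{GenomeMap}.
#' @seealso [defaultGenomeMap()]
#' @examples
#' GenomeMap(c(chr1 = 286.3, chr2 = 268.8))
#' @export GenomeMap
#' @exportClass GenomeMap
GenomeMap <- function(lengthsCM) new("GenomeMap", lengthsCM = lengthsCM)

setClass("GenomeMap", representation(lengthsCM = "numeric"))

setValidity("GenomeMap", function(object) {
  if (length(object@lengthsCM) < 1L || any(!is.finite(object@lengthsCM)) ||
      any(object@lengthsCM <= 0))
    "all chromosome lengths must be positive and finite" else TRUE
})

setMethod("show", "GenomeMap", function(object) {
  cat(sprintf("GenomeMap: %d chromosomes, total %.1f cM\n",
              length(object@lengthsCM), sum(object@lengthsCM)))
})

#' Half-open genetic-length bins
#'
#' Ordered bin edges in centimorgans; bin \code{b} is
#' \code{[edgesCM[b], edgesCM[b + 1])}.
#'
#' @slot edgesCM strictly increasing numeric vector of edges, in cM.
#'
#' @param edgesCM bin edges in cM.
#' @return A \code{LengthBins}.
#' @seealso [defaultIBDBins()], [defaultAncientROHBins()]
#' @examples
#' LengthBins(4:15)
#' @export LengthBins
#' @exportClass LengthBins
LengthBins <- function(edgesCM) new("LengthBins", edgesCM = as.numeric(edgesCM))

setClass("LengthBins", representation(edgesCM = "numeric"))

setValidity("LengthBins", function(object) {
  e <- object@edgesCM
  if (length(e) < 2L || any(!is.finite(e)) || any(diff(e) <= 0) || e[1] < 0)
    "edges must be >= 0, finite and strictly increasing (need >= 2)" else TRUE
})

setMethod("show", "LengthBins", function(object) {
  cat(sprintf("LengthBins: %d half-open bins on [%g, %g) cM\n",
              length(object@edgesCM) - 1L, min(object@edgesCM),
              max(object@edgesCM)))
})

## ---------------------------------------------------------------------------
## Segment count table
## ---------------------------------------------------------------------------

#' Observed or simulated segment counts per genetic-length bin
#'
#' @slot counts non-negative counts, one per bin.
#' @slot bins the [LengthBins-class] the counts refer to.
#' @slot nIndividuals number of diploid individuals (may be \code{NA} for
#'   simulated tables specified directly by pair count).
#' @slot nPairs number of haplotype pairs the counts sum over.
#' @slot sampling the [SamplingSpec-class] of the cohort.
#' @slot label free-text cohort label.
#'
#' @param counts,bins,nIndividuals,nPairs,sampling,label see slots;
#'   \code{nPairs} defaults to [pairCount()] of \code{nIndividuals} under the
#'   sampling mode.
#' @return A \code{SegmentCountTable}.
#' @examples
#' SegmentCountTable(counts = rep(1, 11), bins = defaultIBDBins(),
#'                   nIndividuals = 10, sampling = SamplingSpec(mode = "IBD"))
#' @export SegmentCountTable
#' @exportClass SegmentCountTable
SegmentCountTable <- function(counts, bins, nIndividuals = NA_real_,
                              nPairs = NULL, sampling = SamplingSpec(),
                              label = "") {
  if (is.null(nPairs)) {
    if (is.na(nIndividuals))
      stop("either nPairs or nIndividuals must be given")
    nPairs <- pairCount(nIndividuals, sampling@mode)
  }
  new("SegmentCountTable", counts = as.numeric(counts), bins = bins,
      nIndividuals = as.numeric(nIndividuals), nPairs = as.numeric(nPairs),
      sampling = sampling, label = label)
}

setClass("SegmentCountTable",
  representation(counts = "numeric", bins = "LengthBins",
                 nIndividuals = "numeric", nPairs = "numeric",
                 sampling = "SamplingSpec", label = "character"))

setValidity("SegmentCountTable", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@bins@edgesCM) - 1L)
    msg <- c(msg, "counts length must equal the number of bins")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (object@nPairs < 1) msg <- c(msg, "nPairs must be >= 1")
  if (!is.na(object@nIndividuals) &&
      abs(object@nPairs -
          pairCount(object@nIndividuals, object@sampling@mode)) > 0.5)
    msg <- c(msg, "nPairs inconsistent with nIndividuals and mode")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegmentCountTable", function(object) {
  cat(sprintf("SegmentCountTable%s: %d bins, %g segments, %g haplotype pairs (%s)\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              length(object@counts), sum(object@counts), object@nPairs,
              object@sampling@mode))
})

## ---------------------------------------------------------------------------
## Parameter space and fit results
## ---------------------------------------------------------------------------

#' Search space for maximum-likelihood fitting
#'
#' Per-parameter box bounds, fixed-value assignments, tied parameters
#' (copied from another parameter at decode time, e.g. \code{Ng} from
#' \code{Nb}), and the set of parameters searched on a log10 scale.
#'
#' @slot lower,upper named bound vectors over all model parameters.
#' @slot fixed named numeric vector of parameters held fixed.
#' @slot tied named character vector: element \code{"Ng" = "Nb"} means
#'   \code{Ng} is copied from \code{Nb} unless freed or fixed.
#' @slot logScale names of parameters searched on a log10 scale.
#'
#' @seealso [defaultParameterSpace()]
#' @exportClass ParameterSpace
setClass("ParameterSpace",
  representation(lower = "numeric", upper = "numeric", fixed = "numeric",
                 tied = "character", logScale = "character"))

setValidity("ParameterSpace", function(object) {
  msg <- character()
  nm <- names(object@lower)
  if (is.null(nm) || !identical(nm, names(object@upper)))
    msg <- c(msg, "lower and upper must be named identically")
  if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)) ||
      any(object@upper <= object@lower))
    msg <- c(msg, "bounds must be finite with upper > lower")
  if (length(object@fixed) && !all(names(object@fixed) %in% nm))
    msg <- c(msg, "fixed parameters must be model parameters")
  if (length(object@tied) &&
      (!all(names(object@tied) %in% nm) || !all(object@tied %in% nm)))
    msg <- c(msg, "tied parameters must reference model parameters")
  if (!all(object@logScale %in% nm))
    msg <- c(msg, "logScale names must be model parameters")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ParameterSpace", function(object) {
  free <- freeParameters(object)
  cat(sprintf("ParameterSpace: free {%s}", paste(free, collapse = ", ")))
  if (length(object@fixed))
    cat(sprintf("; fixed {%s}",
                paste(sprintf("%s=%g", names(object@fixed), object@fixed),
                      collapse = ", ")))
  if (length(object@tied))
    cat(sprintf("; tied {%s}",
                paste(sprintf("%s<-%s", names(object@tied), object@tied),
                      collapse = ", ")))
  cat("\n")
})

#' Result of a maximum-likelihood fit
#'
#' @slot modelType \code{"single"} or \code{"two_pop"}.
#' @slot estimates named vector of all model parameters at the optimum
#'   (free, fixed and tied).
#' @slot space the [ParameterSpace-class] used.
#' @slot loglik per-pair composite log-likelihood at the optimum (summed
#'   over datasets).
#' @slot diagnostics list with \code{iterations}, \code{seed},
#'   \code{converged} and \code{nEval}.
#' @slot ci matrix of bootstrap intervals (rows = parameters, columns =
#'   \code{"2.5%"}, \code{"97.5%"}), or a 0-row matrix before
#'   [bootstrapCI()] is run.
#'
#' @seealso [fitModel()], [bootstrapCI()]
#' @exportClass FitResult
setClass("FitResult",
  representation(modelType = "character", estimates = "numeric",
                 space = "ParameterSpace", loglik = "numeric",
                 diagnostics = "list", ci = "matrix"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (!object@modelType %in% c("single", "two_pop"))
    msg <- c(msg, "modelType must be 'single' or 'two_pop'")
  if (!is.finite(object@loglik)) msg <- c(msg, "loglik must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s model): per-pair loglik %.6f\n",
              object@modelType, object@loglik))
  est <- object@estimates
  for (p in names(est)) {
    ci <- if (p %in% rownames(object@ci))
      sprintf("  [%.4g, %.4g]", object@ci[p, 1], object@ci[p, 2]) else ""
    fixed <- if (p %in% names(object@space@fixed)) " (fixed)" else ""
    cat(sprintf("  %-4s = %.6g%s%s\n", p, est[p], fixed, ci))
  }
})

## ---------------------------------------------------------------------------
## Synthetic study
## ---------------------------------------------------------------------------

#' A matched synthetic modern-IBD + ancient-ROH study
#'
#' @slot ibd modern-cohort IBD [SegmentCountTable-class].
#' @slot roh ancient-cohort ROH [SegmentCountTable-class].
#' @slot model the generating [DemographicModel-class].
#' @slot genome the [GenomeMap-class] used.
#' @slot seed integer seed the study was generated from.
#'
#' @seealso [generateStudy()]
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
  representation(ibd = "SegmentCountTable", roh = "SegmentCountTable",
                 model = "DemographicModel", genome = "GenomeMap",
                 seed = "integer"))

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy (seed %d)\n", object@seed))
  cat("  modern IBD: "); show(object@ibd)
  cat("  ancient ROH: "); show(object@roh)
})
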