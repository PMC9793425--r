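#' Effective population size at a time in the past
#'
#' @param model a [SinglePopModel-class] or [TwoPopModel-class].
#' @param t generations before present (vectorized, \code{t >= 0}).
#' @param subpop for a two-population model queried inside the split epoch,
#'   which subgroup: \code{"bottleneck"} (size \code{Nb}) or \code{"other"}
#'   (size \code{Na - Nb}).
#' @return Diploid effective size(s) at \code{t}.
#' @examples
#' m <- SinglePopModel(Na = 10000, Nb = 1563, Tb = 41, d = 20, Nc = 1e6)
#' sizeAt(m, c(0, 30, 50))
#' @export
setGeneric("sizeAt", function(model, t, subpop = NA_character_)
  standardGeneric("sizeAt"))

#' @rdname coalescentPMF
#' @export
setGeneric("coalescentPMF", function(model, sampling, Umax = NULL)
  standardGeneric("coalescentPMF"))

## ---- small accessors -------------------------------------------------------

#' Accessors for the core classes
#'
#' \code{pmfMasses} and \code{tailMass} return the per-generation masses and
#' the analytic tail mass of a [CoalescentPMF-class]; \code{pmfMean} its mean
#' TMRCA (tail included).  \code{binEdges} returns the edges (cM) of a
#' [LengthBins-class] or of the bins carried by a [SegmentCountTable-class];
#' \code{binCounts} and \code{nPairs} the counts and haplotype-pair count of
#' a table; \code{chromLengths} the per-chromosome lengths (cM) of a
#' [GenomeMap-class]; \code{estimates} and \code{confint} the parameter
#' estimates and bootstrap intervals of a [FitResult-class].
#'
#' @param object,parm,level,... object to access; \code{confint} follows the
#'   [stats::confint()] signature (only \code{level = 0.95} intervals are
#'   stored).
#' @return See description.
#' @name accessors
#' @examples
#' pmf <- coalescentPMF(SinglePopModel(Na = 100, Nb = 100, Tb = 10, d = 5,
#'                                     Nc = 100), SamplingSpec())
#' head(pmfMasses(pmf)); tailMass(pmf)
NULL

#' @rdname accessors
#' @export
setGeneric("pmfMasses", function(object) standardGeneric("pmfMasses"))
setMethod("pmfMasses", "CoalescentPMF", function(object) object@q)

#' @rdname accessors
#' @export
setGeneric("tailMass", function(object) standardGeneric("tailMass"))
setMethod("tailMass", "CoalescentPMF", function(object) object@tailMass)

#' @rdname accessors
#' @export
setGeneric("pmfMean", function(object) standardGeneric("pmfMean"))
setMethod("pmfMean", "CoalescentPMF", function(object) {
  U <- length(object@q)
  sum(seq_len(U) * object@q) +
    object@tailMass * (U + 1 / object@tailRate)
})

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))
setMethod("binEdges", "LengthBins", function(object) object@edgesCM)
setMethod("binEdges", "SegmentCountTable", function(object) object@bins@edgesCM)

#' @rdname accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
setMethod("binCounts", "SegmentCountTable", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))
setMethod("nPairs", "SegmentCountTable", function(object) object@nPairs)

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(object) standardGeneric("chromLengths"))
setMethod("chromLengths", "GenomeMap", function(object) object@lengthsCM)

#' @rdname accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))
setMethod("estimates", "FitResult", function(object) object@estimates)

#' @rdname accessors
#' @export
setMethod("confint", "FitResult", function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only 95% bootstrap intervals are stored")
  ci <- object@ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
})

#' @rdname accessors
#' @export
setGeneric("freeParameters", function(object) standardGeneric("freeParameters"))
setMethod("freeParameters", "ParameterSpace", function(object) {
  setdiff(names(object@lower), c(names(object@fixed), names(object@tied)))
})

#' Convert a FitResult to the demographic model at its optimum
#'
#' @param fit a [FitResult-class].
#' @return A [SinglePopModel-class] or [TwoPopModel-class] built from the
#'   estimates.
#' @export
fittedModel <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  .paramsToModel(fit@estimates, fit@modelType)
}

## internal: named parameter vector -> model object
.paramsToModel <- function(p, type) {
  if (type == "single")
    SinglePopModel(Na = p[["Na"]], Nb = p[["Nb"]], Tb = p[["Tb"]],
                   d = p[["d"]], Nc = p[["Nc"]])
  else
    TwoPopModel(Na = p[["Na"]], Nb = p[["Nb"]], Tb = p[["Tb"]],
                d = p[["d"]], Nc = p[["Nc"]], f = p[["f"]],
                Ng = if ("Ng" %in% names(p)) p[["Ng"]] else p[["Nb"]])
}
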