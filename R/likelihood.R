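## Poisson composite likelihood over length bins, and the per-pair joint
## objective that balances modern IBD against (much scarcer) ancient ROH.

#' Poisson composite log-likelihood of binned segment counts
#'
#' Treats the count in each length bin as an independent Poisson variable
#' with mean equal to the model expectation and multiplies across bins:
#' \code{total = sum_b [K_b log(lambda_b) - lambda_b - log(K_b!)]}.
#' Constant \code{log(K!)} terms are retained (via \code{lgamma}) so
#' absolute values are comparable across runs.  A bin with
#' \code{lambda_b = 0} and \code{K_b = 0} contributes 0; \code{lambda_b = 0}
#' with \code{K_b > 0} yields \code{-Inf}, returned as a flagged non-finite
#' value rather than an error so optimizers can traverse such models.
#'
#' @param counts a [SegmentCountTable-class], or a numeric vector of counts
#'   (then \code{P} must be given).
#' @param lambda expected counts per bin, as from [expectedBinCounts()].
#' @param P number of haplotype pairs (taken from \code{counts} when it is a
#'   table).
#' @return A list of class \code{"likelihoodValue"} with \code{total},
#'   \code{perPair} (= total / P), \code{binsUsed} and \code{finite}.
#' @examples
#' poissonCompositeLoglik(c(3), lambda = c(2), P = 1)  # total ~ -1.7123
#' @export
poissonCompositeLoglik <- function(counts, lambda, P = NULL) {
  if (is(counts, "SegmentCountTable")) {
    P <- nPairs(counts)
    K <- binCounts(counts)
  } else {
    K <- as.numeric(counts)
    if (is.null(P)) stop("P must be given when counts is a plain vector")
  }
  if (length(K) != length(lambda))
    stop("counts and lambda must have one entry per bin")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  term <- numeric(length(K))
  pos <- lambda > 0
  term[pos] <- K[pos] * log(lambda[pos]) - lambda[pos] - lgamma(K[pos] + 1)
  term[!pos & K > 0] <- -Inf          # model incompatible with the data
  total <- sum(term)
  structure(list(total = total, perPair = total / P,
                 binsUsed = length(K), finite = is.finite(total)),
            class = "likelihoodValue")
}

#' @export
print.likelihoodValue <- function(x, ...) {
  cat(sprintf("composite loglik: total %.6g, per pair %.6g over %d bins%s\n",
              x$total, x$perPair, x$binsUsed,
              if (!x$finite) " (non-finite: model incompatible with data)" else ""))
  invisible(x)
}

#' Joint per-pair log-likelihood of modern IBD and ancient ROH
#'
#' The composite log-likelihood of each data type is divided by its own
#' haplotype-pair count before summing, so that each data type contributes
#' roughly equally to the joint objective despite the extreme imbalance in
#' pair counts (hundreds of thousands of modern IBD pairs vs a handful of
#' ancient ROH pairs).
#'
#' @param ibd,roh \code{"likelihoodValue"} objects computed under the same
#'   demographic model (see [poissonCompositeLoglik()]).
#' @return The scalar joint per-pair log-likelihood; non-finite inputs
#'   propagate.
#' @export
jointLoglik <- function(ibd, roh) {
  stopifnot(inherits(ibd, "likelihoodValue"), inherits(roh, "likelihoodValue"))
  ibd$perPair + roh$perPair
}
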