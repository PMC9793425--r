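## Expected IBD/ROH segment counts per genetic-length bin, and the paper
## trail of table post-processing rules (gap merging, high-ROH exclusion,
## binning).  All internal lengths are in Morgans; user interfaces are in cM.

.CM_PER_MORGAN <- 100

#' Default genetic map, length bins and pair counts
#'
#' \code{defaultGenomeMap()} returns the packaged sex-averaged genetic
#' lengths of the 22 human autosomes (HapMap-derived, in cM).
#' \code{defaultIBDBins()} returns 11 one-cM bins on [4, 15) cM;
#' \code{defaultAncientROHBins()} the same plus [15, 20), [20, 30) and
#' [30, 40) cM, implementing the 40-cM cap used for ancient ROH.
#' \code{pairCount(n, mode)} is the number of haplotype pairs contributing
#' segments for \code{n} diploid individuals: \code{choose(2n, 2) - n}
#' between-individual (non-ROH) pairs for IBD, and \code{n} within-individual
#' pairs for ROH.
#'
#' @param n number of diploid individuals.
#' @param mode \code{"IBD"} or \code{"ROH"}.
#' @return See description.
#' @examples
#' pairCount(637, "IBD")   # 810264
#' pairCount(16, "ROH")    # 16
#' @name defaults
NULL

#' @rdname defaults
#' @export
defaultGenomeMap <- function() {
  path <- system.file("extdata", "genome_map_sexavg_cM.tsv",
                      package = "IBDemog", mustWork = TRUE)
  tab <- utils::read.delim(path)
  GenomeMap(lengthsCM = stats::setNames(tab$length_cM, tab$chromosome))
}

#' @rdname defaults
#' @export
defaultIBDBins <- function() LengthBins(edgesCM = as.numeric(4:15))

#' @rdname defaults
#' @export
defaultAncientROHBins <- function() LengthBins(edgesCM = c(4:15, 20, 30, 40))

#' @rdname defaults
#' @export
pairCount <- function(n, mode = c("IBD", "ROH")) {
  mode <- match.arg(mode)
  if (any(n < 1)) stop("n must be >= 1")
  if (mode == "IBD") choose(2 * n, 2) - n else n
}

## ---- closed-form expectation ----------------------------------------------

## Per-pair expected counts for every (t_sep, bin) over one genome.
## u: vector of lineage-separation times (2u meioses); edgesM in Morgans.
## Returns a length(u) x nbins matrix.  For a chromosome of length L the
## density of shared-segment lengths is [a^2 (L - l) + 2 a] e^{-a l} with
## a = 2 t_sep, whose antiderivative is F(l) = e^{-a l} (a (l - L) - 1);
## the whole-chromosome event contributes e^{-a L}.
.expectedCountsMatrix <- function(u, genomeM, edgesM) {
  a <- 2 * u
  nb <- length(edgesM) - 1L
  out <- matrix(0, length(u), nb)
  for (L in genomeM) {
    Fv <- function(l) exp(-a * l) * (a * (l - L) - 1)
    for (b in seq_len(nb)) {
      lo <- edgesM[b]; hi <- edgesM[b + 1L]
      if (lo < L) out[, b] <- out[, b] + Fv(min(hi, L)) - Fv(lo)
      if (lo <= L && L < hi) out[, b] <- out[, b] + exp(-a * L)
    }
  }
  out
}

#' Expected per-pair segment counts conditional on the TMRCA
#'
#' Closed-form expected number of IBD/ROH segments per genetic-length bin
#' shared by two haplotypes whose lineages separated \code{tSep} generations
#' ago (so segment lengths are exponential-like with rate \code{2 tSep} per
#' Morgan), summed over the chromosomes of \code{genome}.  Both interior
#' segments, chromosome-edge segments and the whole-chromosome event are
#' included.
#'
#' @param tSep lineage separation time in generations (TMRCA before
#'   sampling); must be \code{>= 1}.
#' @param genome a [GenomeMap-class].
#' @param bins a [LengthBins-class].
#' @return Named numeric vector of expected counts per bin (per haplotype
#'   pair).
#' @examples
#' g <- GenomeMap(c(chr1 = 100))  # one 1-Morgan chromosome
#' expectedCountsGivenTmrca(10, g, LengthBins(c(4, 15)))  # ~8.18
#' @export
expectedCountsGivenTmrca <- function(tSep, genome, bins) {
  stopifnot(is(genome, "GenomeMap"), is(bins, "LengthBins"))
  if (length(tSep) != 1L || tSep < 1)
    stop("tSep must be a single value >= 1")
  E <- .expectedCountsMatrix(tSep, chromLengths(genome) / .CM_PER_MORGAN,
                             binEdges(bins) / .CM_PER_MORGAN)
  stats::setNames(drop(E), .binLabels(bins))
}

.binLabels <- function(bins) {
  e <- binEdges(bins)
  sprintf("[%g,%g)", e[-length(e)], e[-1])
}

#' Expected bin counts under a demographic model
#'
#' Marginalizes the conditional expectation [expectedCountsGivenTmrca()]
#' over the coalescence-time distribution of \code{model}/\code{sampling}
#' and scales by the number of haplotype pairs:
#' \code{lambda_b = P * sum_u q(u) E_b(u)}, with the analytic geometric tail
#' of the PMF summed to convergence (increments below 1e-12 of the running
#' total).
#'
#' @param model a [SinglePopModel-class] or [TwoPopModel-class].
#' @param sampling a [SamplingSpec-class].
#' @param genome a [GenomeMap-class].
#' @param bins a [LengthBins-class].
#' @param P number of haplotype pairs (see [pairCount()]).
#' @param Umax optional PMF truncation override (see [coalescentPMF()]).
#' @return Named numeric vector \code{lambda} of expected counts per bin.
#' @examples
#' m <- SinglePopModel(Na = 1000, Nb = 100, Tb = 30, d = 10, Nc = 1e4)
#' expectedBinCounts(m, SamplingSpec(), defaultGenomeMap(),
#'                   defaultIBDBins(), P = 100)
#' @export
expectedBinCounts <- function(model, sampling, genome, bins, P, Umax = NULL) {
  stopifnot(is(model, "DemographicModel"))
  if (P < 1) stop("P must be >= 1")
  pmf <- coalescentPMF(model, sampling, Umax)
  lambda <- .lambdaFromPMF(pmf@q, pmf@tailMass, pmf@tailRate,
                           chromLengths(genome) / .CM_PER_MORGAN,
                           binEdges(bins) / .CM_PER_MORGAN)
  stats::setNames(P * lambda, .binLabels(bins))
}

## Chunked evaluation of sum_u q(u) E_b(u) (+ geometric tail), with early
## termination once a chunk adds < 1e-12 of the running total in every bin.
## minU: do not terminate before this u (the hazard only becomes stationary
## in the ancestral epoch).
.lambdaFromPMF <- function(q, tailMass, tailRate, genomeM, edgesM,
                           chunk = 2048L, rel = 1e-12) {
  nb <- length(edgesM) - 1L
  lambda <- numeric(nb)
  U <- length(q)
  minU <- min(U, 8192L)
  u0 <- 0L
  while (u0 < U) {
    uu <- (u0 + 1L):min(u0 + chunk, U)
    E <- .expectedCountsMatrix(uu, genomeM, edgesM)
    inc <- drop(q[uu] %*% E)
    lambda <- lambda + inc
    u0 <- uu[length(uu)]
    if (u0 >= minU && all(inc <= rel * pmax(lambda, .Machine$double.xmin)))
      return(lambda)
  }
  ## analytic geometric tail beyond U
  if (tailMass > 0) {
    r <- tailRate
    logSurv <- 0   # log of (1 - r)^{j-1} at the start of the chunk
    j0 <- 0L
    repeat {
      jj <- (j0 + 1L):(j0 + chunk)
      w <- tailMass * r * exp(logSurv + log1p(-r) * (jj - 1L - j0))
      E <- .expectedCountsMatrix(U + jj, genomeM, edgesM)
      inc <- drop(w %*% E)
      lambda <- lambda + inc
      logSurv <- logSurv + log1p(-r) * chunk
      j0 <- jj[length(jj)]
      if (all(inc <= rel * pmax(lambda, .Machine$double.xmin))) break
    }
  }
  lambda
}

## ---- segment-table post-processing ----------------------------------------

## Segment records are data.frames with columns
## sample, chromosome, start_cM, end_cM, length_cM.
.checkRecords <- function(segments) {
  need <- c("sample", "chromosome", "start_cM", "end_cM", "length_cM")
  if (!all(need %in% names(segments)))
    stop("segment records need columns: ", paste(need, collapse = ", "))
  if (any(segments$end_cM <= segments$start_cM))
    stop("segment records must have end_cM > start_cM")
  if (any(abs(segments$length_cM -
              (segments$end_cM - segments$start_cM)) > 1e-6))
    stop("length_cM must equal end_cM - start_cM (within 1e-6 cM)")
  invisible(segments)
}

#' Merge short gaps between neighbouring ROH segments
#'
#' Within each sample and chromosome, two adjacent ROH are merged into one
#' when the gap between them is at most \code{maxGap} cM, both are at least
#' \code{minBoth} cM long, and at least one is \code{minOne} cM or longer.
#' Merging is applied iteratively left-to-right until no merge applies, so a
#' merged segment can participate in a subsequent merge; the operation is
#' idempotent.
#'
#' @param segments segment records: a data.frame with columns
#'   \code{sample}, \code{chromosome}, \code{start_cM}, \code{end_cM},
#'   \code{length_cM}; non-overlapping within sample and chromosome.
#' @param maxGap,minBoth,minOne rule thresholds in cM (defaults 0.5, 2, 4).
#' @return The merged segment records.
#' @examples
#' segs <- data.frame(sample = "s1", chromosome = "chr1",
#'                    start_cM = c(3, 7.4), end_cM = c(7, 9.9),
#'                    length_cM = c(4, 2.5))
#' mergeRohGaps(segs)  # one record 3 - 9.9
#' @export
mergeRohGaps <- function(segments, maxGap = 0.5, minBoth = 2, minOne = 4) {
  .checkRecords(segments)
  key <- paste(segments$sample, segments$chromosome, sep = "\r")
  parts <- lapply(split(seq_len(nrow(segments)), key), function(idx) {
    g <- segments[idx[order(segments$start_cM[idx])], , drop = FALSE]
    if (any(g$start_cM[-1] < g$end_cM[-nrow(g)]))
      stop("overlapping segment records within a sample and chromosome")
    i <- 1L
    while (i < nrow(g)) {
      gap <- g$start_cM[i + 1L] - g$end_cM[i]
      len1 <- g$end_cM[i] - g$start_cM[i]
      len2 <- g$end_cM[i + 1L] - g$start_cM[i + 1L]
      if (gap <= maxGap && min(len1, len2) >= minBoth &&
          max(len1, len2) >= minOne) {
        g$end_cM[i] <- g$end_cM[i + 1L]
        g <- g[-(i + 1L), , drop = FALSE]
      } else {
        i <- i + 1L
      }
    }
    g$length_cM <- g$end_cM - g$start_cM
    g
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Exclude individuals with excess total ROH
#'
#' Flags individuals whose total ROH length, counted over segments strictly
#' longer than \code{minLen} cM, strictly exceeds \code{totalThreshold} cM
#' (such individuals likely have closely related parents and would distort
#' population-level inference).
#'
#' @param segments segment records (see [mergeRohGaps()]).
#' @param totalThreshold exclusion threshold on the total, in cM (default 50).
#' @param minLen only segments longer than this count towards the total
#'   (default 4 cM).
#' @return A list with \code{retained} (segment records of retained
#'   individuals) and \code{excluded} (data.frame of excluded sample ids and
#'   their totals).
#' @export
filterHighRohIndividuals <- function(segments, totalThreshold = 50,
                                     minLen = 4) {
  .checkRecords(segments)
  long <- segments[segments$length_cM > minLen, , drop = FALSE]
  totals <- tapply(long$length_cM, long$sample, sum, default = 0)
  bad <- names(totals)[totals > totalThreshold]
  list(retained = segments[!segments$sample %in% bad, , drop = FALSE],
       excluded = data.frame(sample = bad,
                             total_cM = as.numeric(totals[bad])))
}

#' Assign segments to half-open length bins
#'
#' Each segment goes to the bin \code{[edge_b, edge_{b+1})} containing its
#' length; segments outside all bins are dropped and counted.
#'
#' @param segments segment records, or a numeric vector of lengths in cM.
#' @param bins a [LengthBins-class].
#' @return A list with \code{counts} (per bin) and \code{dropped} (number of
#'   segments outside all bins).
#' @examples
#' binSegments(c(4.2, 4.9, 14.99, 15), defaultIBDBins())
#' @export
binSegments <- function(segments, bins) {
  stopifnot(is(bins, "LengthBins"))
  lengths <- if (is.numeric(segments)) segments else
    .checkRecords(segments)$length_cM
  edges <- binEdges(bins)
  idx <- findInterval(lengths, edges)
  inside <- idx >= 1L & idx <= length(edges) - 1L
  counts <- tabulate(idx[inside], nbins = length(edges) - 1L)
  list(counts = stats::setNames(counts, .binLabels(bins)),
       dropped = sum(!inside))
}

#' Build a SegmentCountTable from segment records
#'
#' Convenience wrapper: bins the records with [binSegments()] (reporting
#' dropped segments with a message) and wraps the counts with their cohort
#' metadata.
#'
#' @param segments segment records.
#' @param bins a [LengthBins-class].
#' @param nIndividuals cohort size (diploid individuals).
#' @param sampling a [SamplingSpec-class].
#' @param label cohort label.
#' @return A [SegmentCountTable-class].
#' @export
makeCountTable <- function(segments, bins, nIndividuals, sampling,
                           label = "") {
  b <- binSegments(segments, bins)
  if (b$dropped > 0)
    message(b$dropped, " segment(s) outside all bins were dropped")
  SegmentCountTable(counts = b$counts, bins = bins,
                    nIndividuals = nIndividuals, sampling = sampling,
                    label = label)
}
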