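#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline. Thresholds mirror the
#' study design: posterior-overlap positivity cut-offs at 5/20/40%, a 5-fold
#' nearest-neighbour rule for lineage bias, a 10-fold max/min rule for
#' balance within the involved lineages, tracing eligibility at MCF >= 2%
#' (driver) / >= 1% (CH-US), 10,000 permutations, and a 40-week gestation
#' offset for age scales that start at conception.
#'
#' @param thetaGridSize number of MCF grid points for posterior integration.
#' @param effGridSize number of extraction-efficiency grid points.
#' @param priorBeta length-2 shape parameters of the beta prior on the MCF.
#' @param effPriorMean mean of the exponential prior on extraction efficiency.
#' @param positivityThresholds strictly increasing overlap cut-offs
#'   (positive / likely positive / inconclusive boundaries).
#' @param biasFold fold-change a nearest-neighbour MCF gap must exceed to
#'   count as a lineage bias.
#' @param balanceFold upper bound (exclusive) on the max/min MCF ratio within
#'   the involved lineage group for a balanced/named call.
#' @param tracingCuts named MCF cut-offs `c(driver = , chus = )` for tracing
#'   eligibility.
#' @param nPermutations permutation count for the concordance test.
#' @param gestationWeeks weeks from conception to birth.
#' @param minDroplets minimum accepted droplet events per well.
#' @param ciLevel credible/confidence level used throughout.
#' @return A list of class `traceConfig`.
#' @examples
#' cfg <- traceConfig()
#' cfg$positivityThresholds
#' @export
traceConfig <- function(thetaGridSize = 401L,
                        effGridSize = 201L,
                        priorBeta = c(1, 1),
                        effPriorMean = 1,
                        positivityThresholds = c(0.05, 0.20, 0.40),
                        biasFold = 5,
                        balanceFold = 10,
                        tracingCuts = c(driver = 0.02, chus = 0.01),
                        nPermutations = 10000L,
                        gestationWeeks = 40,
                        minDroplets = 8000L,
                        ciLevel = 0.95) {
  stopifnot(thetaGridSize >= 11, effGridSize >= 11,
            length(priorBeta) == 2, all(priorBeta > 0),
            effPriorMean > 0,
            length(positivityThresholds) == 3,
            nPermutations >= 1, gestationWeeks >= 0, minDroplets >= 1,
            ciLevel > 0, ciLevel < 1)
  if (any(diff(positivityThresholds) <= 0) || positivityThresholds[1] <= 0)
    stop("positivity thresholds must be positive and strictly increasing")
  if (biasFold <= 1 || balanceFold <= 1)
    stop("fold thresholds must exceed 1")
  if (!all(c("driver", "chus") %in% names(tracingCuts)))
    stop("tracingCuts needs named entries 'driver' and 'chus'")
  structure(list(
    thetaGridSize = as.integer(thetaGridSize),
    effGridSize = as.integer(effGridSize),
    priorBeta = priorBeta,
    effPriorMean = effPriorMean,
    positivityThresholds = positivityThresholds,
    biasFold = biasFold,
    balanceFold = balanceFold,
    tracingCuts = tracingCuts,
    nPermutations = as.integer(nPermutations),
    gestationWeeks = gestationWeeks,
    minDroplets = as.integer(minDroplets),
    ciLevel = ciLevel
  ), class = "traceConfig")
}
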