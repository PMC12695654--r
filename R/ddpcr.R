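#' Ploidy of the assayed locus
#'
#' Autosomes and the female X carry two copies; the male X and the Y carry
#' one.
#'
#' @param chromClass `"autosome"`, `"X"` or `"Y"`.
#' @param sex `"M"` or `"F"`.
#' @return 1 or 2.
#' @export
ploidyOf <- function(chromClass, sex) {
  chromClass <- match.arg(chromClass, .CHROM_CLASSES)
  sex <- match.arg(sex, c("M", "F"))
  if (chromClass == "autosome") return(2)
  if (chromClass == "X") return(if (sex == "F") 2 else 1)
  if (sex == "F") stop("a Y-chromosome assay is impossible in a female donor")
  1
}

#' Closed-form ddPCR quadrant probabilities
#'
#' Under Poisson partitioning of template molecules into droplets, a droplet
#' is free of mutant template with probability `exp(-lambdaM)` and free of
#' wild-type template with probability `exp(-lambdaW)`, independently. The
#' four quadrant probabilities follow directly.
#'
#' @param lambdaM expected mutant molecules per droplet (>= 0).
#' @param lambdaW expected wild-type molecules per droplet (>= 0).
#' @return Probability 4-vector `(nn, mut_only, wt_only, double_pos)`,
#'   summing to 1.
#' @examples
#' quadrantProbs(0.1, 0.5)
#' @export
quadrantProbs <- function(lambdaM, lambdaW) {
  if (length(lambdaM) != 1 || length(lambdaW) != 1 ||
      !is.finite(lambdaM) || !is.finite(lambdaW) ||
      lambdaM < 0 || lambdaW < 0)
    stop("lambda parameters must be single finite non-negative numbers")
  em <- exp(-lambdaM); ew <- exp(-lambdaW)
  c(nn = em * ew, mut_only = (1 - em) * ew,
    wt_only = em * (1 - ew), double_pos = (1 - em) * (1 - ew))
}

#' Expected molecules per droplet from the assay state
#'
#' Maps the latent state (MCF theta and extraction efficiency e) to the
#' per-droplet Poisson means: mutant cells contribute `mutCopies` mutant
#' copies each, all cells contribute `ploidy` total copies, so
#' `lambdaM = nCells * theta * mutCopies * e / nDroplets` and
#' `lambdaW = nCells * (ploidy - theta * mutCopies) * e / nDroplets`.
#'
#' @param theta mutant cell fraction in \[0, 1\] (vectorised).
#' @param eff extraction efficiency (> 0, vectorised).
#' @param nCells cells loaded.
#' @param nDroplets accepted droplets.
#' @param ploidy 1 or 2.
#' @param mutCopies mutant copies per mutant cell (1 = heterozygous).
#' @return List with vectors `lambdaM` and `lambdaW`.
#' @examples
#' lambdasFromState(0.05, 0.5, nCells = 9090, nDroplets = 14000, ploidy = 2)
#' @export
lambdasFromState <- function(theta, eff, nCells, nDroplets, ploidy = 2,
                             mutCopies = 1) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  if (any(eff <= 0)) stop("efficiency must be positive")
  if (any(theta * mutCopies > ploidy + 1e-12))
    stop("theta * mutCopies exceeds the locus ploidy")
  lm <- nCells * theta * mutCopies * eff / nDroplets
  lw <- nCells * pmax(ploidy - theta * mutCopies, 0) * eff / nDroplets
  list(lambdaM = lm, lambdaW = lw)
}

## quadratic grid: fine near 0 where small clones live, coarse near 1
.thetaGrid <- function(n) seq(0, 1, length.out = n)^2

## trapezoid cell widths for an arbitrary strictly increasing grid
.gridWidths <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' Posterior over the mutant cell fraction from one ddPCR well
#'
#' Deterministic 2-D grid integration of the joint posterior over the MCF
#' theta (beta prior) and the extraction efficiency e (exponential prior),
#' with a multinomial likelihood of the four quadrant counts under Poisson
#' droplet occupancy. The efficiency is marginalised out; the returned object
#' carries the theta marginal, its mean and the equal-tailed credible
#' interval.
#'
#' The theta grid is quadratically spaced (fine near zero, where clonal
#' fractions of interest live); the efficiency grid sits on equal-mass
#' quantiles of its exponential prior, so prior weights are uniform there.
#'
#' @param assay a [DropletAssay-class].
#' @param config a [traceConfig()] list (grid sizes, priors, CI level).
#' @param mutCopies mutant copies per mutant cell (default 1, heterozygous).
#' @return A [PosteriorMCF-class].
#' @examples
#' a <- DropletAssay(12000, 25, 1900, 4, nCells = 2000)
#' p <- posteriorMcf(a)
#' mcfMean(p); mcfCI(p)
#' @export
posteriorMcf <- function(assay, config = traceConfig(), mutCopies = 1) {
  stopifnot(is(assay, "DropletAssay"))
  cts <- quadrantCounts(assay)
  if (sum(cts) <= 0) stop("all four quadrant counts are zero")
  D <- sum(cts)
  p <- ploidyOf(assay@chromClass, assay@sex)

  theta <- .thetaGrid(config$thetaGridSize)
  m <- config$effGridSize
  eff <- qexp((seq_len(m) - 0.5) / m, rate = 1 / config$effPriorMean)

  lm <- (assay@nCells * mutCopies / D) * outer(theta, eff)
  lw <- (assay@nCells / D) * outer(pmax(p - theta * mutCopies, 0), eff)
  em <- exp(-lm); ew <- exp(-lw)

  ll <- matrix(0, nrow = length(theta), ncol = m)
  if (cts[1] > 0) ll <- ll + cts[1] * (-lm - lw)
  if (cts[2] > 0) ll <- ll + cts[2] * (log1p(-em) - lw)
  if (cts[3] > 0) ll <- ll + cts[3] * (-lm + log1p(-ew))
  if (cts[4] > 0) ll <- ll + cts[4] * (log1p(-em) + log1p(-ew))

  ## priors: beta weights on the theta grid (trapezoid), uniform over the
  ## equal-mass efficiency grid
  wTheta <- dbeta(theta, config$priorBeta[1], config$priorBeta[2]) *
    .gridWidths(theta)
  if (!is.finite(wTheta[1])) wTheta[1] <- 0
  if (!is.finite(wTheta[length(wTheta)])) wTheta[length(wTheta)] <- 0

  lp <- ll + log(wTheta)
  lp[wTheta == 0, ] <- -Inf
  post <- exp(lp - max(lp))
  post[!is.finite(post)] <- 0
  marg <- rowSums(post)
  marg <- marg / sum(marg)

  mu <- sum(theta * marg)
  alpha <- (1 - config$ciLevel) / 2
  ci <- .massQuantile(theta, marg, c(alpha, 1 - alpha))
  new("PosteriorMCF", theta = theta, mass = marg, mean = mu,
      ciLo = min(ci[1], mu), ciHi = max(ci[2], mu), level = config$ciLevel)
}

## quantiles of a discrete mass on a grid, linear interpolation on the CDF
.massQuantile <- function(x, mass, probs) {
  cdf <- cumsum(mass)
  vapply(probs, function(q) {
    i <- which(cdf >= q)[1]
    if (is.na(i)) return(x[length(x)])
    if (i == 1) return(x[1])
    c0 <- cdf[i - 1]; c1 <- cdf[i]
    if (c1 <= c0) return(x[i])
    x[i - 1] + (x[i] - x[i - 1]) * (q - c0) / (c1 - c0)
  }, numeric(1))
}

#' Synthetic negative-control assay
#'
#' A wild-type-only well matched to the sample: the same total droplets, cell
#' input and genetic context, with all mutant-positive droplets reassigned to
#' the corresponding mutant-free quadrant. Used when no measured control well
#' is available.
#'
#' @param assay a [DropletAssay-class] sample well.
#' @return A [DropletAssay-class] with `mutOnly = doublePos = 0`.
#' @export
nullControlAssay <- function(assay) {
  stopifnot(is(assay, "DropletAssay"))
  DropletAssay(nn = assay@nn + assay@mutOnly,
               mutOnly = 0,
               wtOnly = assay@wtOnly + assay@doublePos,
               doublePos = 0,
               nCells = assay@nCells,
               chromClass = assay@chromClass, sex = assay@sex)
}

#' Overlap area of two posteriors
#'
#' `sum(min(f, g))` over a common theta grid, i.e. the overlap coefficient of
#' the two posterior distributions. Posteriors on different grids are
#' re-gridded by density interpolation onto the first grid.
#'
#' @param a,b [PosteriorMCF-class] objects.
#' @return Overlap fraction in \[0, 1\].
#' @export
overlapArea <- function(a, b) {
  stopifnot(is(a, "PosteriorMCF"), is(b, "PosteriorMCF"))
  if (!isTRUE(all.equal(a@theta, b@theta))) b <- .regrid(b, a@theta)
  min(1, sum(pmin(a@mass, b@mass)))
}

.regrid <- function(post, theta) {
  wSrc <- .gridWidths(post@theta)
  dens <- post@mass / wSrc
  d <- approx(post@theta, dens, xout = theta, yleft = 0, yright = 0)$y
  m <- d * .gridWidths(theta)
  if (sum(m) <= 0) stop("posteriors have non-overlapping, non-regriddable supports")
  new("PosteriorMCF", theta = theta, mass = m / sum(m),
      mean = post@mean, ciLo = post@ciLo, ciHi = post@ciHi,
      level = post@level)
}

#' Positivity call from posterior overlap
#'
#' A sample is called positive when its MCF posterior and the negative
#' control's overlap by less than 5%, likely positive in \[5%, 20%),
#' inconclusive in \[20%, 40%) and negative at >= 40%. The binary collapse
#' maps positive and likely positive to positive, the rest to negative.
#'
#' @param sample,control [PosteriorMCF-class] objects on a common grid.
#' @param thresholds increasing overlap cut-offs (default 0.05, 0.20, 0.40).
#' @return List with `overlap`, `label` (one of `"positive"`,
#'   `"likely_positive"`, `"inconclusive"`, `"negative"`) and `binary`
#'   (`TRUE` for the positive collapse).
#' @export
positivity <- function(sample, control,
                       thresholds = traceConfig()$positivityThresholds) {
  ov <- overlapArea(sample, control)
  label <- if (ov < thresholds[1]) "positive"
    else if (ov < thresholds[2]) "likely_positive"
    else if (ov < thresholds[3]) "inconclusive"
    else "negative"
  list(overlap = ov, label = label,
       binary = label %in% c("positive", "likely_positive"))
}

#' Convert a VAF to a mutant cell fraction
#'
#' Heterozygous sites on two-copy loci give MCF = 2 x VAF (capped at 1);
#' one-copy loci (male X/Y) give MCF = VAF.
#'
#' @param vaf variant allele frequency in \[0, 1\] (vectorised).
#' @param ploidy 1 or 2.
#' @return MCF in \[0, 1\].
#' @examples
#' vafToMcf(0.25, ploidy = 2)  # 0.5
#' vafToMcf(0.25, ploidy = 1)  # 0.25
#' @export
vafToMcf <- function(vaf, ploidy = 2) {
  if (any(vaf < 0 | vaf > 1)) stop("VAF must lie in [0, 1]")
  if (!ploidy %in% c(1, 2)) stop("ploidy must be 1 or 2")
  if (ploidy == 1) return(vaf)
  mcf <- 2 * vaf
  if (any(mcf > 1)) {
    message(sum(mcf > 1), " MCF value(s) capped at 1")
    mcf <- pmin(mcf, 1)
  }
  mcf
}

#' Cell equivalents of a DNA mass
#'
#' A diploid human cell holds 3e9 bp x 2 x 660 Da/bp x 1.67e-12 pg/Da of DNA,
#' rounded to 6.6 pg; the cell count for a template mass is the floor of
#' mass / 6.6 pg. 60 ng of bulk DNA corresponds to 9,090 cells, the bulk-DNA
#' convention used for marrow mononuclear-cell wells.
#'
#' @param massNg template DNA mass in nanograms.
#' @return Integer number of cell equivalents.
#' @examples
#' cellsFromDnaMass(60)  # 9090
#' @export
cellsFromDnaMass <- function(massNg) {
  if (length(massNg) != 1 || !is.finite(massNg) || massNg <= 0)
    stop("DNA mass must be a single positive number (ng)")
  floor(massNg * 1000 / perCellDnaPg())
}

#' DNA mass of a single diploid cell
#' @return Picograms per cell, rounded to one decimal (6.6).
#' @export
perCellDnaPg <- function() round(3e9 * 2 * 660 * 1.67e-12, 1)

#' Tracing eligibility of a clone
#'
#' Clones qualify for lineage tracing at bulk MCF >= 2% when marked by a CH
#' driver mutation, or >= 1% when marked by a CH-US (undetermined
#' significance) mutation.
#'
#' @param mcfBulk bulk-marrow MCF in \[0, 1\] (vectorised).
#' @param driverFlag logical; `TRUE` for CH driver mutations.
#' @param cuts named cut-offs `c(driver = , chus = )`.
#' @return Logical vector.
#' @export
tracingEligible <- function(mcfBulk, driverFlag,
                            cuts = traceConfig()$tracingCuts) {
  if (any(mcfBulk < 0 | mcfBulk > 1)) stop("MCF must lie in [0, 1]")
  ifelse(driverFlag, mcfBulk >= cuts[["driver"]], mcfBulk >= cuts[["chus"]])
}
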