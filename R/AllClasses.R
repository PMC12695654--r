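#' @import methods
NULL

setOldClass("phylo")

.LINEAGES <- c("P", "E", "M", "B", "T")
.CHROM_CLASSES <- c("autosome", "X", "Y")
.PATTERN_LABELS <- c("PEMBT_balanced", "PEMB_restricted", "PEMB_biased",
                     "PEM_restricted", "PEM_biased", "other_unique", "no_output")

#' DropletAssay: one duplex ddPCR well
#'
#' Holds the four quadrant droplet counts of a duplex (mutant/wild-type)
#' droplet digital PCR well together with the number of sorted cells loaded
#' into the reaction and the genetic context (chromosome class and donor sex)
#' that determines the ploidy of the assayed locus.
#'
#' @slot nn double-negative droplet count.
#' @slot mutOnly mutant-only droplet count.
#' @slot wtOnly wild-type-only droplet count.
#' @slot doublePos double-positive droplet count.
#' @slot nCells number of cells whose DNA was loaded.
#' @slot chromClass `"autosome"`, `"X"` or `"Y"`.
#' @slot sex `"M"` or `"F"`.
#'
#' @seealso [DropletAssay()], [posteriorMcf()], [simulateDdpcr()]
#' @export
setClass("DropletAssay",
  representation(nn = "numeric", mutOnly = "numeric", wtOnly = "numeric",
                 doublePos = "numeric", nCells = "numeric",
                 chromClass = "character", sex = "character"),
  prototype(chromClass = "autosome", sex = "F"))

setValidity("DropletAssay", function(object) {
  cts <- c(object@nn, object@mutOnly, object@wtOnly, object@doublePos)
  if (any(!is.finite(cts)) || any(cts < 0))
    return("quadrant counts must be finite and non-negative")
  if (any(cts != round(cts)))
    return("quadrant counts must be integers")
  if (sum(cts) <= 0)
    return("total droplet count must be positive")
  if (length(object@nCells) != 1 || !is.finite(object@nCells) || object@nCells < 1)
    return("nCells must be a positive number")
  if (!object@chromClass %in% .CHROM_CLASSES)
    return("chromClass must be one of 'autosome', 'X', 'Y'")
  if (!object@sex %in% c("M", "F"))
    return("sex must be 'M' or 'F'")
  if (object@chromClass == "Y" && object@sex == "F")
    return("a Y-chromosome assay is impossible in a female donor")
  TRUE
})

#' Construct a DropletAssay
#'
#' @param nn,mutOnly,wtOnly,doublePos quadrant droplet counts
#'   (double-negative, mutant-only, wild-type-only, double-positive).
#' @param nCells number of cells loaded into the reaction.
#' @param chromClass chromosome class of the assayed mutation.
#' @param sex donor sex.
#' @return A [DropletAssay-class] object.
#' @examples
#' a <- DropletAssay(nn = 14000, mutOnly = 12, wtOnly = 900, doublePos = 2,
#'                   nCells = 2000)
#' nDroplets(a)
#' @export
DropletAssay <- function(nn, mutOnly, wtOnly, doublePos, nCells,
                         chromClass = "autosome", sex = "F") {
  new("DropletAssay", nn = as.numeric(nn), mutOnly = as.numeric(mutOnly),
      wtOnly = as.numeric(wtOnly), doublePos = as.numeric(doublePos),
      nCells = as.numeric(nCells), chromClass = chromClass, sex = sex)
}

#' Total droplets in an assay
#' @param x a [DropletAssay-class].
#' @return Integer total of the four quadrant counts.
#' @export
nDroplets <- function(x) {
  stopifnot(is(x, "DropletAssay"))
  x@nn + x@mutOnly + x@wtOnly + x@doublePos
}

#' Quadrant counts of an assay
#' @param x a [DropletAssay-class].
#' @return Named numeric vector (nn, mut_only, wt_only, double_pos).
#' @export
quadrantCounts <- function(x) {
  stopifnot(is(x, "DropletAssay"))
  c(nn = x@nn, mut_only = x@mutOnly, wt_only = x@wtOnly,
    double_pos = x@doublePos)
}

setMethod("show", "DropletAssay", function(object) {
  cat("DropletAssay:", nDroplets(object), "droplets,",
      object@nCells, "cells,", object@chromClass,
      sprintf("(%s)\n", object@sex))
  print(quadrantCounts(object))
})

#' PosteriorMCF: gridded posterior over the mutant cell fraction
#'
#' The marginal posterior of the mutant cell fraction theta on a fixed grid,
#' after integrating out the extraction efficiency. Mass sums to one; the mean
#' and equal-tailed 95% credible interval are precomputed.
#'
#' @slot theta grid of MCF values in \[0, 1\].
#' @slot mass posterior probability mass on the grid (sums to 1).
#' @slot mean posterior mean MCF.
#' @slot ciLo,ciHi equal-tailed credible-interval bounds.
#' @slot level credible level (default 0.95).
#' @seealso [posteriorMcf()], [positivity()]
#' @export
setClass("PosteriorMCF",
  representation(theta = "numeric", mass = "numeric", mean = "numeric",
                 ciLo = "numeric", ciHi = "numeric", level = "numeric"))

setValidity("PosteriorMCF", function(object) {
  if (length(object@theta) != length(object@mass))
    return("theta and mass must have equal length")
  if (any(object@theta < 0 | object@theta > 1))
    return("theta grid must lie in [0, 1]")
  if (is.unsorted(object@theta, strictly = TRUE))
    return("theta grid must be strictly increasing")
  if (any(object@mass < 0))
    return("posterior mass must be non-negative")
  if (abs(sum(object@mass) - 1) > 1e-9)
    return("posterior mass must sum to 1 (within 1e-9)")
  ok <- object@ciLo <= object@mean + 1e-12 && object@mean <= object@ciHi + 1e-12
  if (!ok) return("must satisfy ciLo <= mean <= ciHi")
  if (object@ciLo < 0 || object@ciHi > 1)
    return("credible interval must lie in [0, 1]")
  TRUE
})

#' Posterior mean MCF
#' @param x a [PosteriorMCF-class].
#' @return Numeric scalar.
#' @export
mcfMean <- function(x) { stopifnot(is(x, "PosteriorMCF")); x@mean }

#' Posterior credible interval
#' @param x a [PosteriorMCF-class].
#' @return Numeric vector `c(lo, hi)`.
#' @export
mcfCI <- function(x) {
  stopifnot(is(x, "PosteriorMCF"))
  c(lo = x@ciLo, hi = x@ciHi)
}

setMethod("show", "PosteriorMCF", function(object) {
  cat(sprintf("PosteriorMCF: mean %.4g, %g%% CI [%.4g, %.4g] on %d grid points\n",
              object@mean, 100 * object@level, object@ciLo, object@ciHi,
              length(object@theta)))
})

#' CladeTree: rooted mutation-count phylogeny of single-cell colonies
#'
#' Wraps an ape `phylo` tree whose branch lengths are somatic mutation counts.
#' After [makeUltrametric()] the per-node ages (years from conception) are
#' stored in `nodeAges` and the timeline span (donor age at sampling plus
#' gestation) in `span`.
#'
#' @slot phylo rooted `ape::phylo`; `edge.length` are mutation counts and an
#'   optional `root.edge` carries mutations shared by every colony.
#' @slot donorAge donor age at sampling in years (NA until known).
#' @slot gestationWeeks weeks from conception to birth (default 40).
#' @slot nodeAges ages (years from conception) indexed like `phylo` nodes
#'   (tips first, then internal nodes); empty until [makeUltrametric()].
#' @seealso [cladeTree()], [readCladeTree()], [makeUltrametric()]
#' @export
setClass("CladeTree",
  representation(phylo = "phylo", donorAge = "numeric",
                 gestationWeeks = "numeric", nodeAges = "numeric"),
  prototype(donorAge = NA_real_, gestationWeeks = 40, nodeAges = numeric(0)))

setValidity("CladeTree", function(object) {
  tr <- object@phylo
  if (!inherits(tr, "phylo")) return("phylo slot must be an ape phylo tree")
  if (is.null(tr$edge.length)) return("tree must carry branch lengths (mutation counts)")
  if (any(tr$edge.length < 0)) return("branch mutation counts must be non-negative")
  if (anyDuplicated(tr$tip.label)) return("tip labels must be unique")
  if (!ape::is.rooted(tr)) return("tree must be rooted")
  if (length(object@nodeAges) &&
      length(object@nodeAges) != ape::Ntip(tr) + tr$Nnode)
    return("nodeAges must have one entry per node")
  TRUE
})

#' Construct a CladeTree
#'
#' @param phylo a rooted `ape::phylo` with mutation-count branch lengths.
#' @param donorAge donor age at sampling (years), if known.
#' @param gestationWeeks gestation length in weeks (default 40).
#' @return A [CladeTree-class] object.
#' @export
cladeTree <- function(phylo, donorAge = NA_real_, gestationWeeks = 40) {
  new("CladeTree", phylo = phylo, donorAge = as.numeric(donorAge),
      gestationWeeks = as.numeric(gestationWeeks))
}

#' Underlying phylo tree
#' @param x a [CladeTree-class].
#' @return The `ape::phylo` object.
#' @export
treePhylo <- function(x) { stopifnot(is(x, "CladeTree")); x@phylo }

#' Node ages of an ultrametric CladeTree
#' @param x a [CladeTree-class] processed by [makeUltrametric()].
#' @return Numeric vector of ages (years from conception), node-indexed.
#' @export
nodeAges <- function(x) {
  stopifnot(is(x, "CladeTree"))
  if (!length(x@nodeAges))
    stop("tree has no node ages; run makeUltrametric() first")
  x@nodeAges
}

#' Timeline span of a dated tree
#'
#' Years from conception to sampling: donor age plus gestation converted with
#' 365.25-day years.
#' @param x a [CladeTree-class] with a known donor age.
#' @return Numeric scalar (years).
#' @export
timelineSpan <- function(x) {
  stopifnot(is(x, "CladeTree"))
  if (is.na(x@donorAge)) stop("donorAge is unknown")
  x@donorAge + x@gestationWeeks * 7 / 365.25
}

setMethod("show", "CladeTree", function(object) {
  tr <- object@phylo
  cat(sprintf("CladeTree: %d tips, %d internal nodes, %d mutations on branches\n",
              ape::Ntip(tr), tr$Nnode,
              sum(tr$edge.length) + if (is.null(tr$root.edge)) 0 else tr$root.edge))
  if (!is.na(object@donorAge))
    cat(sprintf("  donor age %.1f y (span %.2f y from conception)\n",
                object@donorAge, timelineSpan(object)))
  if (length(object@nodeAges)) cat("  ultrametric: node ages available\n")
})

#' GenotypeMatrix: colony-by-mutation genotype calls with source reads
#'
#' Ternary genotype calls (1 = positive, 0 = negative, NA = unknown) derived
#' from colony read counts, with the underlying mutant/total read matrices
#' retained.
#'
#' @slot calls integer matrix, colonies x mutations, entries 1/0/NA.
#' @slot mutReads,totalReads numeric matrices of the same dimension.
#' @seealso [buildGenotypeMatrix()], [perfectPhylogeny()], [colonyPurity()]
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", mutReads = "matrix", totalReads = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- dim(object@calls)
  if (!identical(d, dim(object@mutReads)) || !identical(d, dim(object@totalReads)))
    return("calls, mutReads and totalReads must share dimensions")
  v <- object@calls
  if (!all(v %in% c(0L, 1L, NA)))
    return("calls must be 1 (positive), 0 (negative) or NA (unknown)")
  if (any(object@mutReads > object@totalReads, na.rm = TRUE))
    return("mutant reads cannot exceed total reads")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("calls must carry colony rownames and mutation colnames")
  TRUE
})

#' Genotype call matrix
#' @param x a [GenotypeMatrix-class].
#' @return Integer matrix (1/0/NA), colonies x mutations.
#' @export
genotypeCalls <- function(x) { stopifnot(is(x, "GenotypeMatrix")); x@calls }

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@calls
  cat(sprintf("GenotypeMatrix: %d colonies x %d mutations (%.1f%% positive, %.1f%% unknown)\n",
              nrow(v), ncol(v), 100 * mean(v == 1L, na.rm = TRUE),
              100 * mean(is.na(v))))
})
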