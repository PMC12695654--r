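#' Lineage concordance score of a clade
#'
#' The proportion of a clade's terminal clones exhibiting the clade's most
#' frequent lineage-positivity pattern. Admissible patterns are
#' `all_positive`, `T_negative` and `BT_negative`; modal ties give the same
#' score by definition and are flagged.
#'
#' @param labels character vector (length >= 2) of pattern labels for the
#'   clade's terminal clones.
#' @return List: `score` in (0, 1\], `modal` pattern, `tied` logical.
#' @examples
#' concordanceScore(c("T_negative", "T_negative", "all_positive"))$score
#' @export
concordanceScore <- function(labels) {
  if (length(labels) < 2)
    stop("a clade needs at least 2 terminal clones")
  ok <- c("all_positive", "T_negative", "BT_negative")
  if (!all(labels %in% ok))
    stop("labels must be among: ", paste(ok, collapse = ", "))
  tab <- table(labels)
  top <- max(tab)
  list(score = top / length(labels),
       modal = names(tab)[which.max(tab)],
       tied = sum(tab == top) > 1)
}

#' Permutation test of clade lineage concordance
#'
#' Observed statistic: the mean per-clade concordance score (optionally the
#' clade-size-weighted mean). Null distribution: in each of `B` draws, every
#' clade is refilled by sampling its size without replacement from the pooled
#' clone labels of all donors, scored by the maximum pattern frequency, and
#' the per-clade scores are averaged. Empirical p uses the add-one
#' convention, `p = (1 + #(null >= observed)) / (B + 1)`.
#'
#' @param clades list of character vectors (terminal-clone pattern labels per
#'   clade, each of length >= 2). Clades of size < 2 are dropped with a
#'   message.
#' @param B number of permutations (default 10,000).
#' @param seed optional integer seed.
#' @param weighted logical; weight clades by size in the pooled statistic.
#' @return List of class `ConcordanceResult`: `observed`, `perClade`,
#'   `null` (numeric vector of B null statistics), `p`, `B`, `nClades`.
#' @export
concordanceTest <- function(clades, B = 10000L, seed = NULL,
                            weighted = FALSE) {
  if (B < 1) stop("B must be at least 1")
  sizes <- lengths(clades)
  if (any(sizes < 2)) {
    message("dropping ", sum(sizes < 2), " clade(s) with fewer than 2 clones")
    clades <- clades[sizes >= 2]
  }
  if (!length(clades)) stop("no eligible clade (size >= 2)")
  if (!is.null(seed)) set.seed(seed)

  pool <- unlist(clades, use.names = FALSE)
  lev <- unique(pool)
  poolCode <- match(pool, lev)
  sizes <- lengths(clades)
  if (max(sizes) > length(pool))
    stop("largest clade exceeds the pooled clone count")

  perClade <- vapply(clades, function(cl) concordanceScore(cl)$score, 1)
  w <- if (weighted) sizes / sum(sizes) else rep(1 / length(sizes), length(sizes))
  observed <- sum(w * perClade)

  nullStat <- vapply(seq_len(B), function(b) {
    s <- vapply(sizes, function(k) {
      drawn <- poolCode[sample.int(length(poolCode), k)]
      max(tabulate(drawn, nbins = length(lev))) / k
    }, 1)
    sum(w * s)
  }, 1)
  p <- (1 + sum(nullStat >= observed - 1e-12)) / (B + 1)
  structure(list(observed = observed, perClade = perClade, null = nullStat,
                 p = p, B = B, nClades = length(clades)),
            class = "ConcordanceResult")
}

#' Phylogenetic weight matrix
#'
#' Weights are the inverse of one plus the pairwise phylogenetic age
#' distance, `1/(1 + d)`, zeroed across donors and on the diagonal.
#'
#' @param dist symmetric matrix of phylogenetic age distances.
#' @param donor donor id per row/column of `dist`.
#' @return Symmetric weight matrix with a zero diagonal.
#' @export
phyloWeights <- function(dist, donor) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (length(donor) != n) stop("donor must match the distance matrix")
  if (any(abs(dist - t(dist)) > 1e-9)) stop("distance matrix must be symmetric")
  w <- 1 / (1 + dist)
  w[outer(donor, donor, "!=")] <- 0
  diag(w) <- 0
  w
}

#' Moran's I with phylogenetic weights
#'
#' For values x with mean x-bar and weight matrix W (see [phyloWeights()]):
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Expectation under no autocorrelation is `-1/(n-1)`; the variance uses the
#' normality assumption, and the one-sided (greater) p-value tests for
#' positive autocorrelation. A permutation p (label shuffling) is available
#' via `nsim`.
#'
#' @param values numeric vector (one clone value, e.g. a lineage MCF divided
#'   by the HSC MCF), or a matrix with one column per lineage.
#' @param dist symmetric phylogenetic age-distance matrix between clones.
#' @param donor donor id per clone; cross-donor weights are zero.
#' @param nsim permutation count for an optional permutation p (0 = off).
#' @param seed optional integer seed (permutation p only).
#' @return For a vector: list of class `MoranResult` with `I`, `expectation`,
#'   `variance`, `p` (normal approximation, one-sided greater), and `pSim`
#'   when `nsim > 0`. For a matrix: a data.frame with one row per column.
#' @export
moransI <- function(values, dist, donor, nsim = 0L, seed = NULL) {
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    out <- lapply(seq_len(ncol(values)), function(j)
      moransI(values[, j], dist, donor, nsim = nsim, seed = seed))
    return(data.frame(
      lineage = colnames(values) %||% paste0("V", seq_len(ncol(values))),
      I = vapply(out, `[[`, 1, "I"),
      expectation = vapply(out, `[[`, 1, "expectation"),
      variance = vapply(out, `[[`, 1, "variance"),
      p = vapply(out, `[[`, 1, "p"),
      row.names = NULL))
  }
  n <- length(values)
  w <- phyloWeights(dist, donor)
  if (n < 3 || sum(rowSums(w) > 0) < 3)
    stop("need at least 3 clones connected by nonzero weights")
  if (all(w == 0)) stop("weight graph is fully disconnected")
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) stop("constant values: Moran's I is undefined")

  S0 <- sum(w)
  I <- (n / S0) * as.numeric(t(z) %*% w %*% z) / s2
  E <- -1 / (n - 1)
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  V <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - E^2
  p <- pnorm((I - E) / sqrt(V), lower.tail = FALSE)

  res <- list(I = I, expectation = E, variance = V, p = p, n = n)
  if (nsim > 0) {
    if (!is.null(seed)) set.seed(seed)
    Isim <- vapply(seq_len(nsim), function(b) {
      zp <- sample(z)
      (n / S0) * as.numeric(t(zp) %*% w %*% zp) / s2
    }, 1)
    res$pSim <- (1 + sum(Isim >= I - 1e-12)) / (nsim + 1)
  }
  structure(res, class = "MoranResult")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Positivity-pattern label of a lineage profile
#'
#' Collapses a five-lineage positivity vector to the three canonical
#' concordance patterns: `all_positive`, `T_negative` (all but T),
#' `BT_negative` (all but B and T); anything else is `NA` and excluded
#' upstream of the concordance test.
#'
#' @param positive named logical vector over P, E, M, B, T.
#' @return One of the three labels, or `NA_character_`.
#' @export
positivityPattern <- function(positive) {
  stopifnot(all(.LINEAGES %in% names(positive)))
  pos <- .LINEAGES[positive[.LINEAGES]]
  if (setequal(pos, .LINEAGES)) return("all_positive")
  if (setequal(pos, c("P", "E", "M", "B"))) return("T_negative")
  if (setequal(pos, c("P", "E", "M"))) return("BT_negative")
  NA_character_
}
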