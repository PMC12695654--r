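## Classification of clonal lineage output across the five major blood
## lineages: platelet (P, via MkP), erythroid (E, via EP), myeloid (M), B and
## T. A clone is biased between two neighbouring lineages when their MCFs
## differ by more than `biasFold` (default 5); a named group call additionally
## requires the max/min MCF ratio within the involved group to stay below
## `balanceFold` (default 10). Only the canonical splits {P,E,M,B}|{T} and
## {P,E,M}|{B,T} receive named labels.

#' Nearest-neighbour gap structure of a lineage profile
#'
#' Orders the positive lineages by decreasing MCF (ties broken by the fixed
#' precedence P > E > M > B > T) and returns consecutive MCF ratios.
#' Negative lineages are excluded: they rank below any positive lineage.
#'
#' @param mcf named numeric vector of per-lineage MCFs with names among
#'   P, E, M, B, T.
#' @param positive named logical positivity per lineage (default: MCF > 0).
#' @return List with `lineages` (positive lineages, descending MCF), `mcf`
#'   (their values) and `ratios` (consecutive ratios, length
#'   `length(lineages) - 1`). With no positive lineage, a `no_output`
#'   sentinel: empty vectors and `noOutput = TRUE`.
#' @examples
#' gapStructure(c(P = .10, E = .09, M = .08, B = .07, T = .05))$ratios
#' @export
gapStructure <- function(mcf, positive = mcf > 0) {
  x <- .lineageVector(mcf, positive)
  pos <- names(x)[x > 0]
  if (!length(pos))
    return(list(lineages = character(0), mcf = numeric(0),
                ratios = numeric(0), noOutput = TRUE))
  ord <- pos[order(-x[pos], match(pos, .LINEAGES))]
  v <- unname(x[ord])
  ratios <- if (length(v) > 1) v[-length(v)] / v[-1] else numeric(0)
  ratios[is.nan(ratios)] <- 1
  list(lineages = ord, mcf = v, ratios = ratios, noOutput = FALSE)
}

## canonicalise to a full named P,E,M,B,T vector; negatives contribute 0
.lineageVector <- function(mcf, positive) {
  if (is.null(names(mcf)) || !all(names(mcf) %in% .LINEAGES))
    stop("mcf must be named with lineages among P, E, M, B, T")
  if (any(mcf < 0 | mcf > 1)) stop("MCFs must lie in [0, 1]")
  x <- setNames(numeric(5), .LINEAGES)
  x[names(mcf)] <- ifelse(positive, mcf, 0)
  x
}

#' Classify a clone's lineage output pattern
#'
#' Deterministic rule-based call on the five-lineage MCF profile:
#' \itemize{
#'   \item `PEMBT_balanced`: all five lineages positive, no
#'     nearest-neighbour ratio above `biasFold`, and max/min below
#'     `balanceFold`.
#'   \item `PEMB_restricted` / `PEMB_biased`: P, E, M, B form the top group
#'     (no gap inside it, max/min < `balanceFold`) separated from T by more
#'     than `biasFold`; restricted when T is negative, biased when T is
#'     positive but suppressed.
#'   \item `PEM_restricted` / `PEM_biased`: analogous with {P,E,M} over
#'     {B,T}; biased when at least one of B, T is positive (and no
#'     >`biasFold` gap between positive B and T, which would be a
#'     non-canonical structure).
#'   \item `other_unique`: any other involvement set or gap structure.
#'   \item `no_output`: no positive lineage.
#' }
#' Ratios against a zero (negative) lineage count as infinite, hence always
#' exceed `biasFold`. The call is invariant to a common rescaling of all
#' MCFs.
#'
#' @inheritParams gapStructure
#' @param biasFold nearest-neighbour fold-change defining a bias (strict >).
#' @param balanceFold max/min fold bound within the involved group (strict <).
#' @return List with `label`, `involved` (positive lineages), `gapRatio`
#'   (top-group min over bottom-group max, `Inf` against negatives) and
#'   `topSpread` (top-group max/min).
#' @examples
#' classifyPattern(c(P = .10, E = .09, M = .08, B = .07, T = 0))$label
#' @export
classifyPattern <- function(mcf, positive = mcf > 0, biasFold = 5,
                            balanceFold = 10) {
  x <- .lineageVector(mcf, positive)
  involved <- names(x)[x > 0]
  res <- function(label, gapRatio = NA_real_, topSpread = NA_real_)
    list(label = label, involved = involved, gapRatio = gapRatio,
         topSpread = topSpread)
  if (!length(involved)) return(res("no_output"))

  gs <- gapStructure(x)
  gaps <- which(gs$ratios > biasFold)

  grp <- function(top) {
    bottom <- setdiff(.LINEAGES, top)
    gap <- min(x[top]) / max(x[bottom], 0)
    if (is.nan(gap)) gap <- Inf  # 0/0: no bottom signal at all
    spread <- max(x[top]) / min(x[top])
    list(gap = gap, spread = spread)
  }

  if (setequal(involved, .LINEAGES)) {
    g <- grp(.LINEAGES)
    if (!length(gaps) && g$spread < balanceFold)
      return(res("PEMBT_balanced", Inf, g$spread))
    if (identical(gaps, 4L) && setequal(gs$lineages[1:4], c("P", "E", "M", "B"))) {
      g4 <- grp(c("P", "E", "M", "B"))
      if (g4$spread < balanceFold)
        return(res("PEMB_biased", g4$gap, g4$spread))
    }
    if (identical(gaps, 3L) && setequal(gs$lineages[1:3], c("P", "E", "M"))) {
      g3 <- grp(c("P", "E", "M"))
      if (g3$spread < balanceFold)
        return(res("PEM_biased", g3$gap, g3$spread))
    }
    return(res("other_unique"))
  }

  if (setequal(involved, c("P", "E", "M", "B"))) {
    g4 <- grp(c("P", "E", "M", "B"))
    if (!length(gaps) && g4$spread < balanceFold)
      return(res("PEMB_restricted", g4$gap, g4$spread))
    if (identical(gaps, 3L) && setequal(gs$lineages[1:3], c("P", "E", "M"))) {
      g3 <- grp(c("P", "E", "M"))
      if (g3$spread < balanceFold)
        return(res("PEM_biased", g3$gap, g3$spread))
    }
    return(res("other_unique"))
  }

  if (setequal(involved, c("P", "E", "M", "T"))) {
    ## bottom group {B, T} with B negative, T suppressed
    if (identical(gaps, 3L) && setequal(gs$lineages[1:3], c("P", "E", "M"))) {
      g3 <- grp(c("P", "E", "M"))
      if (g3$spread < balanceFold)
        return(res("PEM_biased", g3$gap, g3$spread))
    }
    return(res("other_unique"))
  }

  if (setequal(involved, c("P", "E", "M"))) {
    g3 <- grp(c("P", "E", "M"))
    if (!length(gaps) && g3$spread < balanceFold)
      return(res("PEM_restricted", g3$gap, g3$spread))
    return(res("other_unique"))
  }

  res("other_unique")
}

#' Tabulate pattern calls across clones
#'
#' Counts each label and reports the pooled subtotals used in the study's
#' summaries: PEMB restricted + biased, PEM restricted + biased, and the
#' positivity-level groups (all five lineages involved, T-negative,
#' B/T-negative).
#'
#' @param labels character vector of labels from [classifyPattern()].
#' @return List with `counts` (named integer vector over all labels),
#'   `pooled` (`PEMB`, `PEM`), and `total`.
#' @export
patternCensus <- function(labels) {
  stopifnot(all(labels %in% .PATTERN_LABELS))
  counts <- table(factor(labels, levels = .PATTERN_LABELS))
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts,
       pooled = c(PEMB = counts[["PEMB_restricted"]] + counts[["PEMB_biased"]],
                  PEM = counts[["PEM_restricted"]] + counts[["PEM_biased"]]),
       total = length(labels))
}
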