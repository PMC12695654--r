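#' Ternary genotype matrix from colony read counts
#'
#' Entry rules: positive when VAF >= 0.15 and mutant reads >= 2; negative
#' when mutant reads = 0 and total reads >= 5; unknown otherwise.
#'
#' @param reads data.frame with columns `colony`, `mutationId`, `mutReads`,
#'   `totalReads` (one row per colony x mutation).
#' @param vafCut,minMutReads positivity thresholds.
#' @param minNegReads minimum depth for a confident negative.
#' @return A [GenotypeMatrix-class].
#' @examples
#' r <- data.frame(colony = "c1", mutationId = "m1",
#'                 mutReads = 3, totalReads = 15)
#' genotypeCalls(buildGenotypeMatrix(r))
#' @export
buildGenotypeMatrix <- function(reads, vafCut = 0.15, minMutReads = 2,
                                minNegReads = 5) {
  need <- c("colony", "mutationId", "mutReads", "totalReads")
  if (!all(need %in% names(reads)))
    stop("reads needs columns: ", paste(need, collapse = ", "))
  if (any(reads$mutReads > reads$totalReads))
    stop("mutant reads exceed total reads in ",
         sum(reads$mutReads > reads$totalReads), " row(s)")
  if (any(reads$mutReads < 0)) stop("negative read counts")
  colonies <- unique(reads$colony); muts <- unique(reads$mutationId)
  shape <- function(v) {
    m <- matrix(NA_real_, length(colonies), length(muts),
                dimnames = list(colonies, muts))
    m[cbind(match(reads$colony, colonies), match(reads$mutationId, muts))] <- v
    m
  }
  mut <- shape(reads$mutReads); tot <- shape(reads$totalReads)
  vaf <- ifelse(tot > 0, mut / tot, 0)
  calls <- matrix(NA_integer_, length(colonies), length(muts),
                  dimnames = list(colonies, muts))
  calls[vaf >= vafCut & mut >= minMutReads] <- 1L
  calls[mut == 0 & tot >= minNegReads] <- 0L
  new("GenotypeMatrix", calls = calls,
      mutReads = mut, totalReads = tot)
}

#' Colony purity check
#'
#' Single-cell-derived colonies carry their heterozygous somatic mutations at
#' VAF near 0.5; pooled or cross-contaminated wells dilute this. A colony
#' fails when the median VAF over its carried (positive) mutations falls
#' outside `window`, or its mean depth is below `depthFloor`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param window acceptable VAF window (default `c(0.35, 0.65)`).
#' @param depthFloor minimum mean depth (default 8).
#' @return data.frame per colony: `colony`, `medianVaf`, `meanDepth`, `pass`.
#' @export
colonyPurity <- function(gm, window = c(0.35, 0.65), depthFloor = 8) {
  stopifnot(is(gm, "GenotypeMatrix"))
  calls <- gm@calls
  out <- data.frame(colony = rownames(calls),
                    medianVaf = NA_real_, meanDepth = NA_real_,
                    pass = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    carried <- which(calls[i, ] == 1L)
    vafs <- gm@mutReads[i, carried] / gm@totalReads[i, carried]
    out$medianVaf[i] <- if (length(carried)) median(vafs) else NA_real_
    out$meanDepth[i] <- mean(gm@totalReads[i, ], na.rm = TRUE)
    out$pass[i] <- length(carried) > 0 &&
      out$medianVaf[i] >= window[1] && out$medianVaf[i] <= window[2] &&
      out$meanDepth[i] >= depthFloor
  }
  out
}

#' Perfect phylogeny from a clean genotype matrix
#'
#' Builds the tree whose clades are exactly the mutation carrier sets.
#' Unknown entries are treated as non-carriers when forming carrier sets
#' (matrices are near-complete at the intended depths). Mutations carried by
#' every colony become the root edge; mutations private to one colony sit on
#' its terminal branch. Any two carrier sets must be nested or disjoint —
#' with the wild type as root state this is the four-gamete condition — else
#' an error names the offending mutation pair.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return A [CladeTree-class] with branch lengths equal to the number of
#'   mutations mapping to each clade (tips without private mutations get 0).
#' @export
perfectPhylogeny <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  calls <- gm@calls
  calls[is.na(calls)] <- 0L
  colonies <- rownames(calls)
  n <- length(colonies)
  sets <- apply(calls, 2, function(col) which(col == 1L), simplify = FALSE)
  sets <- lapply(sets, as.integer)
  nonEmpty <- lengths(sets) > 0
  sets <- sets[nonEmpty]

  keys <- vapply(sets, paste, "", collapse = ",")
  mutOfKey <- split(names(sets), keys)
  uniq <- sets[!duplicated(keys)]
  names(uniq) <- keys[!duplicated(keys)]

  ## pairwise nested-or-disjoint check (four-gamete test with wild-type root)
  uniq <- uniq[order(-lengths(uniq))]
  for (i in seq_along(uniq)) for (j in seq_len(max(i - 1L, 0L))) {
    a <- uniq[[i]]; b <- uniq[[j]]  # |a| <= |b|
    inter <- length(intersect(a, b))
    if (inter > 0 && !all(a %in% b))
      stop("genotype matrix admits no perfect phylogeny: mutations ",
           mutOfKey[[names(uniq)[j]]][1], " and ",
           mutOfKey[[names(uniq)[i]]][1],
           " have overlapping, non-nested carrier sets")
  }

  full <- seq_len(n)
  rootCount <- 0L
  inner <- list()
  for (k in names(uniq)) {
    s <- uniq[[k]]
    cnt <- length(mutOfKey[[k]])
    if (length(s) == n) rootCount <- rootCount + cnt
    else inner[[length(inner) + 1L]] <- list(set = s, count = cnt)
  }

  build <- function(set, members) {
    ## members: indices into `inner` of sets strictly inside `set`;
    ## children are the maximal ones
    isMax <- vapply(members, function(i)
      !any(vapply(members, function(j)
        i != j && length(inner[[i]]$set) < length(inner[[j]]$set) &&
          all(inner[[i]]$set %in% inner[[j]]$set), TRUE)), TRUE)
    childIdx <- members[isMax]
    pieces <- character(0)
    covered <- integer(0)
    for (i in childIdx) {
      s <- inner[[i]]$set
      covered <- c(covered, s)
      sub <- members[vapply(members, function(j)
        j != i && all(inner[[j]]$set %in% s) &&
          length(inner[[j]]$set) < length(s), TRUE)]
      if (length(s) == 1) {
        pieces <- c(pieces, sprintf("%s:%d", colonies[s], inner[[i]]$count))
      } else {
        pieces <- c(pieces, sprintf("(%s):%d", build(s, sub), inner[[i]]$count))
      }
    }
    loners <- setdiff(set, covered)
    pieces <- c(pieces, sprintf("%s:0", colonies[loners]))
    paste(pieces, collapse = ",")
  }

  nwk <- sprintf("(%s):%d;", build(full, seq_along(inner)), rootCount)
  tr <- ape::read.tree(text = nwk)
  if (ape::Ntip(tr) == 1)
    stop("perfect phylogeny needs at least 2 colonies")
  cladeTree(tr)
}

#' Convert a mutation-count tree to an age scale from conception
#'
#' Assumes a constant lifelong mutation rate. The timeline runs from
#' conception (age 0) to sampling at `S = ageYears + gestationWeeks*7/365.25`
#' years. Node ages are assigned top-down:
#' `age(child) = age(parent) + (S - age(parent)) * b / (b + mBelow)` where
#' `b` is the branch's mutation count and `mBelow` the mean count from the
#' child to the tips below it. Tips land exactly at `S`; ages are monotone
#' along every root-to-tip path; when all root-to-tip counts are equal the
#' scheme reduces to exact proportionality. A root edge, when present, is the
#' branch out of conception.
#'
#' @param tree a [CladeTree-class].
#' @param ageYears donor age at sampling (defaults to the tree's donorAge).
#' @param gestationWeeks gestation length (defaults to the tree's).
#' @return The tree with `nodeAges` filled and dating metadata set.
#' @examples
#' tr <- cladeTree(ape::read.tree(text = "((A:50,B:50):50,C:100):0;"),
#'                 donorAge = 80)
#' nodeAges(makeUltrametric(tr))
#' @export
makeUltrametric <- function(tree, ageYears = NULL, gestationWeeks = NULL) {
  stopifnot(is(tree, "CladeTree"))
  if (!is.null(ageYears)) tree@donorAge <- as.numeric(ageYears)
  if (!is.null(gestationWeeks)) tree@gestationWeeks <- as.numeric(gestationWeeks)
  if (is.na(tree@donorAge)) stop("donor age at sampling is required")
  S <- timelineSpan(tree)
  tr <- treePhylo(tree)
  nt <- ape::Ntip(tr)

  depth <- ape::node.depth.edgelength(tr)
  rootEdge <- if (is.null(tr$root.edge)) 0 else tr$root.edge
  if (any(depth[seq_len(nt)] + rootEdge <= 0))
    stop("every root-to-tip mutation count must be positive")

  ## mean count from each node down to the tips below it
  tipSets <- .tipsBelow(tr)
  mBelow <- vapply(seq_along(tipSets), function(nd) {
    tips <- tipSets[[nd]]
    mean(depth[tips] - depth[nd])
  }, numeric(1))

  ages <- numeric(nt + tr$Nnode)
  root <- nt + 1L
  ages[root] <- S * rootEdge / (rootEdge + mBelow[root])
  for (e in rev(ape::postorder(tr))) {  # parents before children
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    b <- tr$edge.length[e]
    denom <- b + mBelow[ch]
    ages[ch] <- if (denom == 0) ages[p]
                else ages[p] + (S - ages[p]) * b / denom
  }
  ages[seq_len(nt)] <- S  # tips sit exactly at sampling
  tree@nodeAges <- ages
  tree
}

#' Date a mutation's acquisition on a branch
#'
#' The branch is identified by its child node id. The `distal` convention
#' (default, used for driver mutations: descendants replace ancestors, so
#' expansion starts at the branch's distal end) returns the child-node age;
#' `proximal` the parent-node age (0 = conception for the root edge);
#' `midpoint` their mean.
#'
#' @param tree an ultrametric [CladeTree-class] (see [makeUltrametric()]).
#' @param node child node id of the branch.
#' @param convention `"distal"`, `"midpoint"` or `"proximal"`.
#' @return Age in years from conception.
#' @export
dateMutation <- function(tree, node,
                         convention = c("distal", "midpoint", "proximal")) {
  convention <- match.arg(convention)
  ages <- nodeAges(tree)
  tr <- treePhylo(tree)
  if (node < 1 || node > length(ages)) stop("no such node: ", node)
  child <- ages[node]
  root <- ape::Ntip(tr) + 1L
  parent <- if (node == root) 0 else {
    e <- which(tr$edge[, 2] == node)
    if (!length(e)) stop("node ", node, " has no parent branch")
    ages[tr$edge[e, 1]]
  }
  switch(convention, distal = child, proximal = parent,
         midpoint = (child + parent) / 2)
}

## exact (Garwood) Poisson interval on an observed count
.poissonBounds <- function(k, level = 0.95) {
  a <- (1 - level) / 2
  lo <- ifelse(k > 0, qgamma(a, k), 0)
  hi <- qgamma(1 - a, k + 1)
  cbind(lo = lo, hi = hi)
}

#' Confidence interval for a mutation's acquisition age
#'
#' Each branch's mutation count receives an exact (Garwood) Poisson
#' confidence interval. The lower age bound comes from a perturbed tree with
#' the branches on the root-to-node path at their lower count bounds and all
#' remaining branches at their upper bounds; the upper age bound reverses
#' the roles. Each perturbed tree is re-scaled to ultrametric form over the
#' same timeline span before the node is dated, so the bounds bracket the
#' point estimate by construction.
#'
#' With `method = "rate"`, the interval for each branch is built around the
#' expected count (tree-average mutation rate times the branch's current
#' duration) instead of the observed count.
#'
#' @inheritParams dateMutation
#' @param level confidence level (default 0.95).
#' @param method `"count"` (default, interval on the observed count) or
#'   `"rate"`.
#' @return List: `point`, `lo`, `hi` (ages in years from conception) and
#'   `convention`.
#' @export
datingCI <- function(tree, node, level = 0.95,
                     convention = c("distal", "midpoint", "proximal"),
                     method = c("count", "rate")) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  tree <- if (length(tree@nodeAges)) tree else makeUltrametric(tree)
  tr <- treePhylo(tree)
  nt <- ape::Ntip(tr)
  root <- nt + 1L
  point <- dateMutation(tree, node, convention)

  ## branches on the path root -> node (by child id), root edge handled apart
  path <- integer(0)
  nd <- node
  while (nd != root) {
    path <- c(path, nd)
    nd <- tr$edge[which(tr$edge[, 2] == nd), 1]
  }
  onPath <- tr$edge[, 2] %in% path
  rootEdge <- if (is.null(tr$root.edge)) 0 else tr$root.edge

  if (method == "count") {
    bEdge <- .poissonBounds(tr$edge.length, level)
    bRoot <- .poissonBounds(rootEdge, level)
  } else {
    ages <- nodeAges(tree)
    dur <- ages[tr$edge[, 2]] - ages[tr$edge[, 1]]
    S <- timelineSpan(tree)
    depth <- ape::node.depth.edgelength(tr)
    rate <- mean(depth[seq_len(nt)] + rootEdge) / S
    bEdge <- .poissonBounds(rate * dur, level)
    bRoot <- .poissonBounds(rate * ages[root], level)
  }

  perturb <- function(pathCol, otherCol) {
    tr2 <- tr
    tr2$edge.length <- ifelse(onPath, bEdge[, pathCol], bEdge[, otherCol])
    tr2$root.edge <- bRoot[, pathCol]  # upstream of the node by definition
    t2 <- tree
    t2@phylo <- tr2
    t2@nodeAges <- numeric(0)
    dateMutation(makeUltrametric(t2), node, convention)
  }
  lo <- perturb("lo", "hi")
  hi <- perturb("hi", "lo")
  list(point = point, lo = min(lo, point), hi = max(hi, point),
       convention = convention)
}

#' Filter clades eligible for lineage tracing
#'
#' Clades enter the tracing analysis only when their marker mutation reaches
#' an MCF of at least `cut` (default 2%) in immunophenotypic HSCs.
#'
#' @param hscMcf named numeric vector: per-clade HSC MCF.
#' @param cut retention threshold (default 0.02).
#' @return Character vector of retained clade names.
#' @export
cladeFilterForTracing <- function(hscMcf, cut = 0.02) {
  if (!length(hscMcf)) return(character(0))
  keep <- names(hscMcf)[hscMcf >= cut]
  dropped <- setdiff(names(hscMcf), keep)
  if (length(dropped))
    message("dropped ", length(dropped), " clade(s) below ",
            100 * cut, "% HSC MCF: ", paste(dropped, collapse = ", "))
  keep
}
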