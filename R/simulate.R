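## Synthetic cohort generator. Defaults emulate the study conditions: aged
## donors carrying expanded HSC clones with balanced (PEMBT), PEMB- and
## PEM-restricted/-biased output patterns, >8,000-droplet duplex ddPCR wells,
## and phylogenies with constant lifelong mutation accumulation plus expanded
## clades for each traced clone. Every generator emits its ground truth.

.PATTERN_MIX_DEFAULT <- c(PEMBT_balanced = 15, PEMB_restricted = 13,
                          PEMB_biased = 12, PEM_restricted = 7,
                          PEM_biased = 6, other_unique = 4) / 57

#' Simulate a donor with expanded HSC clones
#'
#' Draws `nClones` clones with HSC mutant cell fractions from a log-normal
#' (defaults calibrated so the mean MCF is about 3%), assigns each a lineage
#' output pattern from `patternMix`, and realises per-lineage true MCFs that
#' satisfy the classification rules by construction: restricted lineages get
#' exactly 0; biased patterns place the suppressed lineages at
#' HSC-MCF / U(6, 50) below top-group factors of U(1, 2), guaranteeing the
#' >5-fold gap; balanced/restricted positive lineages use factors U(0.5, 2)
#' (max ratio 4, inside both fold rules).
#'
#' @param age donor age at sampling in years (> 18).
#' @param nClones number of clones to draw (0 allowed).
#' @param patternMix named probability vector over the six pattern labels.
#' @param seed optional integer seed.
#' @param sex donor sex (sampled if `NULL`).
#' @param mcfMeanlog,mcfSdlog log-normal parameters of the HSC MCF.
#' @param driverProb probability a clone is marked by a CH driver mutation.
#' @param acquisitionWindow years-from-conception window (lo, hi) for clone
#'   acquisition ages; defaults to (10, age - 5).
#' @param maxTries retries when a lineage's summed MCF exceeds 1.
#' @return A list of class `SimDonor`: `donorId`, `age`, `sex`, and `clones`,
#'   a data.frame with one row per clone (mutationId, driverFlag, pattern,
#'   trueMcfHsc, mcfP/E/M/B/T, acquisitionAge).
#' @examples
#' d <- simulateDonor(75, nClones = 3, seed = 1)
#' d$clones[, c("pattern", "trueMcfHsc")]
#' @export
simulateDonor <- function(age, nClones,
                          patternMix = .PATTERN_MIX_DEFAULT,
                          seed = NULL, sex = NULL,
                          mcfMeanlog = log(0.022), mcfSdlog = 0.8,
                          driverProb = 47 / 57,
                          acquisitionWindow = c(10, age - 5),
                          maxTries = 20L) {
  if (age <= 18) stop("donor age must exceed 18 years")
  if (nClones < 0) stop("nClones must be non-negative")
  if (abs(sum(patternMix) - 1) > 1e-8) stop("patternMix must sum to 1")
  if (!all(names(patternMix) %in% .PATTERN_LABELS))
    stop("patternMix names must be pattern labels")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sex)) sex <- sample(c("M", "F"), 1)

  for (attempt in seq_len(maxTries)) {
    clones <- .drawClones(nClones, patternMix, mcfMeanlog, mcfSdlog,
                          driverProb, acquisitionWindow)
    tot <- colSums(clones[, paste0("mcf", .LINEAGES), drop = FALSE])
    if (nClones == 0 || (all(tot <= 1) && sum(clones$trueMcfHsc) <= 1)) {
      return(structure(list(
        donorId = sprintf("SD%04d", sample.int(9999L, 1)),
        age = age, sex = sex, clones = clones), class = "SimDonor"))
    }
  }
  stop("could not draw a feasible clone set (lineage MCF sum > 1) in ",
       maxTries, " attempts")
}

.drawClones <- function(n, mix, meanlog, sdlog, driverProb, window) {
  pat <- if (n > 0) sample(names(mix), n, replace = TRUE, prob = mix) else character(0)
  hsc <- pmin(rlnorm(n, meanlog, sdlog), 0.9)
  out <- data.frame(mutationId = sprintf("mut%03d", seq_len(n)),
                    driverFlag = runif(n) < driverProb,
                    pattern = pat, trueMcfHsc = hsc,
                    stringsAsFactors = FALSE)
  fac <- matrix(0, nrow = n, ncol = 5, dimnames = list(NULL, .LINEAGES))
  for (i in seq_len(n)) fac[i, ] <- .patternFactors(pat[i])
  for (l in .LINEAGES) out[[paste0("mcf", l)]] <- pmin(fac[, l] * hsc, 1)
  out$acquisitionAge <- runif(n, window[1], window[2])
  out
}

## per-lineage multipliers of the HSC MCF realising each pattern
.patternFactors <- function(pattern) {
  f <- setNames(numeric(5), .LINEAGES)
  balanced <- function(k) runif(k, 0.5, 2)
  top <- function(k) runif(k, 1, 2)
  ## one shared fold-down plus a mild per-lineage factor keeps the suppressed
  ## group itself tight (no secondary >5-fold gap inside it)
  suppressed <- function(k) 1 / (runif(1, 6, 30) * runif(k, 1, 1.6))
  switch(pattern,
    PEMBT_balanced = { f[] <- balanced(5) },
    PEMB_restricted = { f[c("P", "E", "M", "B")] <- balanced(4) },
    PEMB_biased = { f[c("P", "E", "M", "B")] <- top(4); f["T"] <- suppressed(1) },
    PEM_restricted = { f[c("P", "E", "M")] <- balanced(3) },
    PEM_biased = { f[c("P", "E", "M")] <- top(3); f[c("B", "T")] <- suppressed(2) },
    other_unique = {
      ## a non-canonical involvement set, each observed only rarely in vivo
      pick <- sample(list(c("P"), c("P", "M"), c("E", "M"), c("P", "E")), 1)[[1]]
      f[pick] <- balanced(length(pick))
    },
    stop("unknown pattern label: ", pattern))
  f
}

#' Simulate one duplex ddPCR well
#'
#' Two sampling paths, identical in distribution. `"molecules"` draws the
#' total mutant and wild-type template molecules as Poisson with means
#' `nCells * trueMcf * mutCopies * efficiency` and
#' `nCells * (ploidy - trueMcf * mutCopies) * efficiency`, scatters them
#' uniformly over droplets and tabulates quadrants. `"multinomial"` draws the
#' quadrant counts directly from the closed-form Poisson-occupancy
#' probabilities of [quadrantProbs()].
#'
#' @param trueMcf true mutant cell fraction in \[0, 1\].
#' @param nCells cells loaded into the reaction.
#' @param nDroplets accepted droplets (default 14,000).
#' @param efficiency extraction efficiency (> 0).
#' @param chromClass,sex genetic context (see [ploidyOf()]).
#' @param mutCopies mutant copies per mutant cell.
#' @param method `"molecules"` or `"multinomial"`.
#' @param seed optional integer seed.
#' @return A [DropletAssay-class].
#' @examples
#' simulateDdpcr(0.05, nCells = 2000, seed = 1)
#' @export
simulateDdpcr <- function(trueMcf, nCells, nDroplets = 14000,
                          efficiency = 0.5, chromClass = "autosome",
                          sex = "F", mutCopies = 1,
                          method = c("molecules", "multinomial"),
                          seed = NULL) {
  method <- match.arg(method)
  if (nDroplets < 1) stop("nDroplets must be at least 1")
  if (efficiency <= 0) stop("efficiency must be positive")
  if (trueMcf < 0 || trueMcf > 1) stop("trueMcf must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- ploidyOf(chromClass, sex)

  if (method == "molecules") {
    nm <- rpois(1, nCells * trueMcf * mutCopies * efficiency)
    nw <- rpois(1, nCells * max(p - trueMcf * mutCopies, 0) * efficiency)
    hasM <- tabulate(sample.int(nDroplets, nm, replace = TRUE), nDroplets) > 0
    hasW <- tabulate(sample.int(nDroplets, nw, replace = TRUE), nDroplets) > 0
    cts <- c(sum(!hasM & !hasW), sum(hasM & !hasW),
             sum(!hasM & hasW), sum(hasM & hasW))
  } else {
    lam <- lambdasFromState(trueMcf, efficiency, nCells, nDroplets, p, mutCopies)
    cts <- as.vector(rmultinom(1, nDroplets,
                               quadrantProbs(lam$lambdaM, lam$lambdaW)))
  }
  DropletAssay(cts[1], cts[2], cts[3], cts[4], nCells = nCells,
               chromClass = chromClass, sex = sex)
}

#' Simulate a colony phylogeny with expanded clonal clades
#'
#' Builds the donor's colony tree in age space and converts branch durations
#' to mutation counts under a constant lifelong rate. Background lineages
#' split in a single early developmental burst (age `tDev`); each clone with
#' at least two sampled colonies forms a clade whose stem runs from the burst
#' to the clone's acquisition age, where the clonal expansion fans out. Each
#' colony falls into clone i with probability equal to that clone's HSC MCF
#' (multinomial), so clade tip fractions track clone size. Branch mutation
#' counts are Poisson(rate x duration); clade stems carry at least the
#' clone-defining mutation. Mutations predating the burst appear on the root
#' edge (shared by every colony).
#'
#' @param donor a `SimDonor` from [simulateDonor()].
#' @param nColonies number of sequenced colonies (>= 2).
#' @param mutationRate somatic mutations per year (default 17).
#' @param tDev age (years from conception) of the developmental burst.
#' @param gestationWeeks gestation length in weeks.
#' @param seed optional integer seed.
#' @return A list: `tree` (a [CladeTree-class] with mutation-count branch
#'   lengths), and `truth`, a data.frame per clone with its stem's child node
#'   id (`nodeId`, NA when undetectable), clade tips, true acquisition age and
#'   a `detectable` flag (>= 2 sampled colonies).
#' @export
simulatePhylogeny <- function(donor, nColonies, mutationRate = 17,
                              tDev = 0.3, gestationWeeks = 40, seed = NULL) {
  stopifnot(inherits(donor, "SimDonor"))
  if (nColonies < 2) stop("need at least 2 colonies")
  if (mutationRate < 0) stop("mutation rate must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  S <- donor$age + gestationWeeks * 7 / 365.25
  cl <- donor$clones
  nCl <- nrow(cl)
  probs <- c(if (nCl) cl$trueMcfHsc else numeric(0))
  pBg <- 1 - sum(probs)
  if (pBg < 0) stop("clone HSC MCFs sum beyond 1")
  alloc <- as.vector(rmultinom(1, nColonies, c(probs, pBg)))
  tipNames <- sprintf("c%03d", seq_len(nColonies))

  pieces <- character(0)
  truth <- data.frame(mutationId = character(0), cladeTips = character(0),
                      trueAcquisitionAge = numeric(0), detectable = logical(0),
                      nodeId = integer(0), stringsAsFactors = FALSE)
  used <- 0L
  draw <- function(dur) rpois(1, mutationRate * dur)
  for (i in seq_len(nCl)) {
    k <- alloc[i]
    tips <- tipNames[seq_len(k) + used]; used <- used + k
    a <- cl$acquisitionAge[i]
    detectable <- k >= 2
    if (k >= 2) {
      term <- vapply(tips, function(t) sprintf("%s:%d", t, draw(S - a)), "")
      stem <- max(1L, draw(a - tDev))
      pieces <- c(pieces, sprintf("(%s):%d", paste(term, collapse = ","), stem))
    } else if (k == 1) {
      pieces <- c(pieces, sprintf("%s:%d", tips, draw(S - tDev)))
      warning("clone ", cl$mutationId[i], " received ", k,
              " colonies; marked undetectable")
    } else {
      warning("clone ", cl$mutationId[i], " received 0 colonies; ",
              "marked undetectable")
    }
    truth <- rbind(truth, data.frame(
      mutationId = cl$mutationId[i],
      cladeTips = paste(tips, collapse = ";"),
      trueAcquisitionAge = a, detectable = detectable,
      nodeId = NA_integer_, stringsAsFactors = FALSE))
  }
  bg <- tipNames[seq.int(used + 1L, length.out = nColonies - used)]
  pieces <- c(pieces, vapply(bg, function(t)
    sprintf("%s:%d", t, draw(S - tDev)), ""))
  rootCount <- draw(tDev)
  nwk <- sprintf("(%s):%d;", paste(pieces, collapse = ","), rootCount)
  tr <- ape::read.tree(text = nwk)
  ct <- cladeTree(tr, donorAge = donor$age, gestationWeeks = gestationWeeks)

  ## resolve each detectable clone's stem to the child node of its clade
  for (i in seq_len(nrow(truth))) {
    if (!truth$detectable[i]) next
    tips <- strsplit(truth$cladeTips[i], ";", fixed = TRUE)[[1]]
    truth$nodeId[i] <- ape::getMRCA(tr, tips)
  }
  list(tree = ct, truth = truth)
}

#' Simulate colony read counts over the tree's mutations
#'
#' Expands each branch's mutation count into individual mutations carried by
#' the colonies below that branch (root-edge mutations by every colony), then
#' draws per colony x mutation total reads ~ Poisson(meanDepth) and mutant
#' reads ~ Binomial(total, 0.5) for carriers (heterozygous autosomal) or
#' Binomial(total, errorRate) for non-carriers.
#'
#' @param tree a [CladeTree-class] (e.g. from [simulatePhylogeny()]).
#' @param meanDepth mean sequencing depth (> 0).
#' @param errorRate per-read error VAF for non-carriers (< 0.5).
#' @param seed optional integer seed.
#' @return A list: `reads`, a data.frame (colony, mutationId, mutReads,
#'   totalReads), and `mutationEdges`, mapping mutationId to the child node id
#'   of its branch (0 for the root edge).
#' @export
simulateColonyReads <- function(tree, meanDepth, errorRate = 0, seed = NULL) {
  stopifnot(is(tree, "CladeTree"))
  if (meanDepth <= 0) stop("meanDepth must be positive")
  if (errorRate < 0 || errorRate >= 0.5)
    stop("errorRate must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  tr <- treePhylo(tree)
  nt <- ape::Ntip(tr)
  tipSets <- .tipsBelow(tr)

  ids <- character(0); nodes <- integer(0); carriers <- list()
  rc <- if (is.null(tr$root.edge)) 0L else as.integer(tr$root.edge)
  if (rc > 0) {
    ids <- sprintf("m_root_%02d", seq_len(rc))
    nodes <- rep(0L, rc)
    carriers <- rep(list(seq_len(nt)), rc)
  }
  for (e in seq_len(nrow(tr$edge))) {
    k <- as.integer(tr$edge.length[e])
    if (k <= 0) next
    child <- tr$edge[e, 2]
    ids <- c(ids, sprintf("m_n%03d_%02d", child, seq_len(k)))
    nodes <- c(nodes, rep(child, k))
    carriers <- c(carriers, rep(list(tipSets[[child]]), k))
  }
  nMut <- length(ids)
  if (nMut == 0) stop("tree carries no mutations")

  carrierMat <- matrix(FALSE, nrow = nt, ncol = nMut)
  for (j in seq_len(nMut)) carrierMat[carriers[[j]], j] <- TRUE
  total <- matrix(rpois(nt * nMut, meanDepth), nrow = nt)
  pmat <- ifelse(carrierMat, 0.5, errorRate)
  mut <- matrix(rbinom(nt * nMut, as.vector(total), as.vector(pmat)),
                nrow = nt)
  reads <- data.frame(
    colony = rep(tr$tip.label, nMut),
    mutationId = rep(ids, each = nt),
    mutReads = as.vector(mut), totalReads = as.vector(total),
    stringsAsFactors = FALSE)
  list(reads = reads,
       mutationEdges = data.frame(mutationId = ids, nodeId = nodes,
                                  stringsAsFactors = FALSE))
}

## tip indices below every node (tips themselves included), list indexed by node id
.tipsBelow <- function(tr) {
  nt <- ape::Ntip(tr); nn <- tr$Nnode
  out <- vector("list", nt + nn)
  for (i in seq_len(nt)) out[[i]] <- i
  ## accumulate children into parents in postorder
  for (e in ape::postorder(tr)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  lapply(out, sort)
}
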