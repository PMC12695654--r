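## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## Monte-Carlo droplet partitioning: scatter Poisson molecule totals over
## droplets and tabulate quadrant fractions.
mcQuadrantFractions <- function(lambdaM, lambdaW, nDroplets) {
  nm <- rpois(1, lambdaM * nDroplets)
  nw <- rpois(1, lambdaW * nDroplets)
  hasM <- tabulate(sample.int(nDroplets, nm, replace = TRUE), nDroplets) > 0
  hasW <- tabulate(sample.int(nDroplets, nw, replace = TRUE), nDroplets) > 0
  c(sum(!hasM & !hasW), sum(hasM & !hasW),
    sum(!hasM & hasW), sum(hasM & hasW)) / nDroplets
}

## Literal transcription of the classification rules, case by case.
## mcf: named vector over P,E,M,B,T; positive: named logical.
bruteClassify <- function(mcf, positive = mcf > 0,
                          biasFold = 5, balanceFold = 10) {
  L <- c("P", "E", "M", "B", "T")
  x <- setNames(numeric(5), L)
  x[names(mcf)] <- ifelse(positive, mcf, 0)
  pos <- L[x > 0]
  if (length(pos) == 0) return("no_output")

  noGapWithin <- function(group) {
    v <- sort(x[group], decreasing = TRUE)
    all(v[-length(v)] / v[-1] <= biasFold)
  }
  spreadOk <- function(group) max(x[group]) / min(x[group]) < balanceFold
  isolated <- function(top, bottom) {
    bot <- x[bottom]
    all(min(x[top]) > biasFold * bot) || all(bot == 0)
  }

  if (setequal(pos, L) && noGapWithin(L) && spreadOk(L))
    return("PEMBT_balanced")

  pemb <- c("P", "E", "M", "B")
  if (setequal(pos, pemb) && noGapWithin(pemb) && spreadOk(pemb))
    return("PEMB_restricted")
  if (setequal(pos, L) && isolated(pemb, "T") && min(x[pemb]) > biasFold * x["T"] &&
      noGapWithin(pemb) && spreadOk(pemb))
    return("PEMB_biased")

  pem <- c("P", "E", "M")
  if (setequal(pos, pem) && noGapWithin(pem) && spreadOk(pem))
    return("PEM_restricted")
  ## PEM-biased: top trio isolated from {B,T} by > biasFold (against whichever
  ## of B/T is positive; a negative lineage is below everything), no gap inside
  ## the trio, trio spread < balanceFold, and no extra >fold gap between a
  ## positive B and a positive T (non-canonical structure otherwise)
  if (all(pem %in% pos) && setequal(setdiff(pos, pem), intersect(pos, c("B", "T")))) {
    bt <- x[c("B", "T")]
    btPos <- bt[bt > 0]
    if (length(btPos) >= 1 &&
        min(x[pem]) > biasFold * max(bt) &&
        noGapWithin(pem) && spreadOk(pem) &&
        (length(btPos) < 2 || max(btPos) / min(btPos) <= biasFold))
      return("PEM_biased")
  }
  "other_unique"
}

## Garwood exact Poisson interval via the chi-square route.
garwoodCI <- function(k, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else qchisq(a, 2 * k) / 2
  hi <- qchisq(1 - a, 2 * (k + 1)) / 2
  c(lo, hi)
}

## Clade tip-set/count signature of a mutation-count tree, for exact
## topology + branch-count comparisons (order-independent).
cladeSignature <- function(ct) {
  tr <- treePhylo(ct)
  sets <- cloneTrace:::.tipsBelow(tr)
  sig <- character(0)
  rc <- if (is.null(tr$root.edge)) 0 else tr$root.edge
  if (rc > 0)
    sig <- sprintf("%s|%d", paste(sort(tr$tip.label), collapse = ","), rc)
  for (e in seq_len(nrow(tr$edge))) {
    k <- tr$edge.length[e]
    if (k <= 0) next
    tips <- sort(tr$tip.label[sets[[tr$edge[e, 2]]]])
    sig <- c(sig, sprintf("%s|%d", paste(tips, collapse = ","), k))
  }
  sort(sig)
}

## Build a GenotypeMatrix from explicit carrier sets (clean reads).
gmFromCarriers <- function(colonies, carriers, depth = 20) {
  reads <- do.call(rbind, lapply(names(carriers), function(m) {
    data.frame(colony = colonies, mutationId = m,
               mutReads = ifelse(colonies %in% carriers[[m]], depth / 2, 0),
               totalReads = depth, stringsAsFactors = FALSE)
  }))
  buildGenotypeMatrix(reads)
}

## Minimal SimDonor for targeted phylogeny scenarios.
makeSimDonor <- function(age, clones) {
  structure(list(donorId = "SDTEST", age = age, sex = "F", clones = clones),
            class = "SimDonor")
}
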