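test_that("genotype calls follow the VAF and read-count thresholds", {
  reads <- data.frame(
    colony = "c1", mutationId = c("m1", "m2", "m3", "m4", "m5"),
    mutReads = c(3, 0, 1, 2, 0), totalReads = c(15, 10, 4, 20, 4),
    stringsAsFactors = FALSE)
  calls <- genotypeCalls(buildGenotypeMatrix(reads))[1, ]
  expect_equal(unname(calls["m1"]), 1L)      # VAF 0.2, 3 mutant reads
  expect_equal(unname(calls["m2"]), 0L)      # 0/10
  expect_true(is.na(calls["m3"]))            # 1/4: fails both rules
  expect_true(is.na(calls["m4"]))            # VAF 0.10 < 0.15
  expect_true(is.na(calls["m5"]))            # 0/4: too shallow to clear

  bad <- data.frame(colony = "c1", mutationId = "m1",
                    mutReads = 5, totalReads = 3)
  expect_error(buildGenotypeMatrix(bad), "exceed")
})

test_that("colony purity flags skewed VAF and low depth", {
  mk <- function(vaf, depth = 30) {
    reads <- data.frame(colony = "c1",
                        mutationId = paste0("m", 1:10),
                        mutReads = round(vaf * depth), totalReads = depth)
    colonyPurity(buildGenotypeMatrix(reads))
  }
  expect_true(mk(0.5)$pass)
  expect_false(mk(0.25)$pass)    # doublet-like dilution
  expect_false(mk(0.5, depth = 6)$pass)

  ## doublet mixtures fail more often than singlets
  set.seed(91)
  fails <- function(p) {
    mean(replicate(40, {
      depth <- rpois(12, 30)
      reads <- data.frame(colony = "c1", mutationId = paste0("m", 1:12),
                          mutReads = rbinom(12, depth, p), totalReads = depth)
      gm <- buildGenotypeMatrix(reads)
      any(genotypeCalls(gm) == 1L, na.rm = TRUE) && !colonyPurity(gm)$pass
    }))
  }
  expect_gt(fails(0.25), fails(0.5))
})

test_that("perfect phylogeny reconstructs textbook carrier sets", {
  gm <- gmFromCarriers(c("A", "B", "C"),
                       list(m1 = c("A", "B"), m2 = "A", m3 = "B", m4 = "C"))
  ct <- perfectPhylogeny(gm)
  tr <- treePhylo(ct)
  expect_equal(ape::Ntip(tr), 3)
  expect_setequal(cladeSignature(ct), c("A,B|1", "A|1", "B|1", "C|1"))
  ## (A,B) clade exists
  expect_equal(sort(tr$tip.label[cloneTrace:::.tipsBelow(tr)[[
    ape::getMRCA(tr, c("A", "B"))]]]), c("A", "B"))

  ## nested carriers only -> caterpillar with a root edge
  gm2 <- gmFromCarriers(c("A", "B", "C", "D"),
                        list(m1 = c("A", "B", "C", "D"),
                             m2 = c("A", "B", "C"), m3 = c("A", "B")))
  ct2 <- perfectPhylogeny(gm2)
  tr2 <- treePhylo(ct2)
  expect_equal(tr2$root.edge, 1)
  expect_setequal(cladeSignature(ct2),
                  c("A,B,C,D|1", "A,B,C|1", "A,B|1"))

  gmBad <- gmFromCarriers(c("A", "B", "C"),
                          list(m1 = c("A", "B"), m2 = c("B", "C")))
  expect_error(perfectPhylogeny(gmBad), "m1.*m2|m2.*m1")
})

test_that("perfect phylogeny recovers simulated truth exactly at zero error", {
  for (seed in c(1, 2, 3)) {
    d <- simulateDonor(80, 2, seed = seed,
                       patternMix = c(PEMBT_balanced = 1),
                       mcfMeanlog = log(0.2), mcfSdlog = 0.3)
    sp <- suppressWarnings(simulatePhylogeny(d, 20, mutationRate = 2,
                                             seed = seed + 10))
    rd <- simulateColonyReads(sp$tree, meanDepth = 40, errorRate = 0,
                              seed = seed + 20)
    rec <- perfectPhylogeny(buildGenotypeMatrix(rd$reads))
    expect_identical(cladeSignature(rec), cladeSignature(sp$tree))
  }
})

test_that("ultrametric scaling pins tips at the sampling age and is
           proportional for equal tip counts", {
  tr <- cladeTree(ape::read.tree(text = "((A:50,B:50):50,C:100):0;"),
                  donorAge = 80)
  ut <- makeUltrametric(tr)
  S <- 80 + 40 * 7 / 365.25
  expect_equal(timelineSpan(ut), 80.76659822, tolerance = 1e-8)
  ages <- nodeAges(ut)
  expect_equal(unname(ages[1:3]), rep(S, 3), tolerance = 1e-9)
  ## internal node halfway up the mutation count
  inner <- ape::getMRCA(treePhylo(ut), c("A", "B"))
  expect_equal(ages[inner], S / 2, tolerance = 1e-9)

  expect_error(makeUltrametric(
    cladeTree(ape::read.tree(text = "(A:0,B:5):0;"), donorAge = 50)),
    "positive")
})

test_that("node ages are monotone along every lineage on simulated trees", {
  for (seed in c(5, 6)) {
    d <- simulateDonor(75, 2, seed = seed)
    sp <- suppressWarnings(simulatePhylogeny(d, 25, seed = seed))
    ut <- makeUltrametric(sp$tree)
    tr <- treePhylo(ut); ages <- nodeAges(ut)
    expect_true(all(ages[tr$edge[, 2]] >= ages[tr$edge[, 1]] - 1e-9))
    expect_equal(unname(ages[seq_len(ape::Ntip(tr))]),
                 rep(timelineSpan(ut), ape::Ntip(tr)), tolerance = 1e-9)
  }
})

test_that("branch dating conventions bracket the branch", {
  tr <- cladeTree(ape::read.tree(text = "((A:60,B:60):20,C:80):20;"),
                  donorAge = 99.2334017786862)  # span exactly 100 years
  ut <- makeUltrametric(tr)
  inner <- ape::getMRCA(treePhylo(ut), c("A", "B"))
  expect_equal(dateMutation(ut, inner, "proximal"), 20, tolerance = 1e-9)
  expect_equal(dateMutation(ut, inner, "distal"), 40, tolerance = 1e-9)
  expect_equal(dateMutation(ut, inner, "midpoint"), 30, tolerance = 1e-9)

  root <- ape::Ntip(treePhylo(ut)) + 1L
  expect_equal(dateMutation(ut, root, "proximal"), 0)
  expect_equal(dateMutation(ut, root, "distal"), 20, tolerance = 1e-9)
})

test_that("Poisson branch bounds match the exact Garwood interval", {
  for (k in c(0, 1, 2, 5, 17, 120)) {
    b <- cloneTrace:::.poissonBounds(k)
    expect_equal(unname(b[1, ]), garwoodCI(k), tolerance = 1e-9)
  }
  expect_equal(unname(cloneTrace:::.poissonBounds(0)[1, "hi"]), 3.688879,
               tolerance = 1e-6)
})

test_that("dating intervals bracket the point, widen with fewer mutations,
           and tighten as counts grow", {
  nwk <- "((A:60,B:60):20,C:80):20;"
  age <- 99.2334017786862
  ut1 <- makeUltrametric(cladeTree(ape::read.tree(text = nwk), donorAge = age))
  inner <- ape::getMRCA(treePhylo(ut1), c("A", "B"))
  ci1 <- datingCI(ut1, inner)
  expect_true(ci1$lo <= ci1$point && ci1$point <= ci1$hi)

  tr9 <- ape::read.tree(text = nwk)
  tr9$edge.length <- tr9$edge.length * 9
  tr9$root.edge <- tr9$root.edge * 9
  ut9 <- makeUltrametric(cladeTree(tr9, donorAge = age))
  ci9 <- datingCI(ut9, inner)
  expect_equal(ci9$point, ci1$point, tolerance = 1e-9)
  expect_lt(ci9$hi - ci9$lo, ci1$hi - ci1$lo)

  ## the rate-based alternative also brackets the point
  ciR <- datingCI(ut1, inner, method = "rate")
  expect_true(ciR$lo <= ciR$point && ciR$point <= ciR$hi)
})

test_that("dated clone ages track the truth end to end", {
  set.seed(123)
  est <- truth <- numeric(0)
  for (seed in 1:8) {
    d <- simulateDonor(80, 2, seed = 300 + seed,
                       patternMix = c(PEMBT_balanced = 1),
                       mcfMeanlog = log(0.15), mcfSdlog = 0.4)
    sp <- suppressWarnings(simulatePhylogeny(d, 30, mutationRate = 2,
                                             seed = 400 + seed))
    rd <- simulateColonyReads(sp$tree, meanDepth = 40, errorRate = 0,
                              seed = 500 + seed)
    rec <- perfectPhylogeny(buildGenotypeMatrix(rd$reads))
    rec@donorAge <- 80
    ut <- makeUltrametric(rec)
    tt <- sp$truth[sp$truth$detectable, ]
    for (i in seq_len(nrow(tt))) {
      tips <- strsplit(tt$cladeTips[i], ";")[[1]]
      nd <- ape::getMRCA(treePhylo(ut), tips)
      if (is.null(nd)) next
      est <- c(est, dateMutation(ut, nd))
      truth <- c(truth, tt$trueAcquisitionAge[i])
    }
  }
  expect_gte(length(est), 10)
  expect_gt(cor(est, truth), 0.9)
})

test_that("tracing keeps only clades at >= 2% HSC MCF", {
  suppressMessages({
    expect_identical(cladeFilterForTracing(c(a = 0.05, b = 0.01, c = 0.02)),
                     c("a", "c"))
    expect_identical(cladeFilterForTracing(numeric(0)), character(0))
  })
})
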