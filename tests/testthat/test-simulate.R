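test_that("simulateDonor is deterministic, respects the pattern mix, and
           handles empty clone lists", {
  d1 <- simulateDonor(75, 5, seed = 101)
  d2 <- simulateDonor(75, 5, seed = 101)
  expect_identical(d1, d2)

  mix <- c(PEM_restricted = 1)
  d <- simulateDonor(80, 8, patternMix = mix, seed = 7)
  expect_true(all(d$clones$mcfB == 0))
  expect_true(all(d$clones$mcfT == 0))
  expect_true(all(d$clones$mcfP > 0 & d$clones$mcfE > 0 & d$clones$mcfM > 0))

  d0 <- simulateDonor(70, 0, seed = 1)
  expect_equal(nrow(d0$clones), 0)

  expect_error(simulateDonor(15, 2), "18")
  expect_error(simulateDonor(70, 2, patternMix = c(PEM_biased = 0.5)),
               "sum to 1")
})

test_that("biased and restricted clones satisfy the fold rules by construction", {
  set.seed(55)
  for (pat in c("PEMB_biased", "PEM_biased")) {
    d <- simulateDonor(85, 6, patternMix = setNames(1, pat), seed = NULL)
    m <- as.matrix(d$clones[, paste0("mcf", c("P", "E", "M", "B", "T"))])
    top <- if (pat == "PEMB_biased") 1:4 else 1:3
    for (i in seq_len(nrow(m))) {
      gap <- min(m[i, top]) / max(m[i, -top])
      expect_gt(gap, 5)
      expect_lt(max(m[i, top]) / min(m[i, top]), 10)
    }
  }
})

test_that("ddPCR simulation honours truth and its two sampling paths agree", {
  a <- simulateDdpcr(0, nCells = 2000, seed = 3)
  expect_equal(a@mutOnly, 0)
  expect_equal(a@doublePos, 0)
  b <- simulateDdpcr(0, nCells = 2000, method = "multinomial", seed = 3)
  expect_equal(b@mutOnly + b@doublePos, 0)

  s1 <- simulateDdpcr(0.05, 2000, seed = 9)
  s2 <- simulateDdpcr(0.05, 2000, seed = 9)
  expect_identical(quadrantCounts(s1), quadrantCounts(s2))

  ## both paths draw from the same quadrant distribution
  set.seed(17)
  D <- 1e5
  m1 <- quadrantCounts(simulateDdpcr(0.03, 5000, nDroplets = D))
  m2 <- quadrantCounts(simulateDdpcr(0.03, 5000, nDroplets = D,
                                     method = "multinomial"))
  suppressWarnings(ht <- chisq.test(rbind(m1, m2)))
  expect_gt(ht$p.value, 0.001)

  expect_error(simulateDdpcr(0.1, 100, efficiency = 0), "positive")
  expect_error(simulateDdpcr(0.1, 100, nDroplets = 0), "at least 1")
})

test_that("simulated phylogenies give clones clades of the expected size", {
  clones <- data.frame(mutationId = "mut001", driverFlag = TRUE,
                       pattern = "PEMBT_balanced", trueMcfHsc = 0.5,
                       mcfP = 0.5, mcfE = 0.5, mcfM = 0.5, mcfB = 0.5,
                       mcfT = 0.5, acquisitionAge = 30,
                       stringsAsFactors = FALSE)
  d <- makeSimDonor(80, clones)
  sp <- simulatePhylogeny(d, 40, seed = 12)
  tips <- strsplit(sp$truth$cladeTips, ";")[[1]]
  expect_true(abs(length(tips) - 20) <= 3 * sqrt(40 * 0.25))

  sp2 <- simulatePhylogeny(d, 40, seed = 12)
  expect_identical(ape::write.tree(treePhylo(sp$tree)),
                   ape::write.tree(treePhylo(sp2$tree)))

  ## zero mutation rate on a clone-free donor: valid all-zero tree
  d0 <- simulateDonor(70, 0, seed = 2)
  sp0 <- simulatePhylogeny(d0, 10, mutationRate = 0, seed = 5)
  tr <- treePhylo(sp0$tree)
  expect_true(all(tr$edge.length == 0))
  expect_s4_class(sp0$tree, "CladeTree")

  ## too-small clones are flagged undetectable
  clones$trueMcfHsc <- 0.001
  expect_warning(spu <- simulatePhylogeny(makeSimDonor(80, clones), 10,
                                          seed = 3), "undetectable")
  expect_false(any(spu$truth$detectable))
})

test_that("colony read simulation reproduces the heterozygous VAF structure", {
  clones <- data.frame(mutationId = "mut001", driverFlag = TRUE,
                       pattern = "PEMBT_balanced", trueMcfHsc = 0.4,
                       mcfP = 0.4, mcfE = 0.4, mcfM = 0.4, mcfB = 0.4,
                       mcfT = 0.4, acquisitionAge = 30,
                       stringsAsFactors = FALSE)
  sp <- simulatePhylogeny(makeSimDonor(80, clones), 12, mutationRate = 1,
                          seed = 8)
  rd <- simulateColonyReads(sp$tree, meanDepth = 30, errorRate = 0, seed = 9)
  gm <- buildGenotypeMatrix(rd$reads)

  carried <- genotypeCalls(gm) == 1L
  vafs <- (gm@mutReads / gm@totalReads)[which(carried)]
  expect_gte(length(vafs), 100)
  expect_true(median(vafs) >= 0.45 && median(vafs) <= 0.55)

  ## with zero error rate, true non-carriers never show a mutant read
  tr <- treePhylo(sp$tree)
  below <- cloneTrace:::.tipsBelow(tr)
  isCarrier <- mapply(function(colony, mut) {
    nd <- rd$mutationEdges$nodeId[rd$mutationEdges$mutationId == mut]
    nd == 0 || match(colony, tr$tip.label) %in% below[[nd]]
  }, rd$reads$colony, rd$reads$mutationId)
  expect_true(all(rd$reads$mutReads[!isCarrier] == 0))

  expect_error(simulateColonyReads(sp$tree, meanDepth = 0), "positive")
  expect_error(simulateColonyReads(sp$tree, 30, errorRate = 0.5), "0.5")
})
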