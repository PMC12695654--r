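test_that("quadrant probabilities follow the Poisson occupancy closed form", {
  expect_equal(unname(quadrantProbs(0, 0)), c(1, 0, 0, 0))

  q <- quadrantProbs(0.1, 0.5)
  em <- exp(-0.1); ew <- exp(-0.5)
  expect_equal(unname(q), c(em * ew, (1 - em) * ew, em * (1 - ew),
                            (1 - em) * (1 - ew)), tolerance = 1e-12)
  expect_equal(unname(q), c(0.54881164, 0.05771902, 0.35602578, 0.03744356),
               tolerance = 1e-7)

  expect_equal(unname(quadrantProbs(50, 60)), c(0, 0, 0, 1), tolerance = 1e-12)

  for (lm in c(0, 0.01, 0.3, 2)) for (lw in c(0, 0.2, 1.5))
    expect_equal(sum(quadrantProbs(lm, lw)), 1, tolerance = 1e-12)

  expect_error(quadrantProbs(-0.1, 0.5), "non-negative")
  expect_error(quadrantProbs(NaN, 0.5), "finite")
})

test_that("quadrant probabilities agree with molecule-level Monte Carlo", {
  set.seed(11)
  D <- 2e5
  for (lam in list(c(0.1, 0.5), c(0.8, 0.8), c(0.02, 1.5))) {
    emp <- mcQuadrantFractions(lam[1], lam[2], D)
    q <- quadrantProbs(lam[1], lam[2])
    se <- sqrt(q * (1 - q) / D)
    expect_true(all(abs(emp - q) <= 4 * se + 1e-12),
                info = paste("lambda =", paste(lam, collapse = ",")))
  }
})

test_that("lambdasFromState maps state to per-droplet means", {
  l <- lambdasFromState(0.05, 0.5, nCells = 9090, nDroplets = 14000,
                        ploidy = 2)
  expect_equal(l$lambdaM, 9090 * 0.05 * 0.5 / 14000, tolerance = 1e-12)
  expect_equal(l$lambdaW, 9090 * 1.95 * 0.5 / 14000, tolerance = 1e-12)
  expect_equal(l$lambdaM, 0.016232, tolerance = 1e-4)
  expect_equal(l$lambdaW, 0.633054, tolerance = 1e-4)

  l0 <- lambdasFromState(0, 0.7, 2000, 14000, ploidy = 2)
  expect_equal(l0$lambdaM, 0)
  expect_equal(l0$lambdaW, 2000 * 2 * 0.7 / 14000)

  l1 <- lambdasFromState(1, 0.7, 2000, 14000, ploidy = 1)
  expect_equal(l1$lambdaW, 0)

  expect_error(lambdasFromState(0.5, -1, 100, 1000), "positive")
  expect_error(lambdasFromState(1.2, 0.5, 100, 1000), "\\[0, 1\\]")
})

test_that("posterior has no-mutant floor, concentrates with data, and is
           monotone in the mutant-only count", {
  a0 <- DropletAssay(12000, 0, 1995, 0, nCells = 2000)
  p0 <- posteriorMcf(a0)
  expect_lt(mcfMean(p0), 0.005)
  expect_lt(unname(mcfCI(p0)["lo"]), 5e-5)  # essentially the grid floor
  expect_equal(sum(p0@mass), 1, tolerance = 1e-9)

  a1 <- DropletAssay(12000, 60, 1930, 10, nCells = 2000)
  a2 <- DropletAssay(24000, 120, 3860, 20, nCells = 4000)
  w1 <- diff(mcfCI(posteriorMcf(a1)))
  w2 <- diff(mcfCI(posteriorMcf(a2)))
  expect_lt(w2, w1)

  means <- vapply(c(5, 20, 60, 150), function(m)
    mcfMean(posteriorMcf(DropletAssay(12000, m, 1900, 10, nCells = 2000))),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("posterior recovers a known simulated MCF", {
  set.seed(21)
  est <- replicate(20, {
    a <- simulateDdpcr(0.10, nCells = 2000, nDroplets = 14000,
                       efficiency = 0.5)
    mcfMean(posteriorMcf(a))
  })
  expect_lt(abs(mean(est) - 0.10), 0.02)
})

test_that("positivity is driven by posterior overlap with the control", {
  a <- DropletAssay(12000, 40, 1950, 8, nCells = 2000)
  p <- posteriorMcf(a)
  same <- positivity(p, p)
  expect_equal(same$overlap, 1, tolerance = 1e-9)
  expect_identical(same$label, "negative")
  expect_false(same$binary)

  ctrl <- posteriorMcf(nullControlAssay(a))
  call <- positivity(p, ctrl)
  expect_identical(call$label, "positive")
  expect_lt(call$overlap, 0.05)
  expect_equal(overlapArea(p, ctrl), overlapArea(ctrl, p), tolerance = 1e-12)

  ## constructed posteriors with overlap exactly 0.12 -> likely positive
  grid <- seq(0, 1, length.out = 11)
  mk <- function(mass, mu, lo, hi)
    new("PosteriorMCF", theta = grid, mass = mass, mean = mu,
        ciLo = lo, ciHi = hi, level = 0.95)
  pa <- mk(c(1, rep(0, 10)), 0, 0, 0)
  pb <- mk(c(0.12, 0.88, rep(0, 9)), 0.088, 0, 0.1)
  expect_equal(overlapArea(pa, pb), 0.12, tolerance = 1e-12)
  expect_identical(positivity(pa, pb)$label, "likely_positive")
  pd <- mk(c(rep(0, 9), 0.5, 0.5), 0.95, 0.9, 1)
  expect_identical(positivity(pa, pd)$label, "positive")
})

test_that("an MCF of 0.12% in a bulk-DNA well is detected in most replicates", {
  ## the 9,090-cell convention (60 ng bulk marrow DNA)
  set.seed(31)
  hits <- replicate(25, {
    a <- simulateDdpcr(0.0012, nCells = cellsFromDnaMass(60),
                       nDroplets = 14000, efficiency = 0.5)
    positivity(posteriorMcf(a), posteriorMcf(nullControlAssay(a)))$binary
  })
  expect_gt(mean(hits), 0.5)
})

test_that("VAF/MCF conversion respects ploidy and caps at 1", {
  expect_equal(vafToMcf(0.25, ploidy = 2), 0.5)
  expect_equal(vafToMcf(0.25, ploidy = 1), 0.25)
  expect_equal(vafToMcf(0), 0)
  expect_message(capped <- vafToMcf(0.8, ploidy = 2), "capped")
  expect_equal(capped, 1)
  expect_error(vafToMcf(1.2), "\\[0, 1\\]")
})

test_that("cell-count convention and tracing eligibility", {
  expect_equal(cellsFromDnaMass(60), 9090)
  expect_equal(cellsFromDnaMass(0.0066), 1)
  expect_equal(perCellDnaPg(), 6.6)
  expect_error(cellsFromDnaMass(-1), "positive")

  expect_true(tracingEligible(0.025, TRUE))
  expect_false(tracingEligible(0.015, TRUE))
  expect_true(tracingEligible(0.012, FALSE))
  expect_false(tracingEligible(0.008, FALSE))
})

test_that("ploidy follows chromosome class and sex", {
  expect_equal(ploidyOf("autosome", "M"), 2)
  expect_equal(ploidyOf("X", "F"), 2)
  expect_equal(ploidyOf("X", "M"), 1)
  expect_equal(ploidyOf("Y", "M"), 1)
  expect_error(ploidyOf("Y", "F"), "impossible")
})
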