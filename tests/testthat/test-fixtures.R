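test_that("receptor model reproduces the tabulated rates and Laplacian", {
  m <- nachrModel(0.5)
  e <- edgeTable(m)
  expect_equal(stateLabels(m), c("AR", "A2R", "A2T", "AT", "T"))
  expect_equal(measurement(m), c(1, 1, 0, 0, 0))
  expect_equal(e$rate[2], 0.25)           # binding 1 -> 2 at 0.5 uM
  expect_equal(e$rate[10], 0.05)          # binding 5 -> 4 at 0.5 uM
  expect_equal(e$rate[1], 2e-3 / 3)       # release 2 -> 1
  expect_equal(e$from, c(2L, 1L, 3L, 2L, 3L, 4L, 4L, 1L, 4L, 5L))
  expect_equal(e$to,   c(1L, 2L, 2L, 3L, 4L, 3L, 1L, 4L, 5L, 4L))

  # Laplacian built symbolically from the rate constants, spot-checked
  symbolicL <- function(c) {
    km2s <- 1e-3 / 3; kp2s <- 0.5; km2 <- 2; kp2 <- 0.5
    kp1 <- 0.05; km1 <- 2; a1 <- 3; b1 <- 0.015; a2 <- 0.5; b2 <- 15
    rbind(
      c(-(a1 + kp2s * c), 2 * km2s, 0, b1, 0),
      c(kp2s * c, -(a2 + 2 * km2s), b2, 0, 0),
      c(0, a2, -(b2 + 2 * km2), kp2 * c, 0),
      c(a1, 0, 2 * km2, -(b1 + kp2 * c + km1), 2 * kp1 * c),
      c(0, 0, 0, km1, -2 * kp1 * c))
  }
  for (cc in c(0.5, 1, 10, 100))
    expect_equal(unname(laplacian(nachrModel(cc))), symbolicL(cc),
                 tolerance = 1e-14)

  # the open state AR is sparsely occupied at every tested concentration
  for (cc in c(0.5, 10, 100))
    expect_lt(stationarySummary(nachrModel(cc))@pi[1], 0.015)
  expect_error(nachrModel(0), "positive")
})

test_that("importance scan reproduces the concentration-dependent ranking", {
  scan <- nachrImportanceScan(cGrid = 10^seq(-1, 2, length.out = 25))
  tab <- scan$table
  # low concentration: hidden pair 3-4 leads, then 2-3, then 4-5
  r05 <- tab[which.min(abs(tab$c - 0.5)), ]
  expect_gt(r05$pair.3.4, r05$pair.2.3)
  expect_gt(r05$pair.2.3, r05$pair.4.5)
  # high concentration: the open-closed pair 2-3 leads
  r100 <- tab[nrow(tab), ]
  expect_gt(r100$pair.2.3, r100$pair.3.4)
  # crossover below 10 uM
  expect_false(is.na(scan$crossover))
  expect_lt(scan$crossover, 10)
  expect_gt(scan$crossover, 0.1)
  # pairs 1-2 and 1-4 are negligible: a few percent at most, and below
  # 1e-2 everywhere above the lowest concentrations
  expect_true(all(tab$pair.1.2 < 1.5e-2))
  expect_true(all(tab$pair.1.4 < 1.5e-2))
  expect_true(all(tab$pair.1.4[tab$c >= 0.2] < 1e-2))
})

test_that("timescale scan shows separation at low concentration only", {
  scan <- nachrTimescaleScan(cGrid = 10^seq(-1, 2, length.out = 40))
  expect_true(all(scan$ratio32 > 0 & scan$ratio32 <= 1))
  expect_true(all(scan$ratio42 > 0 & scan$ratio42 <= 1))
  expect_true(all(scan$ratio52 > 0 & scan$ratio52 <= 1))
  expect_true(scan$separated[which.min(abs(scan$c - 0.5))])
  # eigenvalue ratios vary continuously along the grid
  expect_lt(max(abs(diff(log(scan$ratio52)))), 0.5)
})

test_that("catalogued chains assign alpha to the tabulated edges", {
  m3 <- threeStateCase(3, alpha = 2)
  expect_equal(edgeTable(m3)$rate, c(2, 1, 2, 1))
  expect_equal(measurement(m3), c(0, 0, 1))
  m7 <- threeStateCase(7, alpha = 5)
  expect_equal(edgeTable(m7)$rate, c(1, 1, 1, 5))
  m8 <- threeStateCase(8, alpha = 2)
  expect_equal(measurement(m8), c(0, 1, 0))
  expect_equal(edgeTable(m8)$rate, c(2, 2, 1, 1))
  expect_error(threeStateCase(13, 1), "1..12")
  expect_error(threeStateCase(1, -1), "positive")
})

test_that("end-state-observable cases never invert; 2 and 6 converge", {
  grid <- 10^seq(-4, 4, length.out = 17)
  for (cs in 1:7) {
    sc <- caseScan(cs, grid)
    expect_true(all(sc$pair23 >= sc$pair12))
    conv <- sc$pair12[nrow(sc)] / sc$pair23[nrow(sc)]
    if (cs %in% c(2, 6)) {
      expect_gt(conv, 0.99)              # curves converge at large alpha
      expect_lt(sc$eigRatio[nrow(sc)], 1e-3)   # 4 orders of separation
    } else {
      expect_lt(conv, 0.6)
    }
  }
})

test_that("middle-state case 10 inverts without timescale separation", {
  sc <- caseScan(10, 10^seq(-4, 4, length.out = 33))
  rev <- sc$pair12 > sc$pair23
  expect_true(any(rev))
  # reversal happens while the eigenvalues stay within one order
  expect_true(any(rev & sc$eigRatio > 0.1))
})

test_that("named fixtures are addressable", {
  a <- fixtureModel("example-A")
  expect_equal(edgeTable(a)$rate, c(1, 1, 10, 0.1))
  b <- fixtureModel("example-B")
  expect_equal(edgeTable(b)$rate, c(0.1, 1, 10, 10))
  expect_equal(edgeTable(fixtureModel("beta-slice", beta = 10))$rate,
               c(0.1, 1, 10, 1))
  expect_equal(edgeTable(fixtureModel("chain-case-3", alpha = 2))$rate,
               c(2, 1, 2, 1))
  expect_equal(nEdges(fixtureModel("nachr", c = 1)), 10L)
  expect_error(fixtureModel("nope"), "unknown fixture")
  expect_error(fixtureModel("beta-slice"), "beta")
  # each example satisfies one inversion condition but does not invert
  dA <- etaClosedForm(threeStateRates(1, 1, 10, 0.1))
  expect_gt(dA@rates[["a23"]], max(dA@rates[c("a12", "a21", "a32")]))
  expect_false(dA@inverted)
  dB <- etaClosedForm(threeStateRates(0.1, 1, 10, 10))
  expect_lt(dB@rates[["a12"]], dB@rates[["a21"]])
  expect_false(dB@inverted)
})

test_that("lognormal ensembles obey the inversion phenomenology", {
  # near-degenerate width: everything sits at the unit-rate point
  e0 <- sampleEnsemble(2000, w = 1e-4, seed = 3)
  expect_equal(e0@inversionFraction, 0)
  expect_equal(mean(e0@samples$eta), 1 / 8, tolerance = 1e-3)

  e <- sampleEnsemble(2e4, w = sqrt(10), seed = 3)
  s <- e@samples
  expect_equal(e@inversionFraction, mean(s$eta > 0.5))
  # every sample satisfies the four bounds and the factorization
  expect_true(all(s$eta <= s$boundOccupancy * (1 + 1e-12)))
  expect_true(all(s$eta <= s$boundRateRatio * (1 + 1e-12)))
  expect_true(all(s$eta <= s$boundRelaxation * (1 + 1e-12)))
  expect_true(all(s$eta <= s$boundFlux * (1 + 1e-12)))
  expect_equal(s$eta, s$F1 * s$F2, tolerance = 1e-12)
  # necessary conditions hold for every inverted sample
  inv <- s[s$inverted, ]
  expect_gt(nrow(inv), 100)
  expect_true(all(inv$pi2 < inv$pi3))
  expect_true(all(inv$deltaJ < 0))            # J12 < J23
  expect_true(all(inv$tau12 > inv$tau23))
  expect_true(all(inv$nu > 1))
  # none of the single conditions is sufficient
  notinv <- s[!s$inverted, ]
  expect_true(any(notinv$pi2 < notinv$pi3))
  expect_true(any(notinv$deltaJ < 0))
  # inversion is rarer than the iid ordering bound 1/8
  expect_lt(e@inversionFraction, 1 / 8)
  # base-10 option widens the spread further
  e10 <- sampleEnsemble(5000, w = sqrt(10), seed = 3, logBase = "10")
  expect_gt(e10@inversionFraction, e@inversionFraction)
})

test_that("closed-form diagnostics agree with the eigensolver on a subsample", {
  e <- sampleEnsemble(300, w = 2, seed = 8)
  s <- e@samples
  for (i in seq_len(nrow(s))) {
    m <- threeStateChain(s$a12[i], s$a21[i], s$a23[i], s$a32[i])
    pr <- pairRelative(edgeImportance(m))
    etaSpec <- unname(pr[["1-2"]] / (pr[["1-2"]] + pr[["2-3"]]))
    expect_equal(s$eta[i], etaSpec, tolerance = 1e-8)
  }
})

test_that("ordering probability is exactly 1/8 and matches Monte Carlo", {
  expect_identical(orderingProbability(), 1 / 8)
  mc <- orderingProbabilityMC(2e5, seed = 6)
  expect_lt(abs(mc$estimate - 1 / 8), 3 * mc$se)
})
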