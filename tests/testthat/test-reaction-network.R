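test_that("buildModel validates edges, rates and connectivity", {
  # valid 3-state chain
  m <- buildModel(c("S1", "S2", "S3"),
                  data.frame(from = c(1, 2, 2, 3), to = c(2, 1, 3, 2),
                             rate = 1),
                  measurement = c(0, 0, 1), nWalkers = 1)
  expect_s4_class(m, "MarkovNetworkModel")
  expect_equal(nEdges(m), 4L)

  # duplicate directed edge named in the error
  expect_error(
    buildModel(c("a", "b"),
               data.frame(from = c(1, 1, 2), to = c(2, 2, 1), rate = 1),
               c(0, 1)),
    "duplicate directed edge.*1->2")

  # missing return edge: state 3 has no out-edge, not strongly connected
  expect_error(
    buildModel(c("S1", "S2", "S3"),
               data.frame(from = c(1, 2, 2), to = c(2, 1, 3), rate = 1),
               c(0, 0, 1)),
    "not strongly connected.*3")

  # nonpositive rate names the edge
  expect_error(
    buildModel(c("a", "b"),
               data.frame(from = c(1, 2), to = c(2, 1), rate = c(1, -2)),
               c(0, 1)),
    "nonpositive rate.*2")

  # five-state receptor model has m = 10 edges
  expect_equal(nEdges(nachrModel(1)), 10L)
})

test_that("laplacian has the source-column convention and zero column sums", {
  expect_equal(unname(laplacian(unitChain())),
               rbind(c(-1, 1, 0), c(1, -2, 1), c(0, 1, -1)))
  # receptor model at c = 2: entry (1,1) = -(a1 + k*+2 c) = -(3 + 1)
  expect_equal(laplacian(nachrModel(2))[1, 1], -4)
  for (m in list(unitChain(), exampleAChain(), nachrModel(0.5),
                 nachrModel(100))) {
    L <- laplacian(m)
    expect_lt(max(abs(colSums(L))), 1e-12 * max(abs(L)))
    expect_lt(max(abs(L %*% stationarySummary(m)@pi)), 1e-10 * max(abs(L)))
  }
})

test_that("stationary distribution, fluxes and detailed balance are exact", {
  ss <- stationarySummary(unitChain())
  expect_equal(ss@pi, rep(1 / 3, 3))
  expect_equal(ss@perWalkerFlux, rep(1 / 3, 4))
  expect_true(ss@detailedBalance)

  # Example A: pi2/pi3 = 0.01
  ssA <- stationarySummary(exampleAChain())
  expect_equal(ssA@pi[2] / ssA@pi[3], 0.01, tolerance = 1e-12)

  # population flux is the per-walker flux rescaled
  m500 <- threeStateChain(1, 1, 1, 1, nWalkers = 500L)
  expect_equal(stationarySummary(m500)@populationFlux, rep(500 / 3, 4))

  # a one-way cycle is irreducible but not reversible
  cyc <- buildModel(c("a", "b", "c"),
                    data.frame(from = c(1, 2, 3), to = c(2, 3, 1), rate = 1),
                    c(0, 0, 1))
  expect_false(stationarySummary(cyc)@detailedBalance)
})

test_that("receptor model satisfies detailed balance across concentrations", {
  for (cc in 10^seq(-1, 2, length.out = 13)) {
    ss <- stationarySummary(nachrModel(cc))
    expect_true(ss@detailedBalance)
    expect_lt(ss@dbResidual, 1e-10)
  }
})

test_that("spectral decomposition is real, sorted and biorthonormal", {
  dec <- spectralDecomposition(unitChain())
  expect_equal(dec@eigenvalues, c(0, -1, -3), tolerance = 1e-12)

  # Example A eigenvalues: roots of x^2 + 12.1 x + 10.2
  rootsA <- sort((-12.1 + c(1, -1) * sqrt(12.1^2 - 4 * 10.2)) / 2,
                 decreasing = TRUE)
  decA <- spectralDecomposition(exampleAChain())
  expect_equal(decA@eigenvalues[2:3], rootsA, tolerance = 1e-10)
  expect_equal(round(decA@eigenvalues[2], 4), -0.9117)

  for (m in list(unitChain(), exampleAChain(), nachrModel(0.5))) {
    d <- spectralDecomposition(m)
    n <- nStates(m)
    expect_lt(max(abs(crossprod(d@leftVectors, d@rightVectors) - diag(n))),
              1e-10)
    # leading pair carries the stationary law and conservation
    expect_equal(d@rightVectors[, 1], unname(stationarySummary(m)@pi),
                 tolerance = 1e-10)
    expect_equal(d@leftVectors[, 1], rep(1, n), tolerance = 1e-10)
    # spectral reconstruction of L
    L <- laplacian(m)
    rec <- d@rightVectors %*% diag(d@eigenvalues) %*% t(d@leftVectors)
    expect_lt(max(abs(rec - L)), 1e-8 * max(abs(L)))
  }
})

test_that("matrix-exponential relaxation converges to pi (brute force)", {
  skip_if_not_installed("Matrix")
  for (m in list(unitChain(), exampleAChain(), nachrModel(0.5))) {
    L <- laplacian(m)
    dec <- spectralDecomposition(m)
    t50 <- 50 / abs(dec@eigenvalues[2])
    P <- as.matrix(Matrix::expm(L * t50))
    x0 <- numeric(nStates(m)); x0[1] <- 1
    expect_equal(as.numeric(P %*% x0),
                 unname(stationarySummary(m)@pi), tolerance = 1e-8)
  }
})

test_that("noise matrix columns are sqrt-flux stoichiometries", {
  m <- unitChain()
  nm <- noiseMatrix(m)
  expect_equal(unname(nm$B[, 1]), sqrt(1 / 3) * c(-1, 1, 0))
  expect_lt(max(abs(colSums(nm$B))), 1e-14)
  expect_equal(Reduce(`+`, lapply(nm$Bk, tcrossprod)), tcrossprod(nm$B),
               tolerance = 1e-14, ignore_attr = TRUE)
  # population scaling
  m500 <- threeStateChain(1, 1, 1, 1, nWalkers = 500L)
  nm500 <- noiseMatrix(m500, perWalker = FALSE)
  expect_equal(nm500$B, sqrt(500) * noiseMatrix(m500)$B, tolerance = 1e-12)
})
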