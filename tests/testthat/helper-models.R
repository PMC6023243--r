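# Shared fixture builders and independent numerical oracles.

unitChain <- function(nWalkers = 1L) threeStateChain(1, 1, 1, 1,
                                                     nWalkers = nWalkers)
exampleAChain <- function() threeStateChain(1, 1, 10, 0.1)
exampleBChain <- function() threeStateChain(0.1, 1, 10, 10)

# random reversible chain: random rates on a path graph (trees always
# satisfy detailed balance)
randomChain <- function(n = 4, observable = n) {
  rates <- exp(stats::runif(2 * (n - 1), -2, 2))
  edges <- data.frame(
    from = c(seq_len(n - 1), seq_len(n - 1) + 1L),
    to   = c(seq_len(n - 1) + 1L, seq_len(n - 1)),
    rate = rates)
  M <- numeric(n)
  M[observable] <- 1
  buildModel(paste0("S", seq_len(n)), edges, M, 1L)
}

# quadrature oracle for the Lyapunov solution: int_0^inf e^{tL} F e^{tL'} dt
# by composite Simpson with exact per-step propagator powers E_j = (e^{hL})^j.
# Two panels handle stiffness: a fine panel resolving the fastest mode on
# [0, tSplit], then a coarse panel out to the slow-mode horizon tUpper.
simpsonPanel <- function(L, F, E0, t0, t1, nSteps) {
  h <- (t1 - t0) / nSteps
  Estep <- as.matrix(Matrix::expm(L * h))
  w <- c(1, rep(c(4, 2), length.out = nSteps - 1), 1)
  E <- E0
  acc <- matrix(0, nrow(L), ncol(L))
  for (j in seq_len(nSteps + 1L)) {
    acc <- acc + w[j] * (E %*% F %*% t(E))
    E <- E %*% Estep
  }
  list(value = acc * h / 3, Eend = E %*% solve(Estep))
}

lyapunovQuadrature <- function(L, F, tUpper, tSplit = NULL,
                               nSteps = 4000L) {
  stopifnot(requireNamespace("Matrix", quietly = TRUE))
  if (is.null(tSplit)) tSplit <- tUpper / 10
  p1 <- simpsonPanel(L, F, diag(nrow(L)), 0, tSplit, nSteps)
  p2 <- simpsonPanel(L, F, p1$Eend, tSplit, tUpper, nSteps)
  p1$value + p2$value
}

# dense Sylvester oracle: solve vec(LC + CL^T) = -vec(F) with the zero
# column sum constraint appended, via least squares on the stacked system
lyapunovKronecker <- function(L, F) {
  n <- nrow(L)
  K <- kronecker(diag(n), L) + kronecker(L, diag(n))
  constr <- kronecker(diag(n), matrix(1, 1, n))   # column sums of C
  A <- rbind(K, constr)
  b <- c(-as.numeric(F), rep(0, n))
  matrix(qr.solve(A, b), n, n)
}

# per-edge importance via quadrature of the covariance integral
importanceQuadrature <- function(model) {
  L <- laplacian(model)
  ss <- stationarySummary(model)
  nm <- noiseMatrix(model, ss)
  lam <- spectralDecomposition(model)@eigenvalues
  M <- measurement(model)
  tSplit <- 12 / abs(min(lam))       # fast transients resolved finely
  tUpper <- max(40 / abs(lam[2]), 2 * tSplit)
  vapply(nm$Bk, function(Bk) {
    Ck <- lyapunovQuadrature(L, tcrossprod(Bk), tUpper = tUpper,
                             tSplit = tSplit)
    as.numeric(t(M) %*% Ck %*% M)
  }, numeric(1))
}
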