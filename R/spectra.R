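# complex amplitude z_k(omega) = sum_i a_i g_ik / (lambda_i + i omega);
# S_k(omega) = J_k / (2 pi) * |z_k|^2 (two-sided, angular frequency)
.psdClosure <- function(model) {
  ss <- stationarySummary(model)
  if (!ss@detailedBalance)
    stop("power spectral decomposition requires detailed balance")
  dec <- spectralDecomposition(laplacian(model), pi = ss@pi)
  sc <- .spectralCoefficients(model, dec)
  flux <- ss@perWalkerFlux
  function(omega) {
    # returns m x length(omega) matrix of S_k(omega)
    vapply(omega, function(w) {
      d <- 1 / (sc$lambda + 1i * w)
      zk <- crossprod(sc$C, d)              # m x 1 complex
      flux / (2 * pi) * as.numeric(Mod(zk)^2)
    }, numeric(nrow(model@edges)))
  }
}

#' Per-edge power spectral density of the observed process
#'
#' Evaluates the two-sided power spectral density of the observable
#' \eqn{M^\top X(t)} in angular frequency, decomposed over directed edges:
#' \deqn{S_k(\omega) = \frac{J_k}{2\pi} \sum_{l \ge 2} \sum_{j \ge 2}
#'   \frac{(M^\top v_l)(w_l^\top \zeta_k)(\zeta_k^\top w_j)(v_j^\top M)}
#'        {(\lambda_l + i\omega)(\lambda_j - i\omega)}}
#' with \eqn{S(\omega) = \sum_k S_k(\omega)} and
#' \eqn{\int_{-\infty}^{\infty} S_k(\omega)\,d\omega = R_k}. The complex
#' double sum collapses to \eqn{|z_k(\omega)|^2}, so values are exactly
#' real and nonnegative.
#'
#' @param model a reversible [MarkovNetworkModel-class].
#' @param omega positive angular-frequency grid; default 400 log-spaced
#'   points over `[1e-3, 1e3]`.
#' @return list with `omega`, `perEdge` (m x length(omega) matrix),
#'   `total`, `pairs` (matrix of pair-summed densities, one row per
#'   unordered state pair), and `pairOfEdge`.
#' @examples
#' tab <- psd(threeStateChain(1, 1, 1, 1))
#' all(tab$pairs["2-3", ] > tab$pairs["1-2", ])   # observable pair dominates
#' @export
psd <- function(model, omega = 10^seq(-3, 3, length.out = 400)) {
  stopifnot(all(omega > 0))
  f <- .psdClosure(model)
  perEdge <- f(omega)
  if (is.null(dim(perEdge))) perEdge <- matrix(perEdge, nrow = 1)
  pair <- .pairKeys(model@edges)
  pairs <- rowsum(perEdge, pair)
  list(omega = omega, perEdge = perEdge, total = colSums(perEdge),
       pairs = pairs, pairOfEdge = pair)
}

#' Check that per-edge spectra integrate back to the edge importance
#'
#' Computes \eqn{2\int_0^\infty S_k(\omega)\,d\omega} per edge by adaptive
#' quadrature on the closed-form density (not on a grid) and returns the
#' integrals, which must equal \eqn{R_k}.
#'
#' @param model a reversible [MarkovNetworkModel-class].
#' @param rel.tol quadrature relative tolerance.
#' @return numeric vector of per-edge integrals (same order as the edges).
#' @export
psdIntegralCheck <- function(model, rel.tol = 1e-10) {
  f <- .psdClosure(model)
  m <- nrow(model@edges)
  vapply(seq_len(m), function(k) {
    intg <- stats::integrate(function(w) f(w)[k, , drop = TRUE], 0, Inf,
                             rel.tol = rel.tol, subdivisions = 400L)
    if (intg$message != "OK")
      stop("quadrature did not converge for edge ", k, ": ", intg$message)
    2 * intg$value
  }, numeric(1))
}

#' Per-edge lagged covariance of the observed process
#'
#' Evaluates the M-projected per-edge stationary lagged covariance
#' \deqn{M^\top C_k(\tau) M = J_k \sum_{l \ge 2} \sum_{j \ge 2}
#'   \frac{-e^{\lambda_l \tau}}{\lambda_l + \lambda_j}
#'   (M^\top v_l)(w_l^\top \zeta_k)(\zeta_k^\top w_j)(v_j^\top M)}
#' on a grid of nonnegative lags. At \eqn{\tau = 0} the values equal the
#' edge importances \eqn{R_k}; the total decays to 0 as
#' \eqn{\tau \to \infty}. Negative lags follow by symmetry
#' \eqn{C(-\tau) = C(\tau)} and are rejected here.
#'
#' @param model a reversible [MarkovNetworkModel-class].
#' @param tau nonnegative lag grid.
#' @return list with `tau`, `perEdge` (m x length(tau)), `total`.
#' @export
laggedCovariance <- function(model, tau) {
  if (any(tau < 0)) stop("lags must be nonnegative (use symmetry for tau < 0)")
  ss <- stationarySummary(model)
  if (!ss@detailedBalance)
    stop("lagged covariance decomposition requires detailed balance")
  dec <- spectralDecomposition(laplacian(model), pi = ss@pi)
  sc <- .spectralCoefficients(model, dec)
  K <- -1 / outer(sc$lambda, sc$lambda, `+`)
  KC <- K %*% sc$C
  perEdge <- vapply(tau, function(tt) {
    ss@perWalkerFlux * colSums((exp(sc$lambda * tt) * sc$C) * KC)
  }, numeric(nrow(model@edges)))
  if (is.null(dim(perEdge))) perEdge <- matrix(perEdge, nrow = 1)
  list(tau = tau, perEdge = perEdge, total = colSums(perEdge))
}

#' Crossing frequency of two edge subsets' spectral contributions
#'
#' Finds the angular frequency in `bracket` at which
#' \eqn{\sum_{k \in A} S_k(\omega) - \sum_{k \in B} S_k(\omega)} changes
#' sign, by sign scan on a log grid followed by bisection to relative
#' tolerance 1e-6. Returns `NA` when the difference has constant sign on
#' the bracket; when several sign changes exist the smallest crossing is
#' returned with a warning.
#'
#' @param model a reversible [MarkovNetworkModel-class].
#' @param subsetA,subsetB disjoint nonempty integer sets of edge indices.
#' @param bracket positive interval `c(lo, hi)`.
#' @param gridSize points in the initial sign scan.
#' @return crossing frequency (scalar) or `NA`.
#' @export
crossingFrequency <- function(model, subsetA, subsetB,
                              bracket = c(1e-2, 1e2), gridSize = 400L) {
  subsetA <- as.integer(subsetA); subsetB <- as.integer(subsetB)
  m <- nrow(model@edges)
  if (!length(subsetA) || !length(subsetB))
    stop("both edge subsets must be nonempty")
  if (length(intersect(subsetA, subsetB)))
    stop("edge subsets must be disjoint")
  if (!all(c(subsetA, subsetB) %in% seq_len(m)))
    stop("edge indices out of range")
  stopifnot(length(bracket) == 2L, all(bracket > 0), bracket[1] < bracket[2])
  f <- .psdClosure(model)
  diffAt <- function(w) {
    S <- f(w)
    colSums(S[subsetA, , drop = FALSE]) - colSums(S[subsetB, , drop = FALSE])
  }
  grid <- 10^seq(log10(bracket[1]), log10(bracket[2]), length.out = gridSize)
  d <- diffAt(grid)
  flips <- which(d[-1] * d[-length(d)] < 0)
  if (!length(flips)) return(NA_real_)
  if (length(flips) > 1L)
    warning("multiple sign changes in bracket; returning the smallest")
  lo <- grid[flips[1]]; hi <- grid[flips[1] + 1L]
  while ((hi - lo) / lo > 1e-6) {
    mid <- sqrt(lo * hi)
    if (diffAt(mid) * diffAt(lo) <= 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}
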