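# pair label "i-j" (unordered) of each edge
.pairKeys <- function(edges) {
  paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "-")
}

# coefficients shared by the importance / spectral formulas:
# a_i = M^T v_i and g_{ik} = w_i^T zeta_k for the nontrivial eigenpairs
.spectralCoefficients <- function(model, dec) {
  Z <- stoichiometryMatrix(model)
  a <- as.numeric(crossprod(model@measurement, dec@rightVectors))[-1]
  G <- crossprod(dec@leftVectors, Z)[-1, , drop = FALSE]
  list(lambda = dec@eigenvalues[-1], a = a, G = G,
       C = a * G)   # C[i,k] = a_i g_{ik}
}

#' Edge importance: per-edge decomposition of the observable variance
#'
#' Computes, for every directed edge k, its exact contribution \eqn{R_k}
#' to the stationary variance of the observable \eqn{M^\top N(t)}
#' (per-walker normalization) via the spectral double sum
#' \deqn{R_k = J_k \sum_{i \ge 2} \sum_{j \ge 2}
#'   \frac{-1}{\lambda_i + \lambda_j}
#'   (M^\top v_i)(w_i^\top \zeta_k)(\zeta_k^\top w_j)(v_j^\top M).}
#' The decomposition requires a reversible network (detailed balance), under
#' which \eqn{\lambda_i + \lambda_j < 0} for all nontrivial pairs, so no
#' denominator can vanish. The total \eqn{R = \sum_k R_k} equals the
#' multinomial variance \eqn{M^\top C M} of a single walker.
#'
#' Relative importances \eqn{r_k = R_k / R} and pair-aggregated relative
#' importances (summing the two directed edges of each unordered state
#' pair) are included; under detailed balance reciprocal edges contribute
#' equally.
#'
#' @param model a reversible [MarkovNetworkModel-class].
#' @param dec optional precomputed [SpectralDecomposition-class].
#' @param ... unused.
#' @return an [EdgeImportance-class].
#' @examples
#' ei <- edgeImportance(threeStateChain(1, 1, 1, 1))
#' pairRelative(ei)          # hidden pair 1/8, observable pair 7/8
#' @export
setMethod("edgeImportance", "MarkovNetworkModel",
          function(model, dec = NULL, ...) {
  ss <- stationarySummary(model)
  if (!ss@detailedBalance)
    stop("edge importance requires detailed balance (reversible network); ",
         sprintf("detailed-balance residual = %.3e", ss@dbResidual))
  if (is.null(dec))
    dec <- spectralDecomposition(laplacian(model), pi = ss@pi)
  sc <- .spectralCoefficients(model, dec)
  K <- -1 / outer(sc$lambda, sc$lambda, `+`)
  stopifnot(all(is.finite(K)), all(K > 0))  # lambda_i + lambda_j < 0 always
  perEdge <- ss@perWalkerFlux * colSums(sc$C * (K %*% sc$C))
  perEdge <- pmax(perEdge, 0)
  total <- sum(perEdge)
  pair <- .pairKeys(model@edges)
  relative <- perEdge / total
  pairRel <- tapply(relative, pair, sum)
  pairRel <- pairRel[order(-pairRel)]
  new("EdgeImportance", perEdge = as.numeric(perEdge), total = total,
      relative = as.numeric(relative),
      pairRelative = stats::setNames(as.numeric(pairRel), names(pairRel)),
      pairOfEdge = pair)
})

#' Accessors for EdgeImportance
#'
#' @param x an [EdgeImportance-class].
#' @return `perEdgeImportance()` the vector \eqn{R_k}; `totalImportance()`
#'   \eqn{R = \sum_k R_k}; `relativeImportance()` \eqn{R_k / R};
#'   `pairRelative()` named vector of pair-aggregated relative importances.
#' @name importance-accessors
#' @aliases perEdgeImportance totalImportance relativeImportance pairRelative
NULL

#' @rdname importance-accessors
#' @export
perEdgeImportance <- function(x) x@perEdge
#' @rdname importance-accessors
#' @export
totalImportance <- function(x) x@total
#' @rdname importance-accessors
#' @export
relativeImportance <- function(x) x@relative
#' @rdname importance-accessors
#' @export
pairRelative <- function(x) x@pairRelative

#' Solve the network Lyapunov equation spectrally
#'
#' Returns the unique symmetric zero-row-sum solution \eqn{C} of
#' \eqn{LC + CL^\top = -F} for a symmetric matrix \eqn{F} whose rows and
#' columns sum to zero, via the spectral formula
#' \deqn{C = \sum_{\lambda < 0} \sum_{\lambda' < 0}
#'   \frac{-1}{\lambda + \lambda'} v_\lambda (w_\lambda^\top F w_{\lambda'})
#'   v_{\lambda'}^\top,}
#' which is exact in the zero-sum subspace without any deflation. Pass
#' \eqn{F = BB^\top} to obtain the stationary covariance.
#'
#' @param L graph Laplacian (n x n).
#' @param F symmetric n x n matrix with zero row/column sums.
#' @param dec a [SpectralDecomposition-class] of `L`.
#' @param tol validation tolerance on symmetry/zero-sum of `F`, relative to
#'   `max(abs(F))`.
#' @return the n x n solution matrix.
#' @export
lyapunovSolve <- function(L, F, dec, tol = 1e-8) {
  scale <- max(abs(F), 1e-300)
  if (max(abs(F - t(F))) > tol * scale)
    stop("F must be symmetric")
  if (max(abs(colSums(F))) > tol * scale || max(abs(rowSums(F))) > tol * scale)
    stop("rows and columns of F must sum to zero")
  lam <- dec@eigenvalues[-1]
  V <- dec@rightVectors[, -1, drop = FALSE]
  W <- dec@leftVectors[, -1, drop = FALSE]
  K <- -1 / outer(lam, lam, `+`)
  M <- K * (crossprod(W, F) %*% W)
  V %*% M %*% t(V)
}

#' Per-edge decomposition of the stationary covariance matrix
#'
#' Solves \eqn{L C_k + C_k L^\top = -B_k B_k^\top} for every edge and sums:
#' \eqn{C = \sum_k C_k} is the per-walker stationary covariance, and
#' \eqn{M^\top C_k M = R_k} recovers the edge importance.
#'
#' @param model a reversible [MarkovNetworkModel-class].
#' @param perWalker use per-walker fluxes (default TRUE).
#' @param ... unused.
#' @return a [CovarianceDecomposition-class].
#' @export
setMethod("covarianceDecomposition", "MarkovNetworkModel",
          function(model, perWalker = TRUE, ...) {
  ss <- stationarySummary(model)
  if (!ss@detailedBalance)
    stop("covariance decomposition requires detailed balance")
  L <- laplacian(model)
  dec <- spectralDecomposition(L, pi = ss@pi)
  nm <- noiseMatrix(model, ss, perWalker = perWalker)
  Ck <- lapply(nm$Bk, function(Bk) lyapunovSolve(L, tcrossprod(Bk), dec))
  C <- Reduce(`+`, Ck)
  res <- max(abs(L %*% C + C %*% t(L) + tcrossprod(nm$B)))
  new("CovarianceDecomposition", cov = C, covEdges = Ck,
      lyapunovResidual = res)
})

#' Stationary variance of the observable
#'
#' Multinomial stationary variance of \eqn{M^\top N}:
#' \eqn{N_{tot} (\sum_i M_i^2 \pi_i - (M^\top \pi)^2)}. For an indicator
#' measurement over open states this is the familiar open-state variance
#' \eqn{N_{tot}(\pi_1(1-\pi_1) + \pi_2(1-\pi_2) - 2\pi_1\pi_2)}.
#'
#' @param pi stationary probability vector.
#' @param M measurement vector.
#' @param nWalkers population size (default 1, per-walker units).
#' @return scalar variance.
#' @export
observableVariance <- function(pi, M, nWalkers = 1) {
  stopifnot(length(pi) == length(M))
  nWalkers * (sum(M^2 * pi) - sum(M * pi)^2)
}
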