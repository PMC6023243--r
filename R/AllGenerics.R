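#' @rdname laplacian
#' @export
setGeneric("laplacian", function(model) standardGeneric("laplacian"))

#' @rdname stationarySummary
#' @export
setGeneric("stationarySummary",
           function(model) standardGeneric("stationarySummary"))

#' @rdname spectralDecomposition
#' @export
setGeneric("spectralDecomposition",
           function(x, ...) standardGeneric("spectralDecomposition"))

#' @rdname edgeImportance
#' @export
setGeneric("edgeImportance", function(model, ...)
  standardGeneric("edgeImportance"))

#' @rdname covarianceDecomposition
#' @export
setGeneric("covarianceDecomposition", function(model, ...)
  standardGeneric("covarianceDecomposition"))

# ---- accessors -------------------------------------------------------------

#' Accessors for network model slots
#'
#' @param x a [MarkovNetworkModel-class] (or, for some accessors, another
#'   stochShield object).
#' @return `nStates()` the number of states; `nEdges()` the number of
#'   directed edges; `stateLabels()` the state labels; `edgeTable()` the edge
#'   data.frame (columns `k`, `from`, `to`, `rate`); `measurement()` the
#'   observable weight vector; `nWalkers()` the population size;
#'   `stoichiometryMatrix()` the n x m matrix whose column k is
#'   \eqn{\zeta_k}.
#' @aliases nStates nEdges stateLabels edgeTable measurement nWalkers
#'   stoichiometryMatrix
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname model-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname model-accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname model-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname model-accessors
#' @export
setGeneric("measurement", function(x) standardGeneric("measurement"))
#' @rdname model-accessors
#' @export
setGeneric("nWalkers", function(x) standardGeneric("nWalkers"))
#' @rdname model-accessors
#' @export
setGeneric("stoichiometryMatrix",
           function(x) standardGeneric("stoichiometryMatrix"))

setMethod("nStates", "MarkovNetworkModel", function(x) x@nStates)
setMethod("nEdges", "MarkovNetworkModel", function(x) nrow(x@edges))
setMethod("stateLabels", "MarkovNetworkModel", function(x) x@stateLabels)
setMethod("edgeTable", "MarkovNetworkModel", function(x) x@edges)
setMethod("measurement", "MarkovNetworkModel", function(x) x@measurement)
setMethod("nWalkers", "MarkovNetworkModel", function(x) x@nWalkers)

setMethod("stoichiometryMatrix", "MarkovNetworkModel", function(x) {
  n <- x@nStates
  e <- x@edges
  Z <- matrix(0, n, nrow(e))
  Z[cbind(e$from, seq_len(nrow(e)))] <- -1
  Z[cbind(e$to, seq_len(nrow(e)))] <- 1
  rownames(Z) <- x@stateLabels
  Z
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "MarkovNetworkModel", function(object) {
  cat(sprintf(
    "MarkovNetworkModel: %d states, %d directed edges, N_tot = %d\n",
    object@nStates, nrow(object@edges), object@nWalkers))
  cat("states:", paste(sprintf("%s[M=%g]", object@stateLabels,
                               object@measurement), collapse = " "), "\n")
  e <- object@edges
  cat("edges: ", paste(sprintf("%d:%d->%d(%.4g)", e$k, e$from, e$to, e$rate),
                       collapse = " "), "\n")
})

setMethod("show", "SpectralDecomposition", function(object) {
  cat("SpectralDecomposition with eigenvalues:\n")
  print(signif(object@eigenvalues, 6))
  cat(sprintf("biorthogonality residual %.2e, imaginary residual %.2e\n",
              object@residuals[["biorthogonality"]],
              object@residuals[["imaginary"]]))
})

setMethod("show", "StationarySummary", function(object) {
  cat("StationarySummary\n  pi:", signif(object@pi, 6), "\n")
  cat(sprintf("  detailed balance: %s (residual %.2e)\n",
              object@detailedBalance, object@dbResidual))
})

setMethod("show", "EdgeImportance", function(object) {
  cat("EdgeImportance (per-walker)\n")
  print(data.frame(edge = seq_along(object@perEdge),
                   pair = object@pairOfEdge,
                   Rk = signif(object@perEdge, 6),
                   relative = signif(object@relative, 6)))
  cat("total R =", format(object@total, digits = 10), "\n")
  cat("pair-relative:\n")
  print(signif(object@pairRelative, 6))
})

setMethod("show", "ReversalDiagnostics", function(object) {
  cat(sprintf("ReversalDiagnostics: eta = %.6g (%s)\n", object@eta,
              if (object@inverted) "INVERTED" else "not inverted"))
  cat(sprintf("  F1 = %.6g, F2 = %.6g, nu = %.6g, deltaJ = %.6g\n",
              object@F1, object@F2, object@nu, object@deltaJ))
  cat("  bounds:", paste(sprintf("%s=%.4g", names(object@bounds),
                                 object@bounds), collapse = ", "), "\n")
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf(
    "TrajectorySet: %d time points, dt = %g, seed = %d\n",
    length(object@times), object@dt, object@seed))
  cat("approximations:", paste(names(object@approximations),
                               collapse = ", "), "\n")
})

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf(
    "EnsembleResult: %d samples, log-%s sd w = %g, seed = %d\n",
    object@nSamples, object@logBase, object@w, object@seed))
  cat(sprintf("inversion fraction (eta > 1/2): %.4f\n",
              object@inversionFraction))
})
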