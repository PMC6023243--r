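#' Build and validate a Markov reaction network model
#'
#' Assembles a [MarkovNetworkModel-class] from state records, directed edge
#' records, a measurement vector and a population size, and validates it:
#' state indices must be contiguous `1..n`, directed edges unique with
#' positive rates, and the graph strongly connected (irreducible), checked
#' by graph search.
#'
#' @param states character vector of state labels (length n), or a
#'   data.frame with columns `id` and `label`.
#' @param edges data.frame with columns `from`, `to`, `rate` (an optional
#'   `k` column must equal the row order).
#' @param measurement numeric vector \eqn{M} of length n.
#' @param nWalkers positive integer population size \eqn{N_{tot}}.
#' @return a validated [MarkovNetworkModel-class].
#' @examples
#' m <- buildModel(c("C1", "C2", "O"),
#'                 data.frame(from = c(1, 2, 2, 3), to = c(2, 1, 3, 2),
#'                            rate = 1),
#'                 measurement = c(0, 0, 1), nWalkers = 1)
#' laplacian(m)
#' @export
buildModel <- function(states, edges, measurement, nWalkers = 1L) {
  if (is.data.frame(states)) {
    if (!all(c("id", "label") %in% names(states)))
      stop("state records need columns 'id' and 'label'")
    o <- order(states$id)
    if (!identical(as.integer(states$id[o]), seq_len(nrow(states))))
      stop("state ids must be contiguous 1..n")
    labels <- as.character(states$label[o])
  } else {
    labels <- as.character(states)
  }
  n <- length(labels)
  edges <- as.data.frame(edges)
  if (!all(c("from", "to", "rate") %in% names(edges)))
    stop("edge records need columns 'from', 'to', 'rate'")
  e <- data.frame(k = seq_len(nrow(edges)),
                  from = as.integer(edges$from),
                  to = as.integer(edges$to),
                  rate = as.numeric(edges$rate))
  model <- new("MarkovNetworkModel",
               nStates = as.integer(n), stateLabels = labels, edges = e,
               measurement = as.numeric(measurement),
               nWalkers = as.integer(nWalkers))
  validObject(model)
  .checkStronglyConnected(model)
  model
}

# irreducibility via igraph; reports which states are unreachable
.checkStronglyConnected <- function(model) {
  g <- igraph::graph_from_edgelist(
    as.matrix(model@edges[, c("from", "to")]), directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, model@nStates - igraph::vcount(g)))
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    stray <- which(comp$membership != main)
    stop(sprintf(
      "graph is not strongly connected; state(s) %s are not in the main communicating class",
      paste(stray, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Graph Laplacian of the network
#'
#' Returns the n x n matrix \eqn{L} governing the mean dynamics
#' \eqn{dX/dt = LX}: columns index source states
#' (\eqn{L = (A - D)^\top = Q^\top} with \eqn{Q} the generator), so
#' \eqn{L_{ji} = \alpha_{ij}} for each edge \eqn{i \to j} and the diagonal
#' holds minus the out-rate sums. Every column sums to zero.
#'
#' @param model a [MarkovNetworkModel-class].
#' @return numeric n x n matrix with zero column sums.
#' @export
setMethod("laplacian", "MarkovNetworkModel", function(model) {
  n <- model@nStates
  e <- model@edges
  L <- matrix(0, n, n, dimnames = list(model@stateLabels, model@stateLabels))
  for (r in seq_len(nrow(e))) {
    L[e$to[r], e$from[r]] <- L[e$to[r], e$from[r]] + e$rate[r]
    L[e$from[r], e$from[r]] <- L[e$from[r], e$from[r]] - e$rate[r]
  }
  L
})

#' Stationary distribution, fluxes and detailed balance
#'
#' Solves \eqn{L\pi = 0}, \eqn{\sum_i \pi_i = 1} for the stationary
#' distribution, computes per-edge stationary fluxes (per walker
#' \eqn{j_k = \alpha_k \pi_{i(k)}} and population
#' \eqn{J_k = N_{tot} j_k}), and tests detailed balance
#' \eqn{\pi_i \alpha_{ij} = \pi_j \alpha_{ji}} on every reciprocal edge
#' pair (relative tolerance 1e-8; an edge without a reciprocal partner
#' renders the network non-reversible).
#'
#' @param model a [MarkovNetworkModel-class].
#' @return a [StationarySummary-class].
#' @export
setMethod("stationarySummary", "MarkovNetworkModel", function(model) {
  L <- laplacian(model)
  n <- model@nStates
  A <- rbind(L, rep(1, n))
  pi <- as.numeric(qr.solve(A, c(rep(0, n), 1)))
  if (any(pi < -1e-10 * max(abs(pi))))
    stop("stationary solve produced negative entries; network may be reducible")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  if (max(abs(L %*% pi)) > 1e-8 * max(abs(L)))
    stop("no one-dimensional stationary null space (reducible network?)")
  e <- model@edges
  j <- e$rate * pi[e$from]
  # reciprocal partner of each edge, NA if absent
  key <- paste(e$from, e$to)
  rev <- match(paste(e$to, e$from), key)
  if (anyNA(rev)) {
    db <- FALSE
    res <- Inf
  } else {
    res <- max(abs(j - j[rev])) / max(j)
    db <- res <= 1e-8
  }
  new("StationarySummary", pi = pi, perWalkerFlux = j,
      populationFlux = as.numeric(model@nWalkers) * j,
      detailedBalance = db, dbResidual = res)
})

#' Biorthonormal eigendecomposition of the Laplacian
#'
#' For a reversible network the Laplacian is similar to the symmetric
#' matrix \eqn{D_\pi^{-1/2} L D_\pi^{1/2}}, whose eigendecomposition gives a
#' numerically guaranteed real spectrum and an exactly biorthogonal pair of
#' left/right bases; the method computes it this way and transforms back.
#' Eigenvalues are sorted descending with \eqn{\lambda_1 = 0}; the leading
#' right vector is rescaled to \eqn{\pi}, the leading left vector to the
#' all-ones vector. If the network is not reversible a general
#' eigendecomposition is attempted and an error is raised when an
#' eigenvalue has an imaginary part above tolerance, or when the matrix is
#' defective.
#'
#' @param x a [MarkovNetworkModel-class], or the Laplacian matrix itself.
#' @param pi stationary distribution (only when `x` is a matrix).
#' @param tol relative tolerance used to identify the zero eigenvalue and
#'   to bound imaginary residues.
#' @param ... passed through.
#' @return a [SpectralDecomposition-class].
#' @export
setMethod("spectralDecomposition", "MarkovNetworkModel",
          function(x, tol = 1e-10, ...) {
  ss <- stationarySummary(x)
  spectralDecomposition(laplacian(x), pi = ss@pi, tol = tol,
                        reversible = ss@detailedBalance)
})

#' @rdname spectralDecomposition
#' @param reversible logical; when TRUE the detailed-balance symmetrization
#'   is used.
#' @export
setMethod("spectralDecomposition", "matrix",
          function(x, pi, tol = 1e-10, reversible = TRUE, ...) {
  L <- x
  n <- nrow(L)
  stopifnot(length(pi) == n, all(pi > 0))
  if (reversible) {
    s <- sqrt(pi)
    S <- L * outer(1 / s, s)        # D^{-1/2} L D^{1/2}
    asym <- max(abs(S - t(S))) / max(abs(S))
    if (asym > 1e-6)
      stop("Laplacian is not symmetrizable by pi: detailed balance fails")
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    lam <- es$values                 # already descending
    V <- es$vectors * s              # rows scaled: v = D^{1/2} u
    W <- es$vectors / s              # w = D^{-1/2} u
    imagres <- 0
  } else {
    es <- eigen(L)
    imagres <- max(abs(Im(es$values)))
    if (imagres > tol * max(abs(es$values), 1))
      stop(sprintf(
        "complex eigenvalue (imaginary part %.3e): non-reversible network; edge-importance formula not applicable",
        imagres))
    ord <- order(Re(es$values), decreasing = TRUE)
    lam <- Re(es$values)[ord]
    V <- Re(es$vectors)[, ord, drop = FALSE]
    W <- tryCatch(t(solve(V)), error = function(e)
      stop("defective Laplacian: no full biorthogonal eigenbasis"))
  }
  scale <- max(abs(lam))
  nzero <- sum(abs(lam) < tol * scale)
  if (nzero != 1L)
    stop(sprintf("expected exactly one zero eigenvalue, found %d", nzero))
  lam[1] <- 0
  if (any(lam[-1] >= 0))
    stop("nontrivial eigenvalues must be strictly negative")
  # rescale the stationary pair: v1 -> pi, w1 -> ones
  c1 <- sum(V[, 1])
  V[, 1] <- V[, 1] / c1
  W[, 1] <- W[, 1] * c1
  biorth <- max(abs(crossprod(W, V) - diag(n)))
  if (biorth > 1e-8)
    stop(sprintf("biorthogonality residual too large: %.3e", biorth))
  new("SpectralDecomposition", eigenvalues = lam, rightVectors = V,
      leftVectors = W,
      residuals = c(biorthogonality = biorth, imaginary = imagres))
})

#' Noise coefficient matrix B and its per-edge pieces
#'
#' Column k of \eqn{B} is \eqn{\sqrt{J_k}\,\zeta_k} with \eqn{J_k} the
#' stationary flux of edge k (per-walker flux by default). \eqn{B_k} is
#' \eqn{B} with all columns except k zeroed, so that
#' \eqn{BB^\top = \sum_k B_k B_k^\top}.
#'
#' @param model a [MarkovNetworkModel-class].
#' @param summary optional precomputed [StationarySummary-class].
#' @param perWalker logical; use per-walker fluxes \eqn{j_k} (default) or
#'   population fluxes \eqn{N_{tot} j_k}.
#' @return list with elements `B` (n x m matrix) and `Bk` (list of m
#'   matrices).
#' @export
noiseMatrix <- function(model, summary = stationarySummary(model),
                        perWalker = TRUE) {
  flux <- if (perWalker) summary@perWalkerFlux else summary@populationFlux
  Z <- stoichiometryMatrix(model)
  B <- Z * rep(sqrt(flux), each = nrow(Z))
  Bk <- lapply(seq_len(ncol(B)), function(k) {
    M <- matrix(0, nrow(B), ncol(B))
    M[, k] <- B[, k]
    M
  })
  list(B = B, Bk = Bk)
}
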