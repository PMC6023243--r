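#' Colquhoun-Hawkes 5-state nicotinic acetylcholine receptor model
#'
#' Builds the 5-state nAChR gating scheme with states AR (singly bound,
#' open), A2R (doubly bound, open), A2T (doubly bound, closed), AT (singly
#' bound, closed) and T (unbound, closed), ten directed edges numbered as
#' in the standard tabulation (pair 1/2 between states 1 and 2, then
#' clockwise, ending with pair 9/10 between AT and T), and measurement
#' \eqn{M = (1,1,0,0,0)} marking the conducting states. Binding edges 2, 6
#' and 10 have rates proportional to the acetylcholine concentration `c`
#' (in micromolar); the single cycle 1-2-3-4 satisfies the Kolmogorov
#' criterion for every `c`, so the network is reversible throughout.
#'
#' Rates (per ms, c in uM): edge 1 (2->1) 2/3 x 1e-3; edge 2 (1->2) 0.5c;
#' edge 3 (3->2) 15; edge 4 (2->3) 0.5; edge 5 (3->4) 4; edge 6 (4->3)
#' 0.5c; edge 7 (4->1) 0.015; edge 8 (1->4) 3; edge 9 (4->5) 2; edge 10
#' (5->4) 0.1c.
#'
#' @param c acetylcholine concentration, must be > 0 for irreducibility.
#' @param nWalkers population size (number of channels).
#' @return a [MarkovNetworkModel-class] with 5 states and 10 edges.
#' @examples
#' m <- nachrModel(0.5)
#' stationarySummary(m)@detailedBalance
#' @export
nachrModel <- function(c, nWalkers = 1L) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("concentration c must be a positive number")
  edges <- data.frame(
    from = c(2L, 1L, 3L, 2L, 3L, 4L, 4L, 1L, 4L, 5L),
    to   = c(1L, 2L, 2L, 3L, 4L, 3L, 1L, 4L, 5L, 4L),
    rate = c(2e-3 / 3, 0.5 * c, 15, 0.5, 4, 0.5 * c, 0.015, 3, 2, 0.1 * c))
  buildModel(c("AR", "A2R", "A2T", "AT", "T"), edges,
             measurement = c(1, 1, 0, 0, 0), nWalkers = nWalkers)
}

#' Build a 3-state chain model
#'
#' The chain 1 - 2 - 3 with edges numbered in the conventional order
#' k = 1: 1->2, k = 2: 2->1, k = 3: 2->3, k = 4: 3->2 (so
#' \eqn{\alpha_1 \equiv \alpha_{12}}, \eqn{\alpha_2 \equiv \alpha_{21}},
#' \eqn{\alpha_3 \equiv \alpha_{23}}, \eqn{\alpha_4 \equiv \alpha_{32}}).
#'
#' @param a12,a21,a23,a32 positive rates.
#' @param observableState which state carries the observable (2 or 3).
#' @param nWalkers population size.
#' @return a [MarkovNetworkModel-class].
#' @export
threeStateChain <- function(a12, a21, a23, a32, observableState = 3L,
                            nWalkers = 1L) {
  stopifnot(observableState %in% c(2L, 3L))
  M <- c(0, 0, 0)
  M[observableState] <- 1
  edges <- data.frame(from = c(1L, 2L, 2L, 3L), to = c(2L, 1L, 3L, 2L),
                      rate = c(a12, a21, a23, a32))
  buildModel(c("S1", "S2", "S3"), edges, measurement = M,
             nWalkers = nWalkers)
}

# Table of the twelve canonical one-parameter chains: which of the four
# rates (1->2, 2->1, 2->3, 3->2) equal alpha (vs 1), and the observable.
.caseTable <- list(
  list(obs = 3L, a = c(TRUE,  TRUE,  FALSE, FALSE)),
  list(obs = 3L, a = c(FALSE, TRUE,  TRUE,  FALSE)),
  list(obs = 3L, a = c(TRUE,  FALSE, TRUE,  FALSE)),
  list(obs = 3L, a = c(TRUE,  FALSE, FALSE, FALSE)),
  list(obs = 3L, a = c(FALSE, TRUE,  FALSE, FALSE)),
  list(obs = 3L, a = c(FALSE, FALSE, TRUE,  FALSE)),
  list(obs = 3L, a = c(FALSE, FALSE, FALSE, TRUE)),
  list(obs = 2L, a = c(TRUE,  TRUE,  FALSE, FALSE)),
  list(obs = 2L, a = c(FALSE, TRUE,  TRUE,  FALSE)),
  list(obs = 2L, a = c(TRUE,  FALSE, TRUE,  FALSE)),
  list(obs = 2L, a = c(TRUE,  FALSE, FALSE, FALSE)),
  list(obs = 2L, a = c(FALSE, TRUE,  FALSE, FALSE))
)

#' Canonical one-parameter 3-state chains
#'
#' The twelve catalogued 3-state chains in which a subset of the four
#' rates is set to a common value `alpha` and the rest to 1. Cases 1-7
#' have the end state (3) observable; cases 8-12 have the middle state (2)
#' observable.
#'
#' @param caseId integer 1..12.
#' @param alpha positive rate parameter.
#' @param nWalkers population size.
#' @return a [MarkovNetworkModel-class].
#' @export
threeStateCase <- function(caseId, alpha, nWalkers = 1L) {
  caseId <- as.integer(caseId)
  if (is.na(caseId) || caseId < 1L || caseId > 12L)
    stop("caseId must be an integer in 1..12")
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  cs <- .caseTable[[caseId]]
  r <- ifelse(cs$a, alpha, 1)
  threeStateChain(r[1], r[2], r[3], r[4], observableState = cs$obs,
                  nWalkers = nWalkers)
}

#' Named fixture models
#'
#' Addressable builders for the bundled models: `"nachr"` (requires
#' `c`), `"chain-case-<n>"` (requires `alpha`), `"example-A"` (rates
#' 1, 1, 10, 0.1), `"example-B"` (rates 0.1, 1, 10, 10) and
#' `"beta-slice"` (rates 1/beta, 1, beta, 1; requires `beta`).
#'
#' @param name fixture name.
#' @param c,alpha,beta fixture parameters.
#' @param nWalkers population size.
#' @return a [MarkovNetworkModel-class].
#' @export
fixtureModel <- function(name, c = NULL, alpha = NULL, beta = NULL,
                         nWalkers = 1L) {
  if (identical(name, "nachr")) {
    if (is.null(c)) stop("fixture 'nachr' needs a concentration c")
    return(nachrModel(c, nWalkers))
  }
  if (grepl("^chain-case-[0-9]+$", name)) {
    if (is.null(alpha)) stop("chain-case fixtures need alpha")
    return(threeStateCase(as.integer(sub("chain-case-", "", name)), alpha,
                          nWalkers))
  }
  if (identical(name, "example-A"))
    return(threeStateChain(1, 1, 10, 0.1, nWalkers = nWalkers))
  if (identical(name, "example-B"))
    return(threeStateChain(0.1, 1, 10, 10, nWalkers = nWalkers))
  if (identical(name, "beta-slice")) {
    if (is.null(beta)) stop("fixture 'beta-slice' needs beta")
    return(threeStateChain(1 / beta, 1, beta, 1, nWalkers = nWalkers))
  }
  stop("unknown fixture '", name, "'")
}

#' Edge-importance scan of the nAChR model over concentration
#'
#' Computes pair-aggregated relative edge importances of the nAChR model
#' across an acetylcholine concentration grid and locates the crossover
#' concentration at which the observable pair \{edges 3, 4\} (states 2-3)
#' overtakes the hidden pair \{edges 5, 6\} (states 3-4), by bisection in
#' log10 c between adjacent grid points with opposite ordering.
#'
#' @param cGrid positive concentration grid (uM); default 60 log-spaced
#'   points over `[0.1, 100]`.
#' @param tol bisection tolerance in log10 c.
#' @return list with `table` (data.frame: c plus one column per state
#'   pair) and `crossover` (concentration, or `NA` if none in the grid).
#' @export
nachrImportanceScan <- function(cGrid = 10^seq(-1, 2, length.out = 60),
                                tol = 1e-3) {
  stopifnot(all(cGrid > 0))
  pr <- lapply(cGrid, function(cc) {
    ei <- edgeImportance(nachrModel(cc))
    rowsum(ei@relative, ei@pairOfEdge)[, 1]
  })
  pairNames <- names(pr[[1]])
  tab <- data.frame(c = cGrid,
                    do.call(rbind, lapply(pr, function(p) p[pairNames])))
  names(tab) <- c("c", paste0("pair.", gsub("-", ".", pairNames)))
  diffAt <- function(cc) {
    ei <- edgeImportance(nachrModel(cc))
    p <- rowsum(ei@relative, ei@pairOfEdge)[, 1]
    p[["2-3"]] - p[["3-4"]]      # observable pair minus hidden pair
  }
  d <- vapply(cGrid, diffAt, numeric(1))
  flips <- which(d[-1] * d[-length(d)] < 0)
  crossover <- NA_real_
  if (length(flips)) {
    lo <- log10(cGrid[flips[1]]); hi <- log10(cGrid[flips[1] + 1L])
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (diffAt(10^mid) * diffAt(10^lo) <= 0) hi <- mid else lo <- mid
    }
    crossover <- 10^((lo + hi) / 2)
  }
  list(table = tab, crossover = crossover)
}

#' Timescale-separation scan of the nAChR model
#'
#' Ratios of nontrivial Laplacian eigenvalues \eqn{\lambda_2/\lambda_j}
#' (j = 3, 4, 5) across a concentration grid, with a separation flag when
#' any ratio drops below 0.1 (eigenvalues differing by at least an order
#' of magnitude).
#'
#' @param cGrid positive concentration grid.
#' @return data.frame with columns `c`, `ratio32`, `ratio42`, `ratio52`,
#'   `separated`.
#' @export
nachrTimescaleScan <- function(cGrid = 10^seq(-1, 2, length.out = 60)) {
  stopifnot(all(cGrid > 0))
  rows <- lapply(cGrid, function(cc) {
    lam <- spectralDecomposition(nachrModel(cc))@eigenvalues
    r <- lam[2] / lam[3:5]
    data.frame(c = cc, ratio32 = r[1], ratio42 = r[2], ratio52 = r[3],
               separated = any(r < 0.1))
  })
  do.call(rbind, rows)
}

#' Scan a canonical chain case over its rate parameter
#'
#' For a catalogued 3-state case, sweeps `alpha` over a grid and reports
#' the eigenvalue ratio \eqn{\lambda_2/\lambda_3} and the pair-aggregated
#' relative importances of the 1-2 and 2-3 edge pairs.
#'
#' @param caseId integer 1..12.
#' @param alphaGrid positive grid; default 33 log-spaced points over
#'   `[1e-4, 1e4]`.
#' @return data.frame with columns `alpha`, `eigRatio`, `pair12`,
#'   `pair23`.
#' @export
caseScan <- function(caseId, alphaGrid = 10^seq(-4, 4, length.out = 33)) {
  stopifnot(all(alphaGrid > 0))
  rows <- lapply(alphaGrid, function(a) {
    m <- threeStateCase(caseId, a)
    lam <- spectralDecomposition(m)@eigenvalues
    ei <- edgeImportance(m)
    p <- rowsum(ei@relative, ei@pairOfEdge)[, 1]
    data.frame(alpha = a, eigRatio = lam[2] / lam[3],
               pair12 = p[["1-2"]], pair23 = p[["2-3"]])
  })
  do.call(rbind, rows)
}

#' Lognormal rate ensemble of 3-state chains
#'
#' Draws `nSamples` independent rate quadruples with
#' \eqn{\log \alpha_{ij} \sim N(0, w^2)} (natural log by default, base 10
#' optionally), evaluates the closed-form reversal diagnostics for each,
#' and reports the fraction of samples with inverted edge importance
#' (\eqn{\eta > 1/2}).
#'
#' @param nSamples ensemble size.
#' @param w standard deviation of the Gaussian log-rates.
#' @param seed integer RNG seed.
#' @param logBase `"e"` (natural log, default) or `"10"`.
#' @return an [EnsembleResult-class].
#' @examples
#' res <- sampleEnsemble(10000, w = 10, seed = 1)
#' res@inversionFraction
#' @export
sampleEnsemble <- function(nSamples, w, seed, logBase = c("e", "10")) {
  logBase <- match.arg(logBase)
  stopifnot(nSamples >= 1, w > 0)
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(4 * nSamples, mean = 0, sd = w),
                  ncol = 4)
  rates <- if (logBase == "e") exp(draws) else 10^draws
  samples <- .threeStateDiagnostics(rates[, 1], rates[, 2], rates[, 3],
                                    rates[, 4])
  new("EnsembleResult", w = as.numeric(w), logBase = logBase,
      nSamples = as.integer(nSamples), seed = as.integer(seed),
      samples = samples, inversionFraction = mean(samples$inverted))
}

#' Probability that one of four iid rates is largest while another pair
#' is ordered
#'
#' For four exchangeable continuous random variables W, X, Y, Z, the
#' probability of the event \eqn{\{Z > \max(W, X, Y)\} \cap \{W < X\}} is
#' computed exactly by enumerating the 24 equally likely orderings. With
#' the identification \eqn{W = \alpha_{12}}, \eqn{X = \alpha_{21}},
#' \eqn{Y = \alpha_{32}}, \eqn{Z = \alpha_{23}} this is the probability
#' that an iid rate ensemble satisfies both necessary inversion
#' conditions, an upper reference point (1/8) for the observed inversion
#' fraction.
#'
#' @return the exact probability (a fraction of 24).
#' @export
orderingProbability <- function() {
  perms <- .permutations4()
  # columns give the ranks of (W, X, Y, Z); count Z largest and W < X
  hit <- apply(perms, 1, function(p) p[4] == 4L && p[1] < p[2])
  sum(hit) / nrow(perms)
}

#' @rdname orderingProbability
#' @param n number of Monte-Carlo draws.
#' @param seed integer RNG seed.
#' @return `orderingProbabilityMC`: list with the point estimate and its
#'   binomial standard error.
#' @export
orderingProbabilityMC <- function(n, seed) {
  set.seed(as.integer(seed))
  W <- stats::runif(n); X <- stats::runif(n)
  Y <- stats::runif(n); Z <- stats::runif(n)
  hit <- (Z > pmax(W, X, Y)) & (W < X)
  p <- mean(hit)
  list(estimate = p, se = sqrt(p * (1 - p) / n))
}

# all 24 permutations of 1:4, one per row
.permutations4 <- function() {
  out <- matrix(0L, 0L, 4L)
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j)))
    out <- rbind(out, c(i, j, k, setdiff(1:4, c(i, j, k))))
  out
}
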