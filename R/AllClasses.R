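#' @import methods
NULL

#' First-order Markov reaction network with an observable
#'
#' A directed, weighted graph on \code{n} states carrying a per-state
#' measurement vector \eqn{M} and a population size \eqn{N_{tot}} of
#' independent random walkers. Each directed edge \code{k} runs from source
#' state \code{i(k)} to target state \code{j(k)} with a positive per-capita
#' rate \eqn{\alpha_k} (units 1/time). The stoichiometry vector of edge
#' \code{k} is \eqn{\zeta_k = e_{j(k)} - e_{i(k)}}.
#'
#' Objects are constructed with [buildModel()] (or the fixture builders
#' [nachrModel()], [threeStateChain()], [threeStateCase()]), which validate
#' positivity of the rates, uniqueness of directed edges and strong
#' connectivity of the graph.
#'
#' @slot nStates integer, number of states (\eqn{\ge 2}).
#' @slot stateLabels character vector of length \code{nStates}.
#' @slot edges data.frame with columns \code{k} (1-based edge index in file
#'   order), \code{from}, \code{to} (1-based state indices) and \code{rate}.
#' @slot measurement numeric vector \eqn{M} of length \code{nStates}.
#' @slot nWalkers integer population size \eqn{N_{tot}}.
#'
#' @seealso [laplacian()], [stationarySummary()], [edgeImportance()]
#' @export
setClass("MarkovNetworkModel",
  slots = c(
    nStates     = "integer",
    stateLabels = "character",
    edges       = "data.frame",
    measurement = "numeric",
    nWalkers    = "integer"
  )
)

setValidity("MarkovNetworkModel", function(object) {
  n <- object@nStates
  e <- object@edges
  msgs <- character(0)
  if (length(n) != 1L || is.na(n) || n < 2L)
    msgs <- c(msgs, "need at least 2 states")
  if (length(object@stateLabels) != n)
    msgs <- c(msgs, "stateLabels must have length nStates")
  if (!all(c("k", "from", "to", "rate") %in% names(e)))
    msgs <- c(msgs, "edges must have columns k, from, to, rate")
  else {
    if (nrow(e) < 2L)
      msgs <- c(msgs, "need at least 2 edges")
    if (!all(e$from %in% seq_len(n)) || !all(e$to %in% seq_len(n)))
      msgs <- c(msgs, "edge endpoints must reference existing states")
    if (any(e$from == e$to))
      msgs <- c(msgs, "self-loops are not allowed")
    if (any(!is.finite(e$rate)) || any(e$rate <= 0)) {
      bad <- which(!is.finite(e$rate) | e$rate <= 0)
      msgs <- c(msgs, sprintf("nonpositive rate on edge(s) %s",
                              paste(e$k[bad], collapse = ", ")))
    }
    key <- paste(e$from, e$to)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)]
      msgs <- c(msgs, sprintf("duplicate directed edge(s): %s",
                              paste(unique(gsub(" ", "->", d)), collapse = ", ")))
    }
  }
  if (length(object@measurement) != n || any(!is.finite(object@measurement)))
    msgs <- c(msgs, "measurement must be a finite vector of length nStates")
  if (length(object@nWalkers) != 1L || is.na(object@nWalkers) ||
      object@nWalkers < 1L)
    msgs <- c(msgs, "nWalkers must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

#' Eigendecomposition of a graph Laplacian
#'
#' Real biorthonormal eigentriples \eqn{(w_i, \lambda_i, v_i)} of the graph
#' Laplacian of a reversible network, sorted so that
#' \eqn{\lambda_1 = 0 > \lambda_2 \ge \dots \ge \lambda_n}. The leading right
#' vector is rescaled to the stationary distribution \eqn{\pi} and the
#' leading left vector to the all-ones vector, so that
#' \eqn{w_i^\top v_j = \delta_{ij}}.
#'
#' @slot eigenvalues numeric, descending, \code{eigenvalues[1] == 0}.
#' @slot rightVectors n x n matrix, columns \eqn{v_i}.
#' @slot leftVectors n x n matrix, columns \eqn{w_i}.
#' @slot residuals named numeric: \code{biorthogonality} is the maximum of
#'   \eqn{|w_i^\top v_j - \delta_{ij}|}; \code{imaginary} the largest
#'   imaginary component discarded.
#' @export
setClass("SpectralDecomposition",
  slots = c(
    eigenvalues  = "numeric",
    rightVectors = "matrix",
    leftVectors  = "matrix",
    residuals    = "numeric"
  )
)

#' Stationary distribution and fluxes of a network
#'
#' @slot pi stationary probability vector.
#' @slot perWalkerFlux \eqn{j_k = \alpha_k \pi_{i(k)}} per edge.
#' @slot populationFlux \eqn{J_k = N_{tot} j_k} per edge.
#' @slot detailedBalance logical; TRUE iff every reciprocal edge pair
#'   satisfies \eqn{\pi_i \alpha_{ij} = \pi_j \alpha_{ji}} within relative
#'   tolerance 1e-8 (an edge without a reciprocal partner makes it FALSE).
#' @slot dbResidual max over reciprocal pairs of
#'   \eqn{|\pi_i \alpha_{ij} - \pi_j \alpha_{ji}|} / max flux.
#' @export
setClass("StationarySummary",
  slots = c(
    pi              = "numeric",
    perWalkerFlux   = "numeric",
    populationFlux  = "numeric",
    detailedBalance = "logical",
    dbResidual      = "numeric"
  )
)

#' Per-edge decomposition of the stationary observable variance
#'
#' Holds the edge importance \eqn{R_k} of every directed edge: its exact
#' contribution to the stationary variance of the observable
#' \eqn{M^\top N(t)}, normalized to a single random walker. The total
#' \eqn{R = \sum_k R_k} equals the multinomial variance
#' \eqn{M^\top C M}.
#'
#' @slot perEdge numeric \eqn{R_k}, one per directed edge, edge order.
#' @slot total \eqn{R = \sum_k R_k}.
#' @slot relative \eqn{r_k = R_k / R}.
#' @slot pairRelative named numeric; for each unordered state pair
#'   \code{"i-j"}, the summed relative importance of its two directed edges.
#' @slot pairOfEdge character, the \code{"i-j"} pair label of each edge.
#' @export
setClass("EdgeImportance",
  slots = c(
    perEdge      = "numeric",
    total        = "numeric",
    relative     = "numeric",
    pairRelative = "numeric",
    pairOfEdge   = "character"
  )
)

#' Per-edge decomposition of the stationary covariance matrix
#'
#' The unique decomposition \eqn{C = \sum_k C_k} of the per-walker
#' stationary covariance, where \eqn{C_k} solves
#' \eqn{L C_k + C_k L^\top = -B_k B_k^\top}.
#'
#' @slot cov n x n per-walker stationary covariance.
#' @slot covEdges list of n x n matrices, one per edge.
#' @slot lyapunovResidual max abs entry of \eqn{LC + CL^\top + BB^\top}.
#' @export
setClass("CovarianceDecomposition",
  slots = c(
    cov              = "matrix",
    covEdges         = "list",
    lyapunovResidual = "numeric"
  )
)

#' Rates of a 3-state chain 1 - 2 - 3
#'
#' Rate quadruple \eqn{(\alpha_{12}, \alpha_{21}, \alpha_{23}, \alpha_{32})}
#' of the chain with states 1, 2, 3, together with which state carries the
#' observable (state 3 for the classic open-state-at-the-end chain, state 2
#' for the middle-state-conducting variant).
#'
#' @slot a12,a21,a23,a32 positive transition rates.
#' @slot observableState integer, 2 or 3.
#' @export
setClass("ThreeStateRates",
  slots = c(a12 = "numeric", a21 = "numeric", a23 = "numeric",
            a32 = "numeric", observableState = "integer")
)

setValidity("ThreeStateRates", function(object) {
  r <- c(object@a12, object@a21, object@a23, object@a32)
  if (length(r) != 4L || any(!is.finite(r)) || any(r <= 0))
    return("all four rates must be positive and finite")
  if (!object@observableState %in% c(2L, 3L))
    return("observableState must be 2 or 3")
  TRUE
})

#' Reversal diagnostics for a 3-state chain with state 3 observable
#'
#' Closed-form quantities governing edge-importance reversal: the fraction
#' \eqn{\eta = R_{12} / (R_{12} + R_{23})} of the observable state's
#' stationary variance generated by the hidden edges, its factorization
#' \eqn{\eta = F_1 F_2}, the eigenvalue ratio \eqn{\nu = \lambda_3 /
#' \lambda_2}, two-state relaxation times \eqn{\tau_{ij} = (\alpha_{ij} +
#' \alpha_{ji})^{-1}}, the flux asymmetry \eqn{\Delta J}, the stationary
#' distribution and four upper bounds on \eqn{\eta}.
#'
#' @slot eta hidden-edge importance fraction, in (0, 1).
#' @slot F1 \eqn{\alpha_{21} / (\alpha_{12} + \alpha_{21})}.
#' @slot F2 \eqn{\alpha_{23} / (\alpha_{12}+\alpha_{21}+\alpha_{23}+\alpha_{32})}.
#' @slot nu \eqn{\lambda_3 / \lambda_2 \ge 1}.
#' @slot tau12,tau23 local relaxation times.
#' @slot deltaJ \eqn{(J_{12} - J_{23}) / (J_{12} + J_{23})}.
#' @slot pi stationary 3-vector.
#' @slot bounds named numeric of the four upper bounds on eta:
#'   \code{occupancy} \eqn{((1-\pi_2)/(1+\pi_2))^2}, \code{rateRatio}
#'   \eqn{\alpha_{23}/(\alpha_{23}+\alpha_{32})}, \code{relaxation}
#'   \eqn{\tau_{12}/(\tau_{12}+\tau_{23})}, \code{flux}
#'   \eqn{1/2 - \Delta J / 2}.
#' @slot inverted logical, \code{eta > 1/2}.
#' @slot rates the input rate quadruple (a12, a21, a23, a32).
#' @export
setClass("ReversalDiagnostics",
  slots = c(
    eta = "numeric", F1 = "numeric", F2 = "numeric", nu = "numeric",
    tau12 = "numeric", tau23 = "numeric", deltaJ = "numeric",
    pi = "numeric", bounds = "numeric", inverted = "logical",
    rates = "numeric"
  )
)

#' Exact jump trajectory of the discrete population process
#'
#' Event-driven output of the Gillespie stochastic simulation algorithm:
#' event times, the edge fired at each event, and the population vector
#' after each event (each summing to \eqn{N_{tot}}).
#'
#' @slot eventTimes increasing numeric.
#' @slot edgeIndices integer, the 1-based edge fired at each event.
#' @slot initialState integer population vector at time 0.
#' @slot statesAfterEvent integer matrix, one row per event.
#' @slot seed integer seed used.
#' @slot tMax simulated horizon.
#' @export
setClass("JumpTrajectory",
  slots = c(
    eventTimes       = "numeric",
    edgeIndices      = "integer",
    initialState     = "integer",
    statesAfterEvent = "matrix",
    seed             = "integer",
    tMax             = "numeric"
  )
)

#' Coupled Langevin trajectories of the full and shielded processes
#'
#' Euler-Maruyama paths of the centered fluctuation process
#' \eqn{dX = LX\,dt + B\,dW} together with stochastic-shielding
#' approximations that retain the noise on a subset of edges only. All
#' paths share the same per-edge Gaussian increments (common random
#' numbers), so an approximation differs from the full path only through
#' the omitted noise terms.
#'
#' @slot times uniform time grid.
#' @slot full matrix, one row per time point, one column per state.
#' @slot approximations named list of matrices like \code{full}.
#' @slot retainedSets named list of integer edge index vectors.
#' @slot model the [MarkovNetworkModel-class] simulated.
#' @slot seed,dt simulation seed and step.
#' @export
setClass("TrajectorySet",
  slots = c(
    times          = "numeric",
    full           = "matrix",
    approximations = "list",
    retainedSets   = "list",
    model          = "MarkovNetworkModel",
    seed           = "integer",
    dt             = "numeric"
  )
)

#' Pathwise discrepancy of a shielded approximation
#'
#' @slot label which approximation was compared.
#' @slot mse empirical stationary mean square of \eqn{M^\top (Y - X)}.
#' @slot theoretical \eqn{\sum_{k \notin retained} R_k}.
#' @slot ratio mse / theoretical.
#' @slot burnIn time discarded before averaging.
#' @export
setClass("DiscrepancyResult",
  slots = c(label = "character", mse = "numeric", theoretical = "numeric",
            ratio = "numeric", burnIn = "numeric")
)

#' Lognormal rate ensemble of 3-state chains
#'
#' @slot w standard deviation of the Gaussian log-rates.
#' @slot logBase "e" or "10".
#' @slot nSamples,seed ensemble size and seed.
#' @slot samples data.frame with one row per quadruple: rates, eta, F1, F2,
#'   nu, deltaJ, tau ratio, pi, the four bounds and the inverted flag.
#' @slot inversionFraction fraction of samples with eta > 1/2.
#' @export
setClass("EnsembleResult",
  slots = c(
    w = "numeric", logBase = "character", nSamples = "integer",
    seed = "integer", samples = "data.frame", inversionFraction = "numeric"
  )
)
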