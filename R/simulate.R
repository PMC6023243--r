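#' Exact stochastic simulation (Gillespie SSA)
#'
#' Simulates the discrete population process exactly: the propensity of
#' edge k is \eqn{\alpha_k N_{i(k)}(t)}, waiting times are exponential in
#' the total propensity and the firing edge is chosen proportionally to
#' its propensity. Every event is recorded. Reproducible given `seed`.
#'
#' @param model a [MarkovNetworkModel-class].
#' @param initial integer population vector summing to `nWalkers(model)`;
#'   default puts all walkers in state 1.
#' @param tMax positive simulation horizon.
#' @param seed integer RNG seed.
#' @param maxEvents safety cap on the number of recorded events.
#' @return a [JumpTrajectory-class].
#' @export
ssaSimulate <- function(model, initial = NULL, tMax, seed,
                        maxEvents = 5e7) {
  if (!is.numeric(tMax) || tMax <= 0) stop("tMax must be positive")
  if (is.null(initial)) {
    initial <- integer(model@nStates)
    initial[1] <- model@nWalkers
  }
  initial <- as.integer(initial)
  if (length(initial) != model@nStates || any(initial < 0) ||
      sum(initial) != model@nWalkers)
    stop("initial must be a nonnegative population vector summing to nWalkers")
  e <- model@edges
  set.seed(as.integer(seed))
  out <- .ssaRun(e$rate, e$from - 1L, e$to - 1L, initial, tMax,
                 as.numeric(maxEvents))
  new("JumpTrajectory", eventTimes = out$times,
      edgeIndices = as.integer(out$edges), initialState = initial,
      statesAfterEvent = out$states, seed = as.integer(seed),
      tMax = as.numeric(tMax))
}

#' Long-run SSA statistics of the observable
#'
#' Runs the SSA without storing the path and returns time-weighted batch
#' means of \eqn{y = M^\top N} and \eqn{y^2} over `[burnIn, tMax]`,
#' from which the stationary mean and variance of the observable and a
#' Monte-Carlo standard error (over batches) are derived.
#'
#' @inheritParams ssaSimulate
#' @param burnIn time discarded before averaging.
#' @param nBatch number of equal-time batches.
#' @return list with `mean`, `variance`, `varianceSE`, `batchMeanY`,
#'   `batchMeanY2`.
#' @export
ssaObservableStats <- function(model, initial = NULL, tMax, seed,
                               burnIn = 0, nBatch = 50L) {
  if (!is.numeric(tMax) || tMax <= 0) stop("tMax must be positive")
  if (burnIn < 0 || burnIn >= tMax) stop("need 0 <= burnIn < tMax")
  if (is.null(initial)) {
    initial <- integer(model@nStates)
    initial[1] <- model@nWalkers
  }
  e <- model@edges
  set.seed(as.integer(seed))
  st <- .ssaStats(e$rate, e$from - 1L, e$to - 1L, as.integer(initial),
                  model@measurement, tMax, burnIn, as.integer(nBatch))
  mu <- mean(st$batchMeanY)
  # per-batch time-average of (y - mu)^2 about the global mean
  vb <- st$batchMeanY2 - 2 * mu * st$batchMeanY + mu^2
  list(mean = mu, variance = mean(vb),
       varianceSE = stats::sd(vb) / sqrt(length(vb)),
       batchMeanY = st$batchMeanY, batchMeanY2 = st$batchMeanY2)
}

#' Langevin simulation with per-edge noise and stochastic shielding
#'
#' Euler-Maruyama integration of the centered fluctuation process
#' \eqn{dX = LX\,dt + B\,dW} (per-walker noise matrix by default),
#' starting from \eqn{X(0) = 0}. One standard Gaussian increment stream
#' per edge is drawn once from `seed`, and every shielded approximation
#' reuses exactly those increments on its retained edges (common random
#' numbers), so approximations differ from the full path only through the
#' omitted noise terms. The full process is always simulated; an empty
#' retained set gives the noise-free relaxation (identically zero here).
#'
#' @param model a [MarkovNetworkModel-class].
#' @param tMax horizon.
#' @param dt positive step; a warning is issued if `dt > 0.1/|lambda_n|`.
#' @param seed integer RNG seed.
#' @param retainedSets named list of integer edge-index vectors; each
#'   entry yields one shielded approximation.
#' @param perWalker use per-walker fluxes in B (default TRUE).
#' @return a [TrajectorySet-class].
#' @export
langevinSimulate <- function(model, tMax, dt, seed, retainedSets = list(),
                             perWalker = TRUE) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (tMax <= dt) stop("tMax must exceed dt")
  ss <- stationarySummary(model)
  dec <- spectralDecomposition(laplacian(model), pi = ss@pi,
                               reversible = ss@detailedBalance)
  lamN <- min(dec@eigenvalues)
  if (dt > 0.1 / abs(lamN))
    warning(sprintf("dt = %g exceeds 0.1/|lambda_n| = %g; integration may be unstable",
                    dt, 0.1 / abs(lamN)))
  m <- nrow(model@edges)
  for (rs in retainedSets)
    if (length(rs) && !all(rs %in% seq_len(m)))
      stop("retained set contains unknown edge indices")
  if (length(retainedSets) && is.null(names(retainedSets)))
    names(retainedSets) <- vapply(retainedSets, function(rs)
      if (length(rs)) paste0("e", paste(rs, collapse = ",")) else "none",
      character(1))
  L <- laplacian(model)
  B <- noiseMatrix(model, ss, perWalker = perWalker)$B
  nSteps <- ceiling(tMax / dt)
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(m * nSteps), nrow = m)
  full <- .emRun(L, B, dt, noise, rep(TRUE, m))
  approx <- lapply(retainedSets, function(rs) {
    mask <- seq_len(m) %in% rs
    .emRun(L, B, dt, noise, mask)
  })
  new("TrajectorySet", times = seq(0, by = dt, length.out = nSteps + 1),
      full = full, approximations = approx,
      retainedSets = lapply(retainedSets, as.integer), model = model,
      seed = as.integer(seed), dt = dt)
}

#' Pathwise discrepancy of a shielded approximation
#'
#' Compares the empirical stationary mean square of
#' \eqn{M^\top U = M^\top (Y - X)} (over times after `burnIn`) with the
#' analytic value \eqn{\sum_{k \notin retained} R_k}: suppressing the
#' noise on a set of edges costs exactly the summed importance of the
#' suppressed edges.
#'
#' @param trajectories a [TrajectorySet-class].
#' @param label name of the approximation to assess.
#' @param burnIn time discarded before averaging; must leave a
#'   non-degenerate window.
#' @return a [DiscrepancyResult-class].
#' @export
discrepancy <- function(trajectories, label, burnIn) {
  ts <- trajectories
  if (!label %in% names(ts@approximations))
    stop("no approximation labelled '", label, "'")
  keep <- ts@times >= burnIn
  if (sum(keep) < 10L) stop("degenerate averaging window after burn-in")
  M <- measurement(ts@model)
  U <- (ts@approximations[[label]] - ts@full) %*% M
  mse <- mean(U[keep]^2)
  ei <- edgeImportance(ts@model)
  suppressed <- setdiff(seq_len(nEdges(ts@model)), ts@retainedSets[[label]])
  theo <- sum(ei@perEdge[suppressed])
  new("DiscrepancyResult", label = label, mse = mse, theoretical = theo,
      ratio = if (theo > 0) mse / theo else NaN, burnIn = burnIn)
}

#' Welch-averaged empirical power spectral density
#'
#' Estimates the two-sided power spectral density of the observable
#' \eqn{M^\top X(t)} (angular-frequency convention: the integral of the
#' density over \eqn{(-\infty, \infty)} equals the variance) from a
#' simulated path, by averaging Hann-windowed periodograms over
#' overlapping segments.
#'
#' @param trajectories a [TrajectorySet-class].
#' @param label approximation name, or `"full"` for the full process.
#' @param burnIn time discarded.
#' @param segmentLength samples per segment (power of two recommended).
#' @param overlap fractional overlap between segments.
#' @return data.frame with columns `omega` and `spec`.
#' @export
empiricalPsd <- function(trajectories, label = "full", burnIn = 0,
                         segmentLength = 2^12, overlap = 0.5) {
  ts <- trajectories
  path <- if (identical(label, "full")) ts@full
          else if (label %in% names(ts@approximations))
            ts@approximations[[label]]
          else stop("no approximation labelled '", label, "'")
  y <- as.numeric(path %*% measurement(ts@model))
  y <- y[ts@times >= burnIn]
  if (length(y) < 2 * segmentLength)
    stop("series too short after burn-in: need at least two segments")
  y <- y - mean(y)
  dt <- ts@dt
  win <- 0.5 * (1 - cos(2 * pi * seq_len(segmentLength) / (segmentLength + 1)))
  wpow <- mean(win^2)
  step <- max(1L, floor(segmentLength * (1 - overlap)))
  starts <- seq(1L, length(y) - segmentLength + 1L, by = step)
  acc <- numeric(segmentLength)
  for (s in starts) {
    seg <- y[s:(s + segmentLength - 1L)] * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  P <- acc / length(starts) * dt / (2 * pi * segmentLength * wpow)
  half <- 2:(segmentLength %/% 2)     # drop DC, keep up to Nyquist
  data.frame(omega = 2 * pi * (half - 1) / (segmentLength * dt),
             spec = P[half])
}
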