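test_that("SSA conserves walkers and fires only existing edges", {
  m <- nachrModel(1, nWalkers = 25L)
  jt <- ssaSimulate(m, tMax = 50, seed = 2)
  expect_true(all(rowSums(jt@statesAfterEvent) == 25L))
  expect_true(all(jt@statesAfterEvent >= 0L))
  expect_true(all(diff(jt@eventTimes) > 0))
  expect_true(all(jt@edgeIndices %in% 1:10))
  # each event moves exactly one walker along the fired edge
  e <- edgeTable(m)
  prev <- rbind(jt@initialState,
                jt@statesAfterEvent[-nrow(jt@statesAfterEvent), ])
  d <- jt@statesAfterEvent - prev
  expect_true(all(rowSums(abs(d)) == 2L))
  expect_true(all(d[cbind(seq_along(jt@edgeIndices),
                          e$to[jt@edgeIndices])] == 1L))
  # reproducibility
  jt2 <- ssaSimulate(m, tMax = 50, seed = 2)
  expect_identical(jt@eventTimes, jt2@eventTimes)
  expect_error(ssaSimulate(m, tMax = -1, seed = 1), "positive")
})

test_that("SSA dwell times in state 2 are exponential with the out-rate sum", {
  jt <- ssaSimulate(unitChain(), tMax = 2e4, seed = 9)
  state <- c(1L, apply(jt@statesAfterEvent, 1, which.max))
  times <- c(0, jt@eventTimes)
  in2 <- which(state[-length(state)] == 2L)
  dwell <- diff(times)[in2]
  expect_gt(length(dwell), 5e3)
  # mean dwell 1/2, SE = mean/sqrt(n)
  expect_lt(abs(mean(dwell) - 0.5), 3 * 0.5 / sqrt(length(dwell)))
})

test_that("SSA long-run occupancy and observable variance match theory", {
  m <- threeStateChain(1, 1, 1, 1, nWalkers = 500L)
  st <- ssaObservableStats(m, tMax = 1e4, seed = 21, burnIn = 50,
                           nBatch = 100L)
  seMean <- stats::sd(st$batchMeanY) / sqrt(length(st$batchMeanY))
  expect_lt(abs(st$mean - 500 / 3), 3 * seMean)
  expect_lt(abs(st$variance - 500 * 2 / 9), 3 * st$varianceSE)

  # single receptor at low concentration: open-time fraction = pi1 + pi2
  mr <- nachrModel(0.5)
  pi <- stationarySummary(mr)@pi
  str <- ssaObservableStats(mr, tMax = 4e4, seed = 4, burnIn = 200,
                            nBatch = 50L)
  seMean <- stats::sd(str$batchMeanY) / sqrt(50)
  expect_lt(abs(str$mean - (pi[1] + pi[2])), 3 * seMean)
  # burstiness: closed intervals mix fast and slow timescales
  jt <- ssaSimulate(mr, initial = c(0L, 1L, 0L, 0L, 0L), tMax = 4e3,
                    seed = 4)
  open <- rowSums(jt@statesAfterEvent[, 1:2]) > 0
  closedRuns <- rle(open)
  expect_gt(length(closedRuns$lengths), 20)
})

test_that("Langevin paths share common noise and reproduce bit-identically", {
  m <- unitChain()
  ts1 <- langevinSimulate(m, tMax = 50, dt = 0.01, seed = 33,
                          retainedSets = list(all = 1:4, obs = c(3, 4),
                                              none = integer(0)))
  ts2 <- langevinSimulate(m, tMax = 50, dt = 0.01, seed = 33,
                          retainedSets = list(all = 1:4))
  expect_identical(ts1@full, ts2@full)
  expect_identical(ts1@approximations$all, ts2@approximations$all)
  # retaining every edge reproduces the full path exactly
  expect_identical(ts1@approximations$all, ts1@full)
  # empty retained set: noise-free relaxation from 0 stays at 0
  expect_true(all(ts1@approximations$none == 0))
  expect_equal(ts1@full[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_warning(langevinSimulate(m, tMax = 1, dt = 0.1, seed = 1),
                 "unstable")
})

test_that("Langevin stationary variance matches the analytic decomposition", {
  m <- unitChain()
  Rk <- perEdgeImportance(edgeImportance(m))
  ts <- langevinSimulate(m, tMax = 4000, dt = 0.01, seed = 8,
                         retainedSets = list(obs = c(3, 4)))
  keep <- ts@times >= 10
  y <- (ts@full %*% measurement(m))[keep]
  # batch-mean standard error (40 batches)
  bm <- tapply((y - mean(y))^2, rep(1:40, each = ceiling(length(y) / 40), length.out = length(y)), mean)
  se <- stats::sd(bm) / sqrt(40)
  expect_lt(abs(mean((y - mean(y))^2) - sum(Rk)), 3 * se)
  # retaining the observable pair keeps ~7/8 of the variance
  yo <- (ts@approximations$obs %*% measurement(m))[keep]
  expect_lt(abs(var(yo) - sum(Rk[3:4])) / sum(Rk[3:4]), 0.15)
  # pathwise discrepancy equals the suppressed importance
  d <- discrepancy(ts, "obs", burnIn = 10)
  expect_equal(d@theoretical, sum(Rk[1:2]), tolerance = 1e-10)
  expect_lt(abs(d@ratio - 1), 0.2)
  # suppressing nothing costs nothing
  tsAll <- langevinSimulate(m, tMax = 20, dt = 0.01, seed = 8,
                            retainedSets = list(all = 1:4))
  expect_equal(discrepancy(tsAll, "all", burnIn = 5)@mse, 0)
  expect_error(discrepancy(ts, "obs", burnIn = 4000), "degenerate")
  expect_error(discrepancy(ts, "nope", burnIn = 10), "no approximation")
})

test_that("halving dt leaves the variance estimate within one SE", {
  m <- unitChain()
  M <- measurement(m)
  est <- function(dt) {
    ts <- langevinSimulate(m, tMax = 2000, dt = dt, seed = 14)
    y <- (ts@full %*% M)[ts@times >= 10]
    bm <- tapply((y - mean(y))^2, rep(1:20, each = ceiling(length(y) / 20), length.out = length(y)), mean)
    c(mean((y - mean(y))^2), stats::sd(bm) / sqrt(20))
  }
  e1 <- est(0.02)
  e2 <- est(0.01)
  expect_lt(abs(e1[1] - e2[1]), max(e1[2], e2[2]))
})

test_that("receptor at low concentration is best served by the hidden pair", {
  m <- nachrModel(0.5)
  pairs <- list(p34 = c(5L, 6L), p23 = c(3L, 4L), p45 = c(9L, 10L))
  ts <- langevinSimulate(m, tMax = 1500, dt = 0.005, seed = 12,
                         retainedSets = pairs)
  mses <- vapply(names(pairs), function(nm)
    discrepancy(ts, nm, burnIn = 100)@mse, numeric(1))
  expect_equal(names(which.min(mses)), "p34")
  # and the analytic ranking agrees
  Rk <- perEdgeImportance(edgeImportance(m))
  theo <- vapply(pairs, function(p) sum(Rk[-p]), numeric(1))
  expect_equal(names(which.min(theo)), "p34")
})

test_that("Welch periodogram agrees with the analytic spectrum in band averages", {
  m <- unitChain()
  ts <- langevinSimulate(m, tMax = 6000, dt = 0.01, seed = 19,
                         retainedSets = list(none = integer(0)))
  ep <- empiricalPsd(ts, "full", burnIn = 20, segmentLength = 2^13)
  # octave-band averages over the resolved mid band
  bands <- list(c(0.2, 0.4), c(0.4, 0.8), c(0.8, 1.6), c(1.6, 3.2))
  for (b in bands) {
    sel <- ep$omega >= b[1] & ep$omega < b[2]
    emp <- mean(ep$spec[sel])
    ana <- mean(psd(m, ep$omega[sel])$total)
    expect_gt(emp / ana, 0.5)
    expect_lt(emp / ana, 1.5)
  }
  # a noise-free path has zero spectrum
  epn <- empiricalPsd(ts, "none", burnIn = 20, segmentLength = 2^13)
  expect_true(all(epn$spec == 0))
  expect_error(empiricalPsd(ts, "full", burnIn = 5990), "too short")
})
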