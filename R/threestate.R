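#' Rate quadruple of a 3-state chain
#'
#' Convenience constructor for [ThreeStateRates-class], the rates
#' \eqn{(\alpha_{12}, \alpha_{21}, \alpha_{23}, \alpha_{32})} of the chain
#' 1 - 2 - 3.
#'
#' @param a12,a21,a23,a32 positive rates.
#' @param observableState 2 or 3 (default 3: end state conducting).
#' @return a [ThreeStateRates-class].
#' @export
threeStateRates <- function(a12, a21, a23, a32, observableState = 3L) {
  obj <- new("ThreeStateRates", a12 = as.numeric(a12), a21 = as.numeric(a21),
             a23 = as.numeric(a23), a32 = as.numeric(a32),
             observableState = as.integer(observableState))
  validObject(obj)
  obj
}

# vectorized closed forms for the 3-state chain with state 3 observable.
# Z = a12 a23 + a12 a32 + a21 a32; pi = (a21 a32, a12 a32, a12 a23)/Z;
# eigenvalues are the roots of lambda^2 + (sum alpha) lambda + Z.
.threeStateDiagnostics <- function(a12, a21, a23, a32) {
  Z <- a12 * a23 + a12 * a32 + a21 * a32
  pi1 <- a21 * a32 / Z
  pi2 <- a12 * a32 / Z
  pi3 <- a12 * a23 / Z
  tr <- a12 + a21 + a23 + a32
  disc <- sqrt(pmax(tr^2 - 4 * Z, 0))
  lam2 <- (-tr + disc) / 2
  lam3 <- (-tr - disc) / 2
  F1 <- a21 / (a12 + a21)
  F2 <- a23 / tr
  eta <- F1 * F2
  tau12 <- 1 / (a12 + a21)
  tau23 <- 1 / (a23 + a32)
  deltaJ <- (a21 - a23) / (a21 + a23)
  data.frame(
    a12 = a12, a21 = a21, a23 = a23, a32 = a32,
    eta = eta, F1 = F1, F2 = F2,
    nu = lam3 / lam2, lambda2 = lam2, lambda3 = lam3,
    tau12 = tau12, tau23 = tau23, deltaJ = deltaJ,
    pi1 = pi1, pi2 = pi2, pi3 = pi3,
    boundOccupancy = ((1 - pi2) / (1 + pi2))^2,
    boundRateRatio = a23 / (a23 + a32),
    boundRelaxation = tau12 / (tau12 + tau23),
    boundFlux = 0.5 - deltaJ / 2,
    inverted = eta > 0.5
  )
}

#' Closed-form hidden-edge importance fraction for a 3-state chain
#'
#' Evaluates the exact expression
#' \deqn{\eta = \frac{R_{12}}{R_{12} + R_{23}}
#'   = \frac{\alpha_{21}}{\alpha_{12} + \alpha_{21}} \cdot
#'     \frac{\alpha_{23}}{\alpha_{12}+\alpha_{21}+\alpha_{23}+\alpha_{32}}
#'   = F_1 F_2}
#' for the chain with state 3 observable, together with the reversal
#' diagnostics: eigenvalue ratio \eqn{\nu = \lambda_3/\lambda_2}, local
#' relaxation times \eqn{\tau_{12}, \tau_{23}}, flux asymmetry
#' \eqn{\Delta J = (J_{12}-J_{23})/(J_{12}+J_{23}) =
#' (\alpha_{21}-\alpha_{23})/(\alpha_{21}+\alpha_{23})}, the stationary
#' distribution, the four upper bounds on \eqn{\eta} (see [etaBounds()]),
#' and the inversion flag \eqn{\eta > 1/2}.
#'
#' @param rates a [ThreeStateRates-class] with `observableState = 3`.
#' @return a [ReversalDiagnostics-class].
#' @examples
#' etaClosedForm(threeStateRates(1, 1, 10, 0.1))@eta   # 0.4132...
#' @export
etaClosedForm <- function(rates) {
  stopifnot(is(rates, "ThreeStateRates"))
  if (rates@observableState != 3L)
    stop("the closed form is derived for observableState = 3")
  d <- .threeStateDiagnostics(rates@a12, rates@a21, rates@a23, rates@a32)
  new("ReversalDiagnostics",
      eta = d$eta, F1 = d$F1, F2 = d$F2, nu = d$nu,
      tau12 = d$tau12, tau23 = d$tau23, deltaJ = d$deltaJ,
      pi = c(d$pi1, d$pi2, d$pi3),
      bounds = c(occupancy = d$boundOccupancy, rateRatio = d$boundRateRatio,
                 relaxation = d$boundRelaxation, flux = d$boundFlux),
      inverted = d$inverted,
      rates = c(a12 = rates@a12, a21 = rates@a21, a23 = rates@a23,
                a32 = rates@a32))
}

#' Four upper bounds on the hidden-edge fraction
#'
#' The four inequalities satisfied by \eqn{\eta} for any positive rates:
#' \itemize{
#'   \item occupancy: \eqn{\eta \le ((1-\pi_2)/(1+\pi_2))^2}
#'   \item rate ratio: \eqn{\eta \le \alpha_{23}/(\alpha_{23}+\alpha_{32})}
#'   \item relaxation: \eqn{\eta \le \tau_{12}/(\tau_{12}+\tau_{23})}
#'   \item flux: \eqn{\eta \le 1/2 - \Delta J/2}
#' }
#' Each implies a necessary condition for inversion (\eqn{\eta > 1/2}).
#'
#' @param rates a [ThreeStateRates-class].
#' @return named numeric vector of the four bounds.
#' @export
etaBounds <- function(rates) {
  stopifnot(is(rates, "ThreeStateRates"))
  d <- .threeStateDiagnostics(rates@a12, rates@a21, rates@a23, rates@a32)
  c(occupancy = d$boundOccupancy, rateRatio = d$boundRateRatio,
    relaxation = d$boundRelaxation, flux = d$boundFlux)
}

#' Canonical transformation driving edge-importance reversal
#'
#' Rescales a rate quadruple by \eqn{\alpha_{12} \to \epsilon \alpha_{12}}
#' (decelerate the hidden exit 1 to 2) and \eqn{\alpha_{23} \to
#' \alpha_{23}/\epsilon} (accelerate the opening 2 to 3), leaving
#' \eqn{\alpha_{21}} and \eqn{\alpha_{32}} unchanged. As
#' \eqn{\epsilon \to 0} the hidden-edge fraction \eqn{\eta} of the
#' transformed chain increases to 1, so any chain can be driven to
#' reversal.
#'
#' @param rates a [ThreeStateRates-class].
#' @param eps positive scale factor; `eps = 1` is the identity.
#' @return the transformed [ThreeStateRates-class].
#' @export
canonicalTransform <- function(rates, eps) {
  stopifnot(is(rates, "ThreeStateRates"))
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("eps must be a positive number")
  threeStateRates(eps * rates@a12, rates@a21, rates@a23 / eps, rates@a32,
                  observableState = rates@observableState)
}

#' Inversion threshold on the one-parameter beta slice
#'
#' On the slice \eqn{\alpha = (1/\beta, 1, \beta, 1)} the closed form
#' reduces to \eqn{\eta(\beta) = (\beta/(1+\beta))^3}, strictly increasing
#' in \eqn{\beta}. The function locates the crossing \eqn{\eta(\beta)=1/2}
#' by bisection on the bracket [1, 100]; the analytic root is
#' \eqn{2^{-1/3}/(1 - 2^{-1/3}) \approx 3.8473}.
#'
#' @param resolution bisection tolerance on beta (default 1e-9).
#' @return the crossing value of beta.
#' @export
betaInversionThreshold <- function(resolution = 1e-9) {
  stopifnot(resolution > 0)
  f <- function(b) etaClosedForm(threeStateRates(1 / b, 1, b, 1))@eta - 0.5
  lo <- 1; hi <- 100
  stopifnot(f(lo) < 0, f(hi) > 0)
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
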