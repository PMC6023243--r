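#include <Rcpp.h>
using namespace Rcpp;

// Gillespie SSA for a first-order transition network.
// Propensity of edge k is rate[k] * N[from[k]]; waiting times are
// exponential in the total propensity, the firing edge is chosen
// proportionally. Indices are 0-based on entry. Records every event.
// [[Rcpp::export(name = ".ssaRun")]]
List ssaRun(NumericVector rate, IntegerVector from, IntegerVector to,
            IntegerVector init, double tMax, double maxEvents) {
  const int m = rate.size();
  const int n = init.size();
  std::vector<int> N(init.begin(), init.end());
  std::vector<double> times;
  std::vector<int> edges;
  std::vector<int> states;
  double t = 0.0;
  RNGScope scope;
  while (true) {
    double a0 = 0.0;
    for (int k = 0; k < m; ++k) a0 += rate[k] * N[from[k]];
    if (a0 <= 0.0) stop("all propensities zero: absorbing population state");
    t += R::rexp(1.0 / a0);
    if (t > tMax) break;
    double u = R::runif(0.0, a0);
    int k = 0;
    double acc = rate[0] * N[from[0]];
    while (u > acc && k < m - 1) { ++k; acc += rate[k] * N[from[k]]; }
    N[from[k]] -= 1;
    N[to[k]] += 1;
    times.push_back(t);
    edges.push_back(k + 1);
    for (int i = 0; i < n; ++i) states.push_back(N[i]);
    if ((double)times.size() >= maxEvents)
      stop("event budget exceeded (maxEvents)");
  }
  IntegerMatrix S(times.size(), n);
  for (size_t r = 0; r < times.size(); ++r)
    for (int i = 0; i < n; ++i) S(r, i) = states[r * n + i];
  return List::create(_["times"] = wrap(times), _["edges"] = wrap(edges),
                      _["states"] = S);
}

// SSA long-run statistics of y = M^T N without storing the path:
// time-weighted batch means of y and y^2 over [burnIn, tMax], split into
// nBatch equal-time batches.
// [[Rcpp::export(name = ".ssaStats")]]
List ssaStats(NumericVector rate, IntegerVector from, IntegerVector to,
              IntegerVector init, NumericVector M, double tMax,
              double burnIn, int nBatch) {
  const int m = rate.size();
  const int n = init.size();
  std::vector<int> N(init.begin(), init.end());
  double y = 0.0;
  for (int i = 0; i < n; ++i) y += M[i] * N[i];
  const double span = (tMax - burnIn) / nBatch;
  NumericVector s1(nBatch), s2(nBatch);
  double t = 0.0;
  RNGScope scope;
  while (t < tMax) {
    double a0 = 0.0;
    for (int k = 0; k < m; ++k) a0 += rate[k] * N[from[k]];
    if (a0 <= 0.0) stop("all propensities zero: absorbing population state");
    double dt = R::rexp(1.0 / a0);
    double t2 = std::min(t + dt, tMax);
    // accumulate the dwell [t, t2) into the overlapped batches
    if (t2 > burnIn) {
      double a = std::max(t, burnIn);
      while (a < t2) {
        int b = std::min((int)((a - burnIn) / span), nBatch - 1);
        double bEnd = burnIn + (b + 1) * span;
        double seg = std::min(t2, bEnd) - a;
        s1[b] += seg * y;
        s2[b] += seg * y * y;
        a += seg;
      }
    }
    t += dt;
    if (t > tMax) break;
    double u = R::runif(0.0, a0);
    int k = 0;
    double acc = rate[0] * N[from[0]];
    while (u > acc && k < m - 1) { ++k; acc += rate[k] * N[from[k]]; }
    N[from[k]] -= 1;
    N[to[k]] += 1;
    y = 0.0;
    for (int i = 0; i < n; ++i) y += M[i] * N[i];
  }
  return List::create(_["batchMeanY"] = s1 / span,
                      _["batchMeanY2"] = s2 / span);
}

// Euler-Maruyama for dX = L X dt + B dW on the centered fluctuation
// process. noise is the m x nSteps matrix of N(0,1) draws (shared across
// retained sets); retain masks edges whose noise is kept. Returns the
// (nSteps+1) x n path starting from zero.
// [[Rcpp::export(name = ".emRun")]]
NumericMatrix emRun(NumericMatrix L, NumericMatrix B, double dt,
                    NumericMatrix noise, LogicalVector retain) {
  const int n = L.nrow();
  const int m = B.ncol();
  const int nSteps = noise.ncol();
  const double sdt = std::sqrt(dt);
  NumericMatrix X(nSteps + 1, n);
  std::vector<double> x(n, 0.0), dx(n);
  for (int s = 0; s < nSteps; ++s) {
    for (int i = 0; i < n; ++i) {
      double drift = 0.0;
      for (int j = 0; j < n; ++j) drift += L(i, j) * x[j];
      dx[i] = drift * dt;
    }
    for (int k = 0; k < m; ++k) {
      if (!retain[k]) continue;
      double w = noise(k, s) * sdt;
      for (int i = 0; i < n; ++i) dx[i] += B(i, k) * w;
    }
    for (int i = 0; i < n; ++i) {
      x[i] += dx[i];
      X(s + 1, i) = x[i];
    }
  }
  return X;
}
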