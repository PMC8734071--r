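#include <Rcpp.h>
using namespace Rcpp;

// Relative emission products across states for every row of a binary
// observation matrix, stabilized by per-feature renormalization: after each
// feature is multiplied in, all state products are divided by their maximum,
// so no product can underflow to zero even with thousands of features.
// Returns the T x S matrix of relative products (row maximum = 1) and the
// per-row accumulated log of the removed normalizers, so that the true joint
// emission probability is B[t,s] * exp(logScale[t]). Observation code 2
// marks a missing call and is skipped.
// [[Rcpp::export(name = ".cs_emission_products")]]
List cs_emission_products(NumericMatrix emissions, IntegerMatrix obs) {
  const int S = emissions.nrow();
  const int D = emissions.ncol();
  const int T = obs.nrow();
  if (obs.ncol() != D)
    stop("observation matrix has %d columns but the model has %d features",
         obs.ncol(), D);
  NumericMatrix B(T, S);
  NumericVector logScale(T);
  std::vector<double> r(S);
  for (int t = 0; t < T; ++t) {
    std::fill(r.begin(), r.end(), 1.0);
    double ls = 0.0;
    for (int d = 0; d < D; ++d) {
      const int o = obs(t, d);
      if (o == 2) continue;
      if (o != 0 && o != 1)
        stop("invalid observation code %d at row %d, column %d", o, t + 1, d + 1);
      double mx = 0.0;
      for (int s = 0; s < S; ++s) {
        const double e = emissions(s, d);
        r[s] *= (o == 1) ? e : (1.0 - e);
        if (r[s] > mx) mx = r[s];
      }
      if (mx <= 0.0)
        stop("all states have zero emission probability at row %d, feature %d",
             t + 1, d + 1);
      for (int s = 0; s < S; ++s) r[s] /= mx;
      ls += std::log(mx);
    }
    for (int s = 0; s < S; ++s) B(t, s) = r[s];
    logScale[t] = ls;
  }
  return List::create(_["B"] = B, _["logScale"] = logScale);
}

// Scaled forward-backward over one observation chunk, treated as an
// independent sequence started from the initial distribution. Returns state
// posteriors, the exact log-likelihood (forward scaling constants plus the
// emission-product normalizers), and the expected sufficient statistics
// needed by the Baum-Welch M-step.
// [[Rcpp::export(name = ".cs_forward_backward")]]
List cs_forward_backward(NumericVector init, NumericMatrix trans,
                         NumericMatrix emissions, IntegerMatrix obs) {
  const int S = init.size();
  const int D = emissions.ncol();
  const int T = obs.nrow();
  if (trans.nrow() != S || trans.ncol() != S || emissions.nrow() != S)
    stop("parameter dimensions disagree");
  if (T < 1) stop("empty observation chunk");

  List ep = cs_emission_products(emissions, obs);
  NumericMatrix B = ep["B"];
  NumericVector logScale = ep["logScale"];

  NumericMatrix alpha(T, S), beta(T, S);
  NumericVector c(T);

  double c0 = 0.0;
  for (int s = 0; s < S; ++s) { alpha(0, s) = init[s] * B(0, s); c0 += alpha(0, s); }
  if (!(c0 > 0.0)) stop("non-finite forward pass at position 1");
  for (int s = 0; s < S; ++s) alpha(0, s) /= c0;
  c[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < S; ++j) {
      double a = 0.0;
      for (int i = 0; i < S; ++i) a += alpha(t - 1, i) * trans(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      ct += a;
    }
    if (!(ct > 0.0) || !std::isfinite(ct))
      stop("non-finite forward pass at position %d", t + 1);
    for (int j = 0; j < S; ++j) alpha(t, j) /= ct;
    c[t] = ct;
  }

  for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < S; ++i) {
      double b = 0.0;
      for (int j = 0; j < S; ++j)
        b += trans(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  NumericMatrix gamma(T, S);
  for (int t = 0; t < T; ++t) {
    double rs = 0.0;
    for (int s = 0; s < S; ++s) { gamma(t, s) = alpha(t, s) * beta(t, s); rs += gamma(t, s); }
    for (int s = 0; s < S; ++s) gamma(t, s) /= rs;
  }

  NumericMatrix transCounts(S, S);
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < S; ++i) {
      const double ai = alpha(t, i);
      if (ai == 0.0) continue;
      for (int j = 0; j < S; ++j)
        transCounts(i, j) +=
          ai * trans(i, j) * B(t + 1, j) * beta(t + 1, j) / c[t + 1];
    }
  }

  NumericVector initCounts(S);
  for (int s = 0; s < S; ++s) initCounts[s] = gamma(0, s);

  NumericMatrix presentCounts(S, D), absentCounts(S, D);
  for (int t = 0; t < T; ++t) {
    for (int d = 0; d < D; ++d) {
      const int o = obs(t, d);
      if (o == 2) continue;
      NumericMatrix& tgt = (o == 1) ? presentCounts : absentCounts;
      for (int s = 0; s < S; ++s) tgt(s, d) += gamma(t, s);
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + logScale[t];

  return List::create(_["gamma"] = gamma, _["logLik"] = ll,
                      _["transCounts"] = transCounts,
                      _["initCounts"] = initCounts,
                      _["presentCounts"] = presentCounts,
                      _["absentCounts"] = absentCounts);
}

// Log-likelihood only (forward pass), for model evaluation without the
// backward-pass cost.
// [[Rcpp::export(name = ".cs_log_likelihood")]]
double cs_log_likelihood(NumericVector init, NumericMatrix trans,
                         NumericMatrix emissions, IntegerMatrix obs) {
  const int S = init.size();
  const int T = obs.nrow();
  List ep = cs_emission_products(emissions, obs);
  NumericMatrix B = ep["B"];
  NumericVector logScale = ep["logScale"];
  std::vector<double> a(S), a2(S);
  double ll = 0.0;
  double c0 = 0.0;
  for (int s = 0; s < S; ++s) { a[s] = init[s] * B(0, s); c0 += a[s]; }
  for (int s = 0; s < S; ++s) a[s] /= c0;
  ll += std::log(c0) + logScale[0];
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < S; ++j) {
      double v = 0.0;
      for (int i = 0; i < S; ++i) v += a[i] * trans(i, j);
      v *= B(t, j);
      a2[j] = v;
      ct += v;
    }
    if (!(ct > 0.0)) stop("non-finite forward pass at position %d", t + 1);
    for (int j = 0; j < S; ++j) a[j] = a2[j] / ct;
    ll += std::log(ct) + logScale[t];
  }
  return ll;
}

// Sample a state path of length T from (init, trans) using R's RNG stream,
// so set.seed() makes the draw reproducible.
// [[Rcpp::export(name = ".cs_simulate_path")]]
IntegerVector cs_simulate_path(NumericVector init, NumericMatrix trans, int T) {
  const int S = init.size();
  IntegerVector path(T);
  double u = R::runif(0.0, 1.0), acc = 0.0;
  int st = S - 1;
  for (int s = 0; s < S; ++s) { acc += init[s]; if (u <= acc) { st = s; break; } }
  path[0] = st;
  for (int t = 1; t < T; ++t) {
    u = R::runif(0.0, 1.0);
    acc = 0.0;
    int nx = S - 1;
    for (int s = 0; s < S; ++s) { acc += trans(st, s); if (u <= acc) { nx = s; break; } }
    st = nx;
    path[t] = st;
  }
  return path + 1;
}
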