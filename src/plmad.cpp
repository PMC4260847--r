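#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Recursive-least-squares noise canceller.
//
// d:    primary input (leg EMG with interference), length n
// ref:  reference input (ECG channel, or an advanced copy of d)
// m:    number of filter taps
// lambda: forgetting factor in (0, 1]
// delta:  initial value of the diagonal inverse-correlation matrix P
// warmup: samples copied through unchanged before adaptation starts
//
// Returns the error sequence e(t) = d(t) - w'u(t): the primary input with
// the reference-predictable component removed. Deterministic.
// [[Rcpp::export]]
NumericVector rls_core(NumericVector d, NumericVector ref, int m,
                       double lambda, double delta, int warmup) {
  const int n = d.size();
  if (ref.size() != n) stop("rls_core: length mismatch");
  if (m < 1) stop("rls_core: need at least one tap");
  NumericVector out(n);
  std::vector<double> w(m, 0.0), P(m * m, 0.0), u(m), Pu(m);
  for (int i = 0; i < m; ++i) P[i * m + i] = delta;
  int t0 = warmup > (m - 1) ? warmup : (m - 1);
  for (int t = 0; t < n && t < t0; ++t) out[t] = d[t];
  for (int t = t0; t < n; ++t) {
    for (int j = 0; j < m; ++j) u[j] = ref[t - j];
    double uPu = 0.0;
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int j = 0; j < m; ++j) s += P[i * m + j] * u[j];
      Pu[i] = s;
      uPu += s * u[i];
    }
    double denom = lambda + uPu;
    double yhat = 0.0;
    for (int j = 0; j < m; ++j) yhat += w[j] * u[j];
    double e = d[t] - yhat;
    out[t] = e;
    for (int j = 0; j < m; ++j) w[j] += (Pu[j] / denom) * e;
    // P <- (P - k u'P) / lambda, with k = Pu/denom and u'P = Pu' (P symm.)
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j)
        P[i * m + j] = (P[i * m + j] - Pu[i] * Pu[j] / denom) / lambda;
  }
  return out;
}

// Three-threshold candidate state machine.
//
// Onset: first sample with y > alpha while the detector is enabled.
// Close: y stays strictly below beta for `fall` consecutive samples; the
// candidate's offset is one past the last sample with y >= psi seen before
// that run. A candidate still open at a shutoff sample or at end of signal
// is closed at last psi-sample + 1 and flagged.
//
// Returns a matrix with 0-based columns: onset, offset_exclusive, flag
// (0 = closed normally, 1 = closed by end of signal, 2 = closed by shutoff).
// [[Rcpp::export]]
IntegerMatrix detect_candidates_core(NumericVector y, NumericVector alpha,
                                     NumericVector beta, NumericVector psi,
                                     LogicalVector enabled, int fall) {
  const int n = y.size();
  if (alpha.size() != n || beta.size() != n || psi.size() != n ||
      enabled.size() != n)
    stop("detect_candidates_core: length mismatch");
  if (fall < 1) stop("detect_candidates_core: fall must be >= 1");
  std::vector<int> v_on, v_off, v_flag;
  bool active = false;
  int onset = -1, last_psi = -1, below = 0;
  for (int t = 0; t < n; ++t) {
    if (!active) {
      if (enabled[t] && y[t] > alpha[t]) {
        active = true; onset = t; last_psi = t; below = 0;
      }
    } else {
      if (!enabled[t]) {
        v_on.push_back(onset); v_off.push_back(last_psi + 1);
        v_flag.push_back(2);
        active = false;
        continue;
      }
      if (y[t] >= psi[t]) last_psi = t;
      if (y[t] < beta[t]) {
        if (++below >= fall) {
          v_on.push_back(onset); v_off.push_back(last_psi + 1);
          v_flag.push_back(0);
          active = false; below = 0;
        }
      } else {
        below = 0;
      }
    }
  }
  if (active) {
    v_on.push_back(onset); v_off.push_back(last_psi + 1); v_flag.push_back(1);
  }
  IntegerMatrix out(v_on.size(), 3);
  for (int i = 0; i < (int)v_on.size(); ++i) {
    out(i, 0) = v_on[i]; out(i, 1) = v_off[i]; out(i, 2) = v_flag[i];
  }
  colnames(out) = CharacterVector::create("onset", "offset", "flag");
  return out;
}
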