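#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Kalman filter for a zero-mean ARMA(p,q) in Harvey's state-space form,
// run at sigma2 = 1 so the innovation variance can be profiled out.
//
// State: alpha_t = T alpha_{t-1} + R eps_t, y_t = alpha_t[0],
// r = max(p, q + 1); T has phi in its first column and an identity
// super-diagonal; R = (1, theta_1, ..., theta_{r-1})'.
//
// Throughout the loop (a, P) are the one-step *prediction* mean and
// covariance for time t.  The transition structure is exploited
// directly (no dense matrix products), and once the prediction
// covariance converges on a gap-free stretch the filter switches to the
// steady-state recursion, O(r) per step.  Missing observations (NA)
// skip the update, which yields the exact marginal likelihood of the
// observed coordinates; a gap ends the steady state and restarts the
// covariance recursion.
//
// Returns sum(log F_t), ssq = sum(v_t^2 / F_t), the observation count,
// and per-time innovations v_t / variance factors F_t (NA at gaps).
// P0 is the stationary state covariance at sigma2 = 1 (Lyapunov solve
// done in R).
// Stationary state covariance at sigma2 = 1: solve the discrete
// Lyapunov equation P = T P T' + R R' through the Kronecker identity
// (I - T (x) T) vec(P) = vec(R R'), by Gaussian elimination with
// partial pivoting.  The system is r^2 x r^2 with r <= max(p, q + 1),
// tiny for any sane ARMA order.
static bool stationary_P0(const std::vector<double>& ph,
                          const std::vector<double>& Rv, int r,
                          std::vector<double>& P) {
  const int m = r * r;
  // T in row-major: T[i][0] = ph[i], T[i][i+1] = 1
  std::vector<double> T(m, 0.0);
  for (int i = 0; i < r; ++i) T[i * r + 0] = ph[i];
  for (int i = 0; i + 1 < r; ++i) T[i * r + i + 1] = 1.0;

  std::vector<double> A(m * m), b(m);
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < r; ++j) {
      const int row = i * r + j;
      b[row] = Rv[i] * Rv[j];
      for (int k = 0; k < r; ++k)
        for (int l = 0; l < r; ++l) {
          const int col = k * r + l;
          A[row * m + col] = (row == col ? 1.0 : 0.0) -
                             T[i * r + k] * T[j * r + l];
        }
    }
  // Gaussian elimination with partial pivoting
  for (int c = 0; c < m; ++c) {
    int piv = c;
    for (int rr = c + 1; rr < m; ++rr)
      if (std::fabs(A[rr * m + c]) > std::fabs(A[piv * m + c])) piv = rr;
    if (std::fabs(A[piv * m + c]) < 1e-300) return false;
    if (piv != c) {
      for (int cc = c; cc < m; ++cc) std::swap(A[c * m + cc], A[piv * m + cc]);
      std::swap(b[c], b[piv]);
    }
    const double d = A[c * m + c];
    for (int rr = c + 1; rr < m; ++rr) {
      const double f = A[rr * m + c] / d;
      if (f == 0.0) continue;
      for (int cc = c; cc < m; ++cc) A[rr * m + cc] -= f * A[c * m + cc];
      b[rr] -= f * b[c];
    }
  }
  for (int c = m - 1; c >= 0; --c) {
    double s = b[c];
    for (int cc = c + 1; cc < m; ++cc) s -= A[c * m + cc] * b[cc];
    b[c] = s / A[c * m + c];
  }
  P = b;
  return true;
}

// [[Rcpp::export(name = ".arma_kf_filter")]]
List arma_kf_filter(NumericVector y, NumericVector phi, NumericVector theta,
                    bool want_innov = false) {
  const int n = y.size();
  const int p = phi.size(), q = theta.size();
  const int r = std::max(p, q + 1);

  std::vector<double> ph(r, 0.0), Rv(r, 0.0);
  for (int i = 0; i < p; ++i) ph[i] = phi[i];
  Rv[0] = 1.0;
  for (int j = 0; j < q; ++j) Rv[j + 1] = theta[j];

  std::vector<double> a(r, 0.0), anew(r), K(r), M(r);
  std::vector<double> P(r * r), TP(r * r);  // row-major
  if (!stationary_P0(ph, Rv, r, P))
    return List::create(_["sumlogF"] = NA_REAL, _["ssq"] = NA_REAL,
                        _["nobs"] = 0, _["ok"] = false,
                        _["v"] = NumericVector(n, NA_REAL),
                        _["F"] = NumericVector(n, NA_REAL));

  double sumlogF = 0.0, ssq = 0.0;
  int nobs = 0;
  bool ok = true;
  bool steady = false;
  double Fss = 1.0;
  std::vector<double> Kss(r);
  long nsteady = 0;          // observed steps spent in the current steady run
  double ssq_steady = 0.0;   // their accumulated v^2 (F is constant = Fss)
  NumericVector v_out(want_innov ? n : 0, NA_REAL),
      F_out(want_innov ? n : 0, NA_REAL);

  for (int t = 0; t < n; ++t) {
    const bool obs = !NumericVector::is_na(y[t]);

    if (steady) {
      if (obs) {
        const double v = y[t] - a[0];
        for (int i = 0; i < r; ++i) a[i] += Kss[i] * v;  // filtered mean
        ssq_steady += v * v;
        ++nsteady;
        ++nobs;
        if (want_innov) { v_out[t] = v; F_out[t] = Fss; }
        // predict mean for t + 1 (P stays at the steady prediction cov)
        const double a0 = a[0];
        for (int i = 0; i < r; ++i)
          anew[i] = ph[i] * a0 + (i + 1 < r ? a[i + 1] : 0.0);
        a = anew;
        continue;
      }
      // gap: no update, so the filtered covariance equals the prediction
      // covariance already held in P; fall through to the full recursion
      steady = false;
      sumlogF += nsteady * std::log(Fss);
      ssq += ssq_steady / Fss;
      nsteady = 0;
      ssq_steady = 0.0;
    }

    // ---- full recursion: update (if observed), then predict ----
    if (obs) {
      const double F = P[0];
      if (!(F > 1e-300) || !std::isfinite(F)) { ok = false; break; }
      const double v = y[t] - a[0];
      for (int i = 0; i < r; ++i) K[i] = P[i * r + 0] / F;
      for (int i = 0; i < r; ++i) M[i] = P[0 * r + i];
      for (int i = 0; i < r; ++i) a[i] += K[i] * v;
      for (int i = 0; i < r; ++i)
        for (int j = 0; j < r; ++j) P[i * r + j] -= K[i] * M[j];
      sumlogF += std::log(F);
      ssq += v * v / F;
      ++nobs;
      if (want_innov) { v_out[t] = v; F_out[t] = F; }
    }

    // mean prediction: a <- T a
    const double a0 = a[0];
    for (int i = 0; i < r; ++i)
      anew[i] = ph[i] * a0 + (i + 1 < r ? a[i + 1] : 0.0);
    a = anew;

    // covariance prediction: P <- T P T' + R R'
    // TP[i][j] = ph[i] P[0][j] + P[i+1][j]
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < r; ++j)
        TP[i * r + j] = ph[i] * P[0 * r + j] +
                        (i + 1 < r ? P[(i + 1) * r + j] : 0.0);
    // Pnew[i][j] = ph[j] TP[i][0] + TP[i][j+1] + R[i] R[j]
    double dP = 0.0;
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < r; ++j) {
        const double val = ph[j] * TP[i * r + 0] +
                           (j + 1 < r ? TP[i * r + j + 1] : 0.0) +
                           Rv[i] * Rv[j];
        dP = std::max(dP, std::fabs(val - P[i * r + j]));
        P[i * r + j] = val;
      }

    // prediction covariance converged across an observed step: freeze
    if (obs && dP < 3e-12 * (1.0 + std::fabs(P[0]))) {
      steady = true;
      Fss = P[0];
      for (int i = 0; i < r; ++i) Kss[i] = P[i * r + 0] / Fss;
    }
  }

  if (nsteady > 0) {  // flush the final steady run
    sumlogF += nsteady * std::log(Fss);
    ssq += ssq_steady / Fss;
  }

  return List::create(_["sumlogF"] = sumlogF, _["ssq"] = ssq,
                      _["nobs"] = nobs, _["ok"] = ok,
                      _["v"] = v_out, _["F"] = F_out);
}

// Conditional sum of squares for a zero-mean ARMA(p,q): innovations by
// direct recursion eps_t = y_t - sum phi_j y_{t-j} - sum theta_l eps_{t-l},
// started after the first p observations.  A term whose lagged value is
// missing is dropped (its innovation is treated as zero and not counted).
// Only used to produce warm starts for the exact-likelihood optimiser.
// [[Rcpp::export(name = ".arma_css")]]
List arma_css(NumericVector y, NumericVector phi, NumericVector theta) {
  const int n = y.size();
  const int p = phi.size(), q = theta.size();
  std::vector<double> eps(n, 0.0);
  double ssq = 0.0;
  int nu = 0;
  for (int t = p; t < n; ++t) {
    if (NumericVector::is_na(y[t])) { eps[t] = 0.0; continue; }
    double e = y[t];
    bool usable = true;
    for (int j = 0; j < p; ++j) {
      if (NumericVector::is_na(y[t - j - 1])) { usable = false; break; }
      e -= phi[j] * y[t - j - 1];
    }
    if (!usable) { eps[t] = 0.0; continue; }
    for (int l = 0; l < q && t - l - 1 >= 0; ++l) e -= theta[l] * eps[t - l - 1];
    eps[t] = e;
    ssq += e * e;
    ++nu;
  }
  return List::create(_["ssq"] = ssq, _["n_used"] = nu);
}

// Simulate a zero-mean ARMA(p,q) path from supplied innovations and a
// stationary initial state draw (both generated in R so all randomness
// flows through R's RNG).
// [[Rcpp::export(name = ".arma_simulate_path")]]
NumericVector arma_simulate_path(NumericVector eps, NumericVector phi,
                                 NumericVector theta, NumericVector a0) {
  const int n = eps.size();
  const int p = phi.size(), q = theta.size();
  const int r = std::max(p, q + 1);

  std::vector<double> ph(r, 0.0), Rv(r, 0.0);
  for (int i = 0; i < p; ++i) ph[i] = phi[i];
  Rv[0] = 1.0;
  for (int j = 0; j < q; ++j) Rv[j + 1] = theta[j];

  std::vector<double> a(r, 0.0), anew(r);
  for (int i = 0; i < r && i < a0.size(); ++i) a[i] = a0[i];

  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    const double a0v = a[0];
    for (int i = 0; i < r; ++i)
      anew[i] = ph[i] * a0v + (i + 1 < r ? a[i + 1] : 0.0) + Rv[i] * eps[t];
    a = anew;
    out[t] = a[0];
  }
  return out;
}
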