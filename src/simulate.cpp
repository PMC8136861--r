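#include <Rcpp.h>
#include "wfpt.h"
#include "rng.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector wfpt_pdf_cpp(NumericVector rt, IntegerVector upper,
                           double v, double a, double w, double ndt,
                           double err) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = wfpt_pdf(rt[i], upper[i % upper.size()], v, a, w, ndt, err);
  return out;
}

// summed log-likelihood over a trial table with per-trial parameters
// [[Rcpp::export]]
List wfpt_loglik_cpp(NumericVector rt, IntegerVector upper,
                     NumericVector v, NumericVector a, NumericVector w,
                     NumericVector ndt, double log_floor, double err) {
  int n = rt.size();
  double ll = 0.0;
  int n_floored = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] <= 0.0 || w[i] <= 0.0 || w[i] >= 1.0 || ndt[i] < 0.0)
      return List::create(_["loglik"] = R_NegInf, _["n_floored"] = n_floored,
                          _["valid"] = false);
    double d = wfpt_pdf(rt[i], upper[i], v[i], a[i], w[i], ndt[i], err);
    double ld = std::log(d);
    if (!(ld > log_floor)) { ld = log_floor; ++n_floored; }
    ll += ld;
  }
  return List::create(_["loglik"] = ll, _["n_floored"] = n_floored,
                      _["valid"] = true);
}

static ZigguratNormal zig;

// single-path Euler-Maruyama first passage; returns decision time (>0) and
// sets *up; returns -1.0 if the cap was hit
static inline double em_path(Xoshiro256& rng, double v, double a, double x0,
                             double dt, double max_t, bool bridge, int* up) {
  double x = x0;
  double sdt = std::sqrt(dt);
  double t = 0.0;
  while (t < max_t) {
    double xn = x + v * dt + sdt * zig.draw(rng);
    t += dt;
    if (xn >= a) { *up = 1; return t; }
    if (xn <= 0.0) { *up = 0; return t; }
    if (bridge) {
      // exact probability that a Brownian bridge between the two interior
      // points crossed a bound inside the step; skipped when negligible
      // (< ~1e-13) to avoid the exp() on the vast majority of steps
      double du = (a - x) * (a - xn);
      if (du < 15.0 * dt) {
        double pu = std::exp(-2.0 * du / dt);
        if (rng.unif() < pu) { *up = 1; return t; }
      }
      double dl = x * xn;
      if (dl < 15.0 * dt) {
        double pl = std::exp(-2.0 * dl / dt);
        if (rng.unif() < pl) { *up = 0; return t; }
      }
    }
    x = xn;
  }
  return -1.0;
}

// n i.i.d. paths at fixed parameters
// [[Rcpp::export]]
List sim_fpt_batch_cpp(int n, double v, double a, double w, double ndt,
                       double dt, double max_t, int max_retries, bool bridge,
                       double seed) {
  Xoshiro256 rng((uint64_t)seed);
  NumericVector rt(n);
  IntegerVector choice(n);
  int n_resampled = 0;
  for (int i = 0; i < n; ++i) {
    int up = 0;
    double t = -1.0;
    int tries = 0;
    while (tries <= max_retries) {
      t = em_path(rng, v, a, w * a, dt, max_t, bridge, &up);
      if (t > 0.0) break;
      ++n_resampled;
      ++tries;
    }
    if (t < 0.0)
      stop("simulation failure: no bound crossed within %f s after %d retries "
           "(v=%f, a=%f, z=%f)", max_t, max_retries, v, a, w);
    rt[i] = t + ndt;
    choice[i] = up;
  }
  return List::create(_["rt"] = rt, _["choice"] = choice,
                      _["n_resampled"] = n_resampled);
}

// one path per trial at trial-varying parameters
// [[Rcpp::export]]
List sim_trials_cpp(NumericVector v, NumericVector a, NumericVector w,
                    NumericVector ndt, double dt, double max_t,
                    int max_retries, bool bridge, double seed) {
  int n = v.size();
  Xoshiro256 rng((uint64_t)seed);
  NumericVector rt(n);
  IntegerVector choice(n);
  int n_resampled = 0;
  for (int i = 0; i < n; ++i) {
    int up = 0;
    double t = -1.0;
    int tries = 0;
    while (tries <= max_retries) {
      t = em_path(rng, v[i], a[i], w[i] * a[i], dt, max_t, bridge, &up);
      if (t > 0.0) break;
      ++n_resampled;
      ++tries;
    }
    if (t < 0.0)
      stop("simulation failure at trial %d: no bound crossed within %f s "
           "(v=%f, a=%f, z=%f)", i + 1, max_t, v[i], a[i], w[i]);
    rt[i] = t + ndt[i];
    choice[i] = up;
  }
  return List::create(_["rt"] = rt, _["choice"] = choice,
                      _["n_resampled"] = n_resampled);
}
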