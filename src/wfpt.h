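#ifndef AACDDM_WFPT_H
#define AACDDM_WFPT_H

#include <cmath>
#include <algorithm>

// First-passage density of a Wiener diffusion between absorbing bounds
// {0, a}, unit diffusion coefficient, drift v, relative start w in (0,1),
// evaluated t seconds after the non-decision time. Small-time / large-time
// series with accuracy-driven term counts; `err` bounds the truncation error
// of the normalized density.

// normalized density (a = 1, v = 0) of absorption at the LOWER bound
inline double wfpt_norm(double tt, double w, double err) {
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * err * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  double p = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int klo = -(int)std::floor((K - 1) / 2.0);
    int khi = (int)std::ceil((K - 1) / 2.0);
    for (int k = klo; k <= khi; ++k) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k)
      p += k * std::exp(-0.5 * k * k * M_PI * M_PI * tt) * std::sin(k * M_PI * w);
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// density of absorption at the chosen bound (upper = approach) at time rt
inline double wfpt_pdf(double rt, int upper, double v, double a, double w,
                       double ndt, double err = 1e-7) {
  double t = rt - ndt;
  if (t <= 0.0) return 0.0;
  if (upper) {          // reflection: upper-bound density
    v = -v;
    w = 1.0 - w;
  }
  double tt = t / (a * a);
  double p = wfpt_norm(tt, w, err);
  return p * std::exp(-v * a * w - 0.5 * v * v * t) / (a * a);
}

#endif
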