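#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

// Adaptive single-site random-walk Metropolis-within-Gibbs sampler for the
// hierarchical affective DDM. Coefficients of the three trial-level
// regressions (drift v, threshold a, starting point z) are either
// subject-level (drawn from a population normal with unknown mean and sd;
// the non-decision time ndt is always subject-level) or group-level (one
// value shared by all subjects, normal prior). Population means get
// conjugate truncated-normal Gibbs updates; population sds get log-scale
// Metropolis updates with half-normal priors. Proposal scales adapt toward
// a target acceptance rate during burn-in only (diminishing adaptation,
// frozen afterwards). Trials whose implied a <= 0 or z outside (0,1)
// carry zero posterior mass, so such proposals are rejected outright.

static inline double dnorm_log(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.918938533204672742 - std::log(s) - 0.5 * z * z;
}

// [[Rcpp::export]]
List run_sampler_cpp(List subjects, List lev, List priors, List init,
                     List control) {
  const int S = subjects.size();
  const int n_iter = as<int>(control["n_iter"]);
  const int n_burn = as<int>(control["n_burn"]);
  const int adapt_interval = as<int>(control["adapt_interval"]);
  const double target_acc = as<double>(control["target_acc"]);
  const double err = as<double>(control["err"]);
  const double log_floor = as<double>(control["log_floor"]);
  const int G = as<int>(control["n_groups"]);

  // trial data
  std::vector<NumericVector> rt_(S);
  std::vector<IntegerVector> up_(S);
  std::vector<NumericMatrix> X_[3];
  for (int f = 0; f < 3; ++f) X_[f].resize(S);
  std::vector<int> grp(S);
  const char* fam_names[3] = {"Xv", "Xa", "Xz"};
  for (int i = 0; i < S; ++i) {
    List si = subjects[i];
    rt_[i] = as<NumericVector>(si["rt"]);
    up_[i] = as<IntegerVector>(si["upper"]);
    for (int f = 0; f < 3; ++f) X_[f][i] = as<NumericMatrix>(si[fam_names[f]]);
    grp[i] = as<int>(si["group"]) - 1;
  }

  // coefficient structure
  IntegerVector lev_[3] = {as<IntegerVector>(lev["v"]),
                           as<IntegerVector>(lev["a"]),
                           as<IntegerVector>(lev["z"])};
  int p_[3] = {(int)lev_[0].size(), (int)lev_[1].size(), (int)lev_[2].size()};

  // priors
  List pr_g = priors["group"];      // per family: mean, sd vectors
  List pr_h = priors["hyper"];      // per family: mean, sd, lb, ub vectors
  List pr_ndt = priors["ndt"];      // mean, sd, lb, ub scalars
  const double sigma_scale = as<double>(priors["sigma_scale"]);
  NumericVector gmean_[3], gsd_[3], hmean_[3], hsd_[3], hlb_[3], hub_[3];
  const char* fam_key[3] = {"v", "a", "z"};
  for (int f = 0; f < 3; ++f) {
    List pg = pr_g[fam_key[f]], ph = pr_h[fam_key[f]];
    gmean_[f] = as<NumericVector>(pg["mean"]);
    gsd_[f] = as<NumericVector>(pg["sd"]);
    hmean_[f] = as<NumericVector>(ph["mean"]);
    hsd_[f] = as<NumericVector>(ph["sd"]);
    hlb_[f] = as<NumericVector>(ph["lb"]);
    hub_[f] = as<NumericVector>(ph["ub"]);
  }
  const double ndt_hmean = as<double>(pr_ndt["mean"]);
  const double ndt_hsd = as<double>(pr_ndt["sd"]);

  // state: coefficient matrices (S x p), value shared across rows when
  // group-level; population means (p x G) and sds (p)
  NumericMatrix B_[3] = {clone(as<NumericMatrix>(init["Bv"])),
                         clone(as<NumericMatrix>(init["Ba"])),
                         clone(as<NumericMatrix>(init["Bz"]))};
  NumericMatrix mu_[3] = {clone(as<NumericMatrix>(init["mu_v"])),
                          clone(as<NumericMatrix>(init["mu_a"])),
                          clone(as<NumericMatrix>(init["mu_z"]))};
  NumericVector sd_[3] = {clone(as<NumericVector>(init["sd_v"])),
                          clone(as<NumericVector>(init["sd_a"])),
                          clone(as<NumericVector>(init["sd_z"]))};
  NumericVector ndt_ = clone(as<NumericVector>(init["ndt"]));
  NumericVector mu_ndt = clone(as<NumericVector>(init["mu_ndt"]));
  double sd_ndt = as<double>(init["sd_ndt"]);

  // linear predictors per family per subject
  std::vector<std::vector<double> > lp_[3];
  for (int f = 0; f < 3; ++f) {
    lp_[f].resize(S);
    for (int i = 0; i < S; ++i) {
      int n = rt_[i].size();
      lp_[f][i].assign(n, 0.0);
      for (int t = 0; t < n; ++t) {
        double acc = 0.0;
        for (int j = 0; j < p_[f]; ++j) acc += X_[f][i](t, j) * B_[f](i, j);
        lp_[f][i][t] = acc;
      }
    }
  }

  long long n_floor = 0;

  // subject log-likelihood, optionally with coefficient (fam 0..2, col j)
  // or ndt (fam 3) perturbed by eps
  auto subj_ll = [&](int i, int fam, int j, double eps) -> double {
    const NumericVector& r = rt_[i];
    const IntegerVector& up = up_[i];
    int n = r.size();
    double nd = ndt_[i] + (fam == 3 ? eps : 0.0);
    if (nd < 0.0) return R_NegInf;
    double ll = 0.0;
    for (int t = 0; t < n; ++t) {
      double vv = lp_[0][i][t] + (fam == 0 ? eps * X_[0][i](t, j) : 0.0);
      double aa = lp_[1][i][t] + (fam == 1 ? eps * X_[1][i](t, j) : 0.0);
      double zz = lp_[2][i][t] + (fam == 2 ? eps * X_[2][i](t, j) : 0.0);
      if (aa <= 1e-10 || zz <= 0.0 || zz >= 1.0) return R_NegInf;
      double d = wfpt_pdf(r[t], up[t], vv, aa, zz, nd, err);
      double ld = std::log(d);
      if (!(ld > log_floor)) { ld = log_floor; ++n_floor; }
      ll += ld;
    }
    return ll;
  };

  std::vector<double> cur_ll(S);
  for (int i = 0; i < S; ++i) {
    cur_ll[i] = subj_ll(i, -1, 0, 0.0);
    if (!std::isfinite(cur_ll[i]))
      stop("initial state has zero posterior mass for subject %d", i + 1);
  }

  // proposal scale bookkeeping: one adaptive scale per scalar update site
  std::vector<double> lsc;  // log proposal sd
  std::vector<int> acc_n, att_n;
  auto new_scale = [&](double s) {
    lsc.push_back(std::log(s));
    acc_n.push_back(0);
    att_n.push_back(0);
    return (int)(lsc.size() - 1);
  };
  // ids: group coefs, subject coefs (per subject), ndt (per subject), sds
  std::vector<std::vector<int> > id_g(3), id_sd(3);
  std::vector<std::vector<std::vector<int> > > id_s(3);
  List sc_g = control["scale_group"], sc_s = control["scale_subject"];
  double sc_ndt = as<double>(control["scale_ndt"]);
  for (int f = 0; f < 3; ++f) {
    NumericVector sg = as<NumericVector>(sc_g[fam_key[f]]);
    NumericVector ss = as<NumericVector>(sc_s[fam_key[f]]);
    id_g[f].assign(p_[f], -1);
    id_sd[f].assign(p_[f], -1);
    id_s[f].assign(p_[f], std::vector<int>());
    for (int j = 0; j < p_[f]; ++j) {
      if (lev_[f][j] == 0) {
        id_g[f][j] = new_scale(sg[j]);
      } else {
        id_sd[f][j] = new_scale(0.3);
        id_s[f][j].resize(S);
        for (int i = 0; i < S; ++i) id_s[f][j][i] = new_scale(ss[j]);
      }
    }
  }
  std::vector<int> id_ndt(S);
  for (int i = 0; i < S; ++i) id_ndt[i] = new_scale(sc_ndt);
  int id_ndt_sd = new_scale(0.3);

  // output layout (R mirrors this order when naming columns):
  // group coefs | hyper mu (xG) + sd per subject-level coef | ndt mu (xG), sd
  // | subject values per subject-level coef | subject ndt | deviance
  int n_keep = n_iter - n_burn;
  int P = 0;
  for (int f = 0; f < 3; ++f)
    for (int j = 0; j < p_[f]; ++j)
      P += (lev_[f][j] == 0) ? 1 : (G + 1 + S);
  P += G + 1 + S + 1;  // ndt block + deviance
  NumericMatrix out(n_keep, P);

  std::vector<double> llbuf(S);

  auto mh_scalar_group = [&](int f, int j) {
    int id = id_g[f][j];
    ++att_n[id];
    double eps = std::exp(lsc[id]) * norm_rand();
    double b = B_[f](0, j);
    double lpr = dnorm_log(b + eps, gmean_[f][j], gsd_[f][j]) -
                 dnorm_log(b, gmean_[f][j], gsd_[f][j]);
    double lln = 0.0, llo = 0.0;
    bool ok = true;
    for (int i = 0; i < S; ++i) {
      llbuf[i] = subj_ll(i, f, j, eps);
      if (!std::isfinite(llbuf[i])) { ok = false; break; }
      lln += llbuf[i];
      llo += cur_ll[i];
    }
    if (ok && std::log(unif_rand()) < lln - llo + lpr) {
      ++acc_n[id];
      for (int i = 0; i < S; ++i) {
        B_[f](i, j) += eps;
        int n = rt_[i].size();
        for (int t = 0; t < n; ++t) lp_[f][i][t] += eps * X_[f][i](t, j);
        cur_ll[i] = llbuf[i];
      }
    }
  };

  auto mh_scalar_subject = [&](int f, int j, int i) {
    int id = id_s[f][j][i];
    ++att_n[id];
    double eps = std::exp(lsc[id]) * norm_rand();
    double b = B_[f](i, j), bn = b + eps;
    if (bn < hlb_[f][j] || bn > hub_[f][j]) return;
    double m = mu_[f](j, grp[i]), s = sd_[f][j];
    double lpr = dnorm_log(bn, m, s) - dnorm_log(b, m, s);
    double lln = subj_ll(i, f, j, eps);
    if (std::isfinite(lln) &&
        std::log(unif_rand()) < lln - cur_ll[i] + lpr) {
      ++acc_n[id];
      B_[f](i, j) = bn;
      int n = rt_[i].size();
      for (int t = 0; t < n; ++t) lp_[f][i][t] += eps * X_[f][i](t, j);
      cur_ll[i] = lln;
    }
  };

  auto mh_ndt_subject = [&](int i) {
    int id = id_ndt[i];
    ++att_n[id];
    double eps = std::exp(lsc[id]) * norm_rand();
    double nn = ndt_[i] + eps;
    if (nn < 0.0) return;
    double m = mu_ndt[grp[i]], s = sd_ndt;
    double lpr = dnorm_log(nn, m, s) - dnorm_log(ndt_[i], m, s);
    double lln = subj_ll(i, 3, 0, eps);
    if (std::isfinite(lln) &&
        std::log(unif_rand()) < lln - cur_ll[i] + lpr) {
      ++acc_n[id];
      ndt_[i] = nn;
      cur_ll[i] = lln;
    }
  };

  // conjugate truncated-normal Gibbs draw for a population mean
  auto gibbs_mu = [&](double sum_x, int n_g, double sdv, double pm, double ps,
                      double lb, double ub) -> double {
    double prec = 1.0 / (ps * ps) + n_g / (sdv * sdv);
    double m = (pm / (ps * ps) + sum_x / (sdv * sdv)) / prec;
    double s = std::sqrt(1.0 / prec);
    double plo = R::pnorm(lb, m, s, 1, 0);
    double phi = R::pnorm(ub, m, s, 1, 0);
    if (phi - plo < 1e-14) return std::min(std::max(m, lb), ub);
    double u = plo + unif_rand() * (phi - plo);
    u = std::min(std::max(u, 1e-15), 1.0 - 1e-15);
    return R::qnorm(u, m, s, 1, 0);
  };

  // log-scale Metropolis for a population sd (half-normal prior)
  auto mh_sigma = [&](int id, double cur, const std::vector<double>& x,
                      const std::vector<double>& m) -> double {
    ++att_n[id];
    double lcur = std::log(cur);
    double lnew = lcur + std::exp(lsc[id]) * norm_rand();
    double sn = std::exp(lnew);
    double lt_new = -0.5 * (sn / sigma_scale) * (sn / sigma_scale) + lnew;
    double lt_cur = -0.5 * (cur / sigma_scale) * (cur / sigma_scale) + lcur;
    for (size_t k = 0; k < x.size(); ++k) {
      lt_new += dnorm_log(x[k], m[k], sn);
      lt_cur += dnorm_log(x[k], m[k], cur);
    }
    if (std::log(unif_rand()) < lt_new - lt_cur) {
      ++acc_n[id];
      return sn;
    }
    return cur;
  };

  // joint funnel moves for a subject-level coefficient: a multiplicative
  // scaling of the subject deviations together with the population sd
  // (log-Hastings includes the +eps Jacobian/prior term), and a joint
  // translation of the population mean with all subject values. Both are
  // exact Metropolis moves; they decorrelate the hierarchy when the
  // likelihood identifies subject values only weakly.
  std::vector<double> delta_buf(S);
  auto scale_move = [&](int f, int j, int id) {
    ++att_n[id];
    double eps = std::exp(lsc[id]) * norm_rand();
    double c = std::exp(eps);
    double sdn = sd_[f][j] * c;
    double lacc = eps - 0.5 * (sdn * sdn - sd_[f][j] * sd_[f][j]) /
                            (sigma_scale * sigma_scale);
    for (int i = 0; i < S; ++i) {
      double m = mu_[f](j, grp[i]);
      double xn = m + c * (B_[f](i, j) - m);
      if (xn < hlb_[f][j] || xn > hub_[f][j]) return;
      delta_buf[i] = xn - B_[f](i, j);
    }
    bool ok = true;
    for (int i = 0; i < S; ++i) {
      llbuf[i] = subj_ll(i, f, j, delta_buf[i]);
      if (!std::isfinite(llbuf[i])) { ok = false; break; }
      lacc += llbuf[i] - cur_ll[i];
    }
    if (ok && std::log(unif_rand()) < lacc) {
      ++acc_n[id];
      sd_[f][j] = sdn;
      for (int i = 0; i < S; ++i) {
        B_[f](i, j) += delta_buf[i];
        int n = rt_[i].size();
        for (int t = 0; t < n; ++t)
          lp_[f][i][t] += delta_buf[i] * X_[f][i](t, j);
        cur_ll[i] = llbuf[i];
      }
    }
  };
  auto shift_move = [&](int f, int j, int id) {
    for (int g = 0; g < G; ++g) {
      ++att_n[id];
      double t0 = std::exp(lsc[id]) * norm_rand();
      double mun = mu_[f](j, g) + t0;
      if (mun < hlb_[f][j] || mun > hub_[f][j]) continue;
      double lacc = dnorm_log(mun, hmean_[f][j], hsd_[f][j]) -
                    dnorm_log(mu_[f](j, g), hmean_[f][j], hsd_[f][j]);
      bool ok = true;
      for (int i = 0; i < S; ++i) {
        llbuf[i] = cur_ll[i];
        if (grp[i] != g) continue;
        double xn = B_[f](i, j) + t0;
        if (xn < hlb_[f][j] || xn > hub_[f][j]) { ok = false; break; }
        llbuf[i] = subj_ll(i, f, j, t0);
        if (!std::isfinite(llbuf[i])) { ok = false; break; }
        lacc += llbuf[i] - cur_ll[i];
      }
      if (ok && std::log(unif_rand()) < lacc) {
        ++acc_n[id];
        mu_[f](j, g) = mun;
        for (int i = 0; i < S; ++i) {
          if (grp[i] != g) continue;
          B_[f](i, j) += t0;
          int n = rt_[i].size();
          for (int t = 0; t < n; ++t)
            lp_[f][i][t] += t0 * X_[f][i](t, j);
          cur_ll[i] = llbuf[i];
        }
      }
    }
  };

  std::vector<std::vector<int> > id_scale(3), id_shift(3);
  for (int f = 0; f < 3; ++f) {
    id_scale[f].assign(p_[f], -1);
    id_shift[f].assign(p_[f], -1);
    for (int j = 0; j < p_[f]; ++j)
      if (lev_[f][j] == 1) {
        id_scale[f][j] = new_scale(0.15);
        id_shift[f][j] = new_scale(0.05);
      }
  }

  std::vector<double> xs, ms;
  int batch = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // 1. group-level coefficients
    for (int f = 0; f < 3; ++f)
      for (int j = 0; j < p_[f]; ++j)
        if (lev_[f][j] == 0) mh_scalar_group(f, j);

    // 2. subject-level coefficients and ndt
    for (int f = 0; f < 3; ++f)
      for (int j = 0; j < p_[f]; ++j)
        if (lev_[f][j] == 1)
          for (int i = 0; i < S; ++i) mh_scalar_subject(f, j, i);
    for (int i = 0; i < S; ++i) mh_ndt_subject(i);

    // 3. population means (Gibbs) and sds (Metropolis)
    for (int f = 0; f < 3; ++f)
      for (int j = 0; j < p_[f]; ++j)
        if (lev_[f][j] == 1) {
          for (int g = 0; g < G; ++g) {
            double sum_x = 0.0;
            int n_g = 0;
            for (int i = 0; i < S; ++i)
              if (grp[i] == g) { sum_x += B_[f](i, j); ++n_g; }
            mu_[f](j, g) = gibbs_mu(sum_x, n_g, sd_[f][j], hmean_[f][j],
                                    hsd_[f][j], hlb_[f][j], hub_[f][j]);
          }
          xs.clear(); ms.clear();
          for (int i = 0; i < S; ++i) {
            xs.push_back(B_[f](i, j));
            ms.push_back(mu_[f](j, grp[i]));
          }
          sd_[f][j] = mh_sigma(id_sd[f][j], sd_[f][j], xs, ms);
        }
    for (int g = 0; g < G; ++g) {
      double sum_x = 0.0;
      int n_g = 0;
      for (int i = 0; i < S; ++i)
        if (grp[i] == g) { sum_x += ndt_[i]; ++n_g; }
      mu_ndt[g] = gibbs_mu(sum_x, n_g, sd_ndt, ndt_hmean, ndt_hsd, 0.0,
                           R_PosInf);
    }
    xs.clear(); ms.clear();
    for (int i = 0; i < S; ++i) {
      xs.push_back(ndt_[i]);
      ms.push_back(mu_ndt[grp[i]]);
    }
    sd_ndt = mh_sigma(id_ndt_sd, sd_ndt, xs, ms);

    // 3b. joint funnel moves on subject-level coefficients
    for (int f = 0; f < 3; ++f)
      for (int j = 0; j < p_[f]; ++j)
        if (lev_[f][j] == 1) {
          scale_move(f, j, id_scale[f][j]);
          shift_move(f, j, id_shift[f][j]);
        }

    // 4. adapt proposal scales during burn-in
    if (iter < n_burn && (iter + 1) % adapt_interval == 0) {
      ++batch;
      double gamma = 0.5 / std::sqrt((double)batch);
      for (size_t k = 0; k < lsc.size(); ++k) {
        if (att_n[k] > 0) {
          double rate = (double)acc_n[k] / att_n[k];
          lsc[k] += gamma * (rate - target_acc);
        }
        acc_n[k] = 0;
        att_n[k] = 0;
      }
    }

    // 5. record
    if (iter >= n_burn) {
      int k = iter - n_burn, c = 0;
      for (int f = 0; f < 3; ++f)
        for (int j = 0; j < p_[f]; ++j)
          if (lev_[f][j] == 0) out(k, c++) = B_[f](0, j);
      for (int f = 0; f < 3; ++f)
        for (int j = 0; j < p_[f]; ++j)
          if (lev_[f][j] == 1) {
            for (int g = 0; g < G; ++g) out(k, c++) = mu_[f](j, g);
            out(k, c++) = sd_[f][j];
          }
      for (int g = 0; g < G; ++g) out(k, c++) = mu_ndt[g];
      out(k, c++) = sd_ndt;
      for (int f = 0; f < 3; ++f)
        for (int j = 0; j < p_[f]; ++j)
          if (lev_[f][j] == 1)
            for (int i = 0; i < S; ++i) out(k, c++) = B_[f](i, j);
      for (int i = 0; i < S; ++i) out(k, c++) = ndt_[i];
      double dev = 0.0;
      for (int i = 0; i < S; ++i) dev += cur_ll[i];
      out(k, c++) = -2.0 * dev;
    }

    if ((iter & 63) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = out, _["n_floor"] = (double)n_floor);
}
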