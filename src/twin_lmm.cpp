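// Twin-block linear mixed model engine.
//
// The covariance model is block-diagonal over families: co-twins share a
// within-pair correlation that depends on zygosity (r_mz for MZ pairs, r_dz
// for DZ pairs), i.e. V = sigma2 * R with R made of 2x2 blocks
// [[1, r], [r, 1]] and 1x1 blocks for singletons.  This is the marginal form
// of random intercepts for family plus an MZ-pair-specific term.  Fixed
// effects and sigma2 are profiled out analytically via the within-pair
// sum/difference rotation, leaving a 1- or 2-parameter likelihood optimised
// by Nelder-Mead on logistic-transformed correlations.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659;
static const double R_MAX = 0.999;  // correlations kept strictly inside (0, 1)

struct ProfOut {
  arma::vec beta;
  arma::mat XtWX;
  double sigma2;
  double loglik;
  bool ok;
};

// Profiled fit at fixed correlations.  XtWX accumulates X' R^{-1} X, etc.
static ProfOut profile_fit(const arma::vec& y, const arma::mat& X,
                           const arma::uvec& first, const arma::uvec& usize,
                           const arma::ivec& zyg,
                           double r_mz, double r_dz, bool reml) {
  const int n = y.n_elem, p = X.n_cols;
  const int U = first.n_elem;
  arma::mat XtWX(p, p, arma::fill::zeros);
  arma::vec XtWy(p, arma::fill::zeros);
  double yWy = 0.0, logdetR = 0.0;
  const double isq2 = std::sqrt(0.5);
  ProfOut out;
  out.ok = false;

  for (int u = 0; u < U; ++u) {
    const arma::uword i = first[u];
    if (usize[u] == 1) {
      const arma::rowvec xi = X.row(i);
      XtWX += xi.t() * xi;
      XtWy += xi.t() * y[i];
      yWy += y[i] * y[i];
    } else {
      const arma::uword j = i + 1;
      const double r = (zyg[u] == 0) ? r_mz : r_dz;
      const double w1 = 1.0 / (1.0 + r), w2 = 1.0 / (1.0 - r);
      logdetR += std::log1p(r) + std::log1p(-r);
      const arma::rowvec xs = (X.row(i) + X.row(j)) * isq2;
      const arma::rowvec xd = (X.row(i) - X.row(j)) * isq2;
      const double ys = (y[i] + y[j]) * isq2;
      const double yd = (y[i] - y[j]) * isq2;
      XtWX += w1 * (xs.t() * xs) + w2 * (xd.t() * xd);
      XtWy += w1 * xs.t() * ys + w2 * xd.t() * yd;
      yWy += w1 * ys * ys + w2 * yd * yd;
    }
  }

  arma::vec beta;
  const bool solved = arma::solve(beta, arma::symmatu(XtWX), XtWy,
                                  arma::solve_opts::likely_sympd);
  if (!solved) return out;
  double rss = yWy - arma::dot(beta, XtWy);
  if (rss < 1e-12) rss = 1e-12;  // exact-fit guard

  double sigma2, loglik;
  if (!reml) {
    sigma2 = rss / n;
    loglik = -0.5 * (n * (LOG2PI + std::log(sigma2)) + logdetR + n);
  } else {
    sigma2 = rss / (n - p);
    double ld, sgn;
    arma::log_det(ld, sgn, arma::symmatu(XtWX));
    loglik = -0.5 * ((n - p) * (LOG2PI + std::log(sigma2)) + logdetR + ld +
                     (n - p));
  }
  out.beta = beta;
  out.XtWX = XtWX;
  out.sigma2 = sigma2;
  out.loglik = loglik;
  out.ok = true;
  return out;
}

static inline double to_r(double t) { return R_MAX / (1.0 + std::exp(-t)); }
static inline double to_t(double r) {
  r = std::min(std::max(r, 1e-6), R_MAX - 1e-6);
  return std::log(r / (R_MAX - r));
}

// Nelder-Mead minimiser (reflection 1, expansion 2, contraction 0.5,
// shrink 0.5).  Converges on the relative spread of simplex values.
static double nelder_mead(const std::function<double(const arma::vec&)>& f,
                          arma::vec& x, double reltol, int maxit,
                          bool& conv, double step = 0.75) {
  const int d = x.n_elem;
  conv = true;
  if (d == 0) return f(x);

  std::vector<arma::vec> pts(d + 1, x);
  arma::vec fv(d + 1);
  for (int i = 1; i <= d; ++i) pts[i][i - 1] += step;
  for (int i = 0; i <= d; ++i) fv[i] = f(pts[i]);
  int neval = d + 1;
  conv = false;

  while (neval < maxit) {
    arma::uvec ord = arma::sort_index(fv);
    const int lo = ord[0], hi = ord[d], nh = ord[d - 1];
    if (std::fabs(fv[hi] - fv[lo]) <=
        reltol * (std::fabs(fv[lo]) + std::fabs(fv[hi]) + 1e-10)) {
      conv = true;
      break;
    }
    arma::vec cen(d, arma::fill::zeros);
    for (int i = 0; i <= d; ++i)
      if (i != hi) cen += pts[i];
    cen /= d;

    arma::vec xr = cen + (cen - pts[hi]);
    double fr = f(xr);
    ++neval;
    if (fr < fv[lo]) {
      arma::vec xe = cen + 2.0 * (cen - pts[hi]);
      double fe = f(xe);
      ++neval;
      if (fe < fr) {
        pts[hi] = xe;
        fv[hi] = fe;
      } else {
        pts[hi] = xr;
        fv[hi] = fr;
      }
    } else if (fr < fv[nh]) {
      pts[hi] = xr;
      fv[hi] = fr;
    } else {
      arma::vec xc = cen + 0.5 * ((fr < fv[hi] ? xr : pts[hi]) - cen);
      double fc = f(xc);
      ++neval;
      if (fc < std::min(fr, fv[hi])) {
        pts[hi] = xc;
        fv[hi] = fc;
      } else {  // shrink towards the best point
        for (int i = 0; i <= d; ++i) {
          if (i == lo) continue;
          pts[i] = pts[lo] + 0.5 * (pts[i] - pts[lo]);
          fv[i] = f(pts[i]);
          ++neval;
        }
      }
    }
  }
  arma::uvec ord = arma::sort_index(fv);
  x = pts[ord[0]];
  return fv[ord[0]];
}

struct TwinFit {
  ProfOut prof;
  double r_mz, r_dz;
  bool conv;
};

// mode 0: free (r_mz, r_dz as identified by the data)
// mode 1: equal correlations, r_mz = r_dz (single family intercept)
// mode 2: r_dz = r_mz / 2 (no common-environment component)
static TwinFit twin_fit(const arma::vec& y, const arma::mat& X,
                        const arma::uvec& first, const arma::uvec& usize,
                        const arma::ivec& zyg, bool reml, int mode,
                        double reltol, int maxit,
                        const arma::vec& start) {
  int n_mz = 0, n_dz = 0;
  for (arma::uword u = 0; u < usize.n_elem; ++u) {
    if (usize[u] == 2) {
      if (zyg[u] == 0) ++n_mz; else ++n_dz;
    }
  }
  const bool has_mz = n_mz > 0, has_dz = n_dz > 0;

  // parameter layout per mode / zygosity composition
  int d;
  if (!has_mz && !has_dz) d = 0;
  else if (mode == 1 || mode == 2) d = 1;
  else d = (has_mz && has_dz) ? 2 : 1;

  auto unpack = [&](const arma::vec& th, double& r1, double& r2) {
    r1 = 0.0; r2 = 0.0;
    if (d == 0) return;
    if (mode == 1) {
      r1 = r2 = to_r(th[0]);
    } else if (mode == 2) {
      r1 = to_r(th[0]);
      r2 = r1 / 2.0;
    } else if (d == 2) {
      r1 = to_r(th[0]);
      r2 = to_r(th[1]);
    } else if (has_mz) {
      r1 = to_r(th[0]);
    } else {
      r2 = to_r(th[0]);
    }
  };

  auto obj = [&](const arma::vec& th) -> double {
    double r1, r2;
    unpack(th, r1, r2);
    ProfOut pr = profile_fit(y, X, first, usize, zyg, r1, r2, reml);
    if (!pr.ok || !std::isfinite(pr.loglik)) return 1e300;
    return -pr.loglik;
  };

  arma::vec th(d);
  const bool warm = start.n_elem == (arma::uword)d;
  for (int i = 0; i < d; ++i) th[i] = warm ? start[i] : to_t(0.2);

  TwinFit fit;
  fit.conv = true;
  if (d > 0)
    nelder_mead(obj, th, reltol, maxit, fit.conv, warm ? 0.2 : 0.75);
  unpack(th, fit.r_mz, fit.r_dz);
  fit.prof = profile_fit(y, X, first, usize, zyg, fit.r_mz, fit.r_dz, reml);
  return fit;
}

static List fit_to_list(const TwinFit& fit, int p) {
  arma::vec se(p, arma::fill::value(NA_REAL));
  if (fit.prof.ok) {
    arma::mat XtWXi;
    if (arma::inv_sympd(XtWXi, arma::symmatu(fit.prof.XtWX)))
      se = arma::sqrt(fit.prof.sigma2 * XtWXi.diag());
  }
  return List::create(
      _["loglik"] = fit.prof.ok ? fit.prof.loglik : NA_REAL,
      _["beta"] = fit.prof.ok ? NumericVector(wrap(fit.prof.beta))
                              : NumericVector(p, NA_REAL),
      _["se"] = wrap(se), _["sigma2"] = fit.prof.ok ? fit.prof.sigma2 : NA_REAL,
      _["r_mz"] = fit.r_mz, _["r_dz"] = fit.r_dz,
      _["converged"] = fit.conv && fit.prof.ok);
}

// [[Rcpp::export]]
List cpp_twin_fit(const arma::vec& y, const arma::mat& X,
                  const arma::uvec& first, const arma::uvec& usize,
                  const arma::ivec& zyg, bool reml, int mode,
                  double reltol, int maxit) {
  arma::vec start;
  TwinFit fit = twin_fit(y, X, first, usize, zyg, reml, mode, reltol, maxit,
                         start);
  return fit_to_list(fit, X.n_cols);
}

// [[Rcpp::export]]
double cpp_twin_profile_loglik(const arma::vec& y, const arma::mat& X,
                               const arma::uvec& first,
                               const arma::uvec& usize, const arma::ivec& zyg,
                               double r_mz, double r_dz, bool reml) {
  ProfOut pr = profile_fit(y, X, first, usize, zyg, r_mz, r_dz, reml);
  return pr.ok ? pr.loglik : NA_REAL;
}

// Per-feature ML likelihood-ratio scan: full model vs model without its
// last fixed-effect column.  Y is n x F (features in columns).
// Returns F x 7: beta_last, se_last, ll_full, ll_reduced, r_mz, r_dz, conv.
// [[Rcpp::export]]
arma::mat cpp_lrt_scan(const arma::mat& Y, const arma::mat& Xf,
                       const arma::mat& Xr, const arma::uvec& first,
                       const arma::uvec& usize, const arma::ivec& zyg,
                       double reltol, int maxit) {
  const int F = Y.n_cols;
  const int pf = Xf.n_cols;
  arma::mat out(F, 7);
  out.fill(NA_REAL);
  for (int f = 0; f < F; ++f) {
    const arma::vec y = Y.col(f);
    arma::vec start;
    TwinFit full = twin_fit(y, Xf, first, usize, zyg, false, 0, reltol,
                            maxit, start);
    if (!full.prof.ok) continue;
    // warm-start the reduced fit at the full-model correlations
    int d = 0;
    {
      int n_mz = 0, n_dz = 0;
      for (arma::uword u = 0; u < usize.n_elem; ++u)
        if (usize[u] == 2) { if (zyg[u] == 0) ++n_mz; else ++n_dz; }
      d = (n_mz > 0) + (n_dz > 0);
    }
    arma::vec st(d);
    if (d == 2) { st[0] = to_t(full.r_mz); st[1] = to_t(full.r_dz); }
    else if (d == 1) st[0] = to_t(std::max(full.r_mz, full.r_dz));
    TwinFit red = twin_fit(y, Xr, first, usize, zyg, false, 0, reltol,
                           maxit, st);
    if (!red.prof.ok) continue;
    arma::mat XtWXi;
    double se = NA_REAL;
    if (arma::inv_sympd(XtWXi, arma::symmatu(full.prof.XtWX)))
      se = std::sqrt(full.prof.sigma2 * XtWXi(pf - 1, pf - 1));
    out(f, 0) = full.prof.beta[pf - 1];
    out(f, 1) = se;
    out(f, 2) = full.prof.loglik;
    out(f, 3) = red.prof.loglik;
    out(f, 4) = full.r_mz;
    out(f, 5) = full.r_dz;
    out(f, 6) = (full.conv && red.conv) ? 1.0 : 0.0;
  }
  return out;
}

// ML fit per feature for a single design; returns F x 4:
// loglik, beta_last, r_mz, r_dz.  Used by permutation scans where the
// reduced-model likelihoods are shared across permutations.  `starts`
// may supply per-feature warm starts as an F x 2 matrix of (r_mz, r_dz)
// from a previous fit of the same feature.
// [[Rcpp::export]]
arma::mat cpp_ml_loglik_scan(const arma::mat& Y, const arma::mat& X,
                             const arma::uvec& first, const arma::uvec& usize,
                             const arma::ivec& zyg, double reltol,
                             int maxit,
                             Nullable<NumericMatrix> starts = R_NilValue) {
  const int F = Y.n_cols;
  arma::mat out(F, 4);
  out.fill(NA_REAL);
  int n_mz = 0, n_dz = 0;
  for (arma::uword u = 0; u < usize.n_elem; ++u)
    if (usize[u] == 2) { if (zyg[u] == 0) ++n_mz; else ++n_dz; }
  const int d = (n_mz > 0) + (n_dz > 0);
  arma::mat st_r;
  if (starts.isNotNull()) st_r = as<arma::mat>(starts.get());
  for (int f = 0; f < F; ++f) {
    arma::vec start;
    if (st_r.n_rows == (arma::uword)F && d > 0 &&
        std::isfinite(st_r(f, 0)) && std::isfinite(st_r(f, 1))) {
      start.set_size(d);
      if (d == 2) { start[0] = to_t(st_r(f, 0)); start[1] = to_t(st_r(f, 1)); }
      else start[0] = to_t(n_mz > 0 ? st_r(f, 0) : st_r(f, 1));
    }
    TwinFit fit = twin_fit(Y.col(f), X, first, usize, zyg, false, 0, reltol,
                           maxit, start);
    if (!fit.prof.ok) continue;
    out(f, 0) = fit.prof.loglik;
    out(f, 1) = fit.prof.beta[X.n_cols - 1];
    out(f, 2) = fit.r_mz;
    out(f, 3) = fit.r_dz;
  }
  return out;
}

// Conditional residuals: REML fit per feature, then remove fixed effects
// and the BLUP of the pair-shared (family) component.  For a pair with
// correlation r the shared-effect BLUP is r/(1+r) * (e_i + e_j); a
// singleton's shared fraction is shrunk by r_mz (its family and
// zygosity-level variance combined).
// [[Rcpp::export]]
arma::mat cpp_cond_residuals(const arma::mat& Y, const arma::mat& X,
                             const arma::uvec& first, const arma::uvec& usize,
                             const arma::ivec& zyg, double reltol,
                             int maxit) {
  const int F = Y.n_cols;
  arma::mat R(Y.n_rows, F);
  R.fill(NA_REAL);
  for (int f = 0; f < F; ++f) {
    const arma::vec y = Y.col(f);
    arma::vec start;
    TwinFit fit = twin_fit(y, X, first, usize, zyg, true, 0, reltol, maxit,
                           start);
    if (!fit.prof.ok) continue;
    arma::vec e = y - X * fit.prof.beta;
    for (arma::uword u = 0; u < usize.n_elem; ++u) {
      const arma::uword i = first[u];
      if (usize[u] == 1) {
        e[i] *= (1.0 - fit.r_mz);
      } else {
        const double r = (zyg[u] == 0) ? fit.r_mz : fit.r_dz;
        const double blup = r / (1.0 + r) * (e[i] + e[i + 1]);
        e[i] -= blup;
        e[i + 1] -= blup;
      }
    }
    R.col(f) = e;
  }
  return R;
}
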