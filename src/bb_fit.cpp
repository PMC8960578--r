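// Per-CpG beta-binomial regression with matched-pair fixed effects and a
// likelihood-ratio test on the case/control term. The mean is modelled on the
// logit scale (intercept + pair dummies + group), the beta precision s on the
// log scale (tau = log s); the intra-site correlation is rho = 1/(1 + s).
// When the dispersion MLE hits the rho -> 0 boundary the test falls back to an
// ordinary binomial GLM likelihood-ratio test. P-values use an F(1, n - p)
// reference (the square of a t rather than a normal reference), a
// small-sample adjustment for the many nuisance parameters fitted per site;
// it converges to the usual chi-squared(1) reference as n grows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ETA_CLAMP = 13.8;  // mu within ~[1e-6, 1-1e-6]
static const double TAU_LO = -7.0;   // rho ~ 0.999
static const double TAU_HI = 12.0;   // rho ~ 6e-6: treated as the boundary

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// negative log-likelihood (constants dropped) and gradient; par = (beta, tau)
static double bb_nll(const vec& par, const mat& X, const vec& m, const vec& n,
                     vec& grad, bool want_grad) {
  const unsigned p = X.n_cols;
  vec beta = par.head(p);
  double tau = clampd(par(p), TAU_LO, TAU_HI);
  double s = std::exp(tau);
  vec eta = X * beta;
  double nll = 0.0;
  if (want_grad) grad.zeros(p + 1);
  vec weta(X.n_rows, fill::zeros);
  double gtau = 0.0;
  for (unsigned i = 0; i < X.n_rows; ++i) {
    double e = clampd(eta(i), -ETA_CLAMP, ETA_CLAMP);
    double mu = 1.0 / (1.0 + std::exp(-e));
    double a = mu * s, b = (1.0 - mu) * s;
    double ll = R::lgammafn(m(i) + a) + R::lgammafn(n(i) - m(i) + b)
      - R::lgammafn(n(i) + a + b) - R::lgammafn(a) - R::lgammafn(b)
      + R::lgammafn(a + b);
    nll -= ll;
    if (want_grad) {
      double dab = R::digamma(a + b) - R::digamma(n(i) + a + b);
      double ga = R::digamma(m(i) + a) - R::digamma(a) + dab;
      double gb = R::digamma(n(i) - m(i) + b) - R::digamma(b) + dab;
      weta(i) = -s * mu * (1.0 - mu) * (ga - gb);
      gtau -= s * (mu * ga + (1.0 - mu) * gb);
    }
  }
  if (want_grad) {
    grad.head(p) = X.t() * weta;
    grad(p) = gtau;
  }
  return nll;
}

// compact BFGS with Armijo backtracking; tau component kept inside its box
static bool bfgs_bb(vec& par, const mat& X, const vec& m, const vec& n,
                    double& nll_out, int max_iter = 200) {
  const unsigned d = par.n_elem;
  mat H = eye(d, d);
  vec g(d), gnew(d);
  double f = bb_nll(par, X, m, n, g, true);
  bool converged = false;
  bool restarted = false;
  for (int it = 0; it < max_iter; ++it) {
    if (norm(g, "inf") < 1e-6 * std::max(1.0, std::fabs(f))) { converged = true; break; }
    vec dir = -H * g;
    double slope = dot(g, dir);
    if (slope > 0) { H = eye(d, d); dir = -g; slope = dot(g, dir); }
    double step = 1.0;
    vec par_new = par;
    double f_new = f;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      par_new = par + step * dir;
      par_new(d - 1) = clampd(par_new(d - 1), TAU_LO, TAU_HI);
      f_new = bb_nll(par_new, X, m, n, gnew, false);
      if (std::isfinite(f_new) && f_new <= f + 1e-4 * step * slope) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) {
      // one restart from a fresh inverse-Hessian before giving up
      if (!restarted) { restarted = true; H = eye(d, d); continue; }
      converged = norm(g, "inf") < 1e-3 * std::max(1.0, std::fabs(f));
      break;
    }
    bb_nll(par_new, X, m, n, gnew, true);
    vec sk = par_new - par, yk = gnew - g;
    double sy = dot(sk, yk);
    if (sy > 1e-12) {
      mat I = eye(d, d);
      mat V = I - (sk * yk.t()) / sy;
      H = V * H * V.t() + (sk * sk.t()) / sy;
    }
    if (std::fabs(f - f_new) < 1e-10 * std::max(1.0, std::fabs(f))) {
      par = par_new; f = f_new; g = gnew; converged = true; break;
    }
    par = par_new; f = f_new; g = gnew;
  }
  nll_out = f;
  return converged;
}

// binomial logistic IRLS; returns log-likelihood (constants dropped)
static double binom_irls(vec& beta, const mat& X, const vec& m, const vec& n,
                         bool& converged) {
  const unsigned p = X.n_cols;
  beta.zeros(p);
  double msum = accu(m), nsum = accu(n);
  double p0 = clampd(msum / std::max(nsum, 1.0), 1e-4, 1.0 - 1e-4);
  beta(0) = std::log(p0 / (1.0 - p0));
  double ll_old = -datum::inf;
  converged = false;
  for (int it = 0; it < 50; ++it) {
    vec eta = clamp(X * beta, -15.0, 15.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = n % mu % (1.0 - mu);
    w = clamp(w, 1e-10, datum::inf);
    vec z = eta + (m - n % mu) / w;
    mat XtW = X.t() * diagmat(w);
    vec beta_new;
    bool solved = solve(beta_new, XtW * X + 1e-10 * eye(p, p), XtW * z);
    if (!solved) break;
    beta = beta_new;
    eta = clamp(X * beta, -15.0, 15.0);
    mu = 1.0 / (1.0 + exp(-eta));
    double ll = accu(m % log(mu) + (n - m) % log(1.0 - mu));
    if (std::fabs(ll - ll_old) < 1e-10 * std::max(1.0, std::fabs(ll))) {
      converged = true; ll_old = ll; break;
    }
    ll_old = ll;
  }
  return ll_old;
}

// [[Rcpp::export(name = ".bb_lrt_sites")]]
Rcpp::List bb_lrt_sites(Rcpp::IntegerMatrix meth, Rcpp::IntegerMatrix total,
                        Rcpp::IntegerVector group, Rcpp::IntegerVector pair,
                        double rho_init = 0.05) {
  const int nsite = meth.nrow(), nsamp = meth.ncol();
  Rcpp::NumericVector p_out(nsite, NA_REAL), stat_out(nsite, NA_REAL),
    rho_out(nsite, NA_REAL), beta_out(nsite, NA_REAL);
  Rcpp::IntegerVector code_out(nsite), boundary_out(nsite),
    ncase_out(nsite), nctrl_out(nsite), npar_out(nsite);
  // code: 0 ok, 1 insufficient data, 2 non-convergence

  int npair_levels = 0;
  for (int j = 0; j < nsamp; ++j) npair_levels = std::max(npair_levels, pair[j]);

  std::vector<int> use; use.reserve(nsamp);
  std::vector<int> pair_has(npair_levels * 2);

  for (int i = 0; i < nsite; ++i) {
    use.clear();
    std::fill(pair_has.begin(), pair_has.end(), 0);
    for (int j = 0; j < nsamp; ++j) {
      int nt = total(i, j), nm = meth(i, j);
      if (nt == NA_INTEGER || nm == NA_INTEGER || nt <= 0) continue;
      use.push_back(j);
      pair_has[(pair[j] - 1) * 2 + group[j]] = 1;
    }
    // keep only pairs observed on both sides; count them
    std::vector<int> pair_ok(npair_levels, 0);
    int npairs = 0;
    for (int k = 0; k < npair_levels; ++k)
      if (pair_has[2 * k] && pair_has[2 * k + 1]) { pair_ok[k] = 1; ++npairs; }
    std::vector<int> keep; keep.reserve(use.size());
    for (int j : use) if (pair_ok[pair[j] - 1]) keep.push_back(j);
    if (npairs < 2) { code_out[i] = 1; continue; }

    const unsigned nobs = keep.size();
    // pair level -> dummy column (first kept pair is reference)
    std::vector<int> pcol(npair_levels, -1);
    int pc = 0;
    for (int k = 0; k < npair_levels; ++k)
      if (pair_ok[k]) pcol[k] = pc++;
    const unsigned pfull = 1 + (npairs - 1) + 1;  // intercept, pair dummies, group
    mat X(nobs, pfull, fill::zeros);
    vec mv(nobs), nv(nobs);
    int ncase = 0, nctrl = 0;
    for (unsigned r = 0; r < nobs; ++r) {
      int j = keep[r];
      X(r, 0) = 1.0;
      int pd = pcol[pair[j] - 1];
      if (pd > 0) X(r, pd) = 1.0;  // dummy columns 1..npairs-1
      X(r, pfull - 1) = group[j];
      mv(r) = meth(i, j);
      nv(r) = total(i, j);
      if (group[j] == 1) ++ncase; else ++nctrl;
    }
    ncase_out[i] = ncase; nctrl_out[i] = nctrl;

    // binomial starting values
    bool bc = false;
    vec beta_full;
    double ll_bin_full = binom_irls(beta_full, X, mv, nv, bc);

    double tau0 = std::log((1.0 - rho_init) / rho_init);
    vec par_full(pfull + 1);
    // separated binomial fits produce huge coefficients; start moderate
    par_full.head(pfull) = clamp(beta_full, -10.0, 10.0);
    par_full(pfull) = tau0;
    double nll_full;
    bool conv_full = bfgs_bb(par_full, X, mv, nv, nll_full);

    bool at_boundary = par_full(pfull) >= TAU_HI - 1e-6;
    mat X0 = X.cols(0, pfull - 2);
    if (at_boundary) {
      // dispersion at rho -> 0: ordinary binomial GLM LRT
      vec beta_null;
      bool bc0 = false;
      double ll_bin_null = binom_irls(beta_null, X0, mv, nv, bc0);
      if (!bc || !bc0) { code_out[i] = 2; continue; }
      double lrt = 2.0 * (ll_bin_full - ll_bin_null);
      if (lrt < 0) lrt = 0;
      stat_out[i] = lrt;
      npar_out[i] = pfull;  // no free dispersion on the binomial route
      double df2 = std::max((double) nobs - pfull, 1.0);
      p_out[i] = R::pf(lrt, 1.0, df2, 0, 0);
      rho_out[i] = 0.0;
      boundary_out[i] = 1;
      beta_out[i] = beta_full(pfull - 1);
      continue;
    }
    vec par_null(pfull);
    par_null.head(pfull - 1) = par_full.head(pfull - 1);
    par_null(pfull - 1) = par_full(pfull);  // tau
    double nll_null;
    bool conv_null = bfgs_bb(par_null, X0, mv, nv, nll_null);
    if (!conv_full || !conv_null) { code_out[i] = 2; continue; }
    double lrt = 2.0 * (nll_null - nll_full);
    if (lrt < 0) lrt = 0;
    stat_out[i] = lrt;
    npar_out[i] = pfull + 1;  // mean parameters plus the dispersion
    double df2 = std::max((double) nobs - (pfull + 1.0), 1.0);
    p_out[i] = R::pf(lrt, 1.0, df2, 0, 0);
    double s = std::exp(par_full(pfull));
    rho_out[i] = 1.0 / (1.0 + s);
    beta_out[i] = par_full(pfull - 1);
  }
  return Rcpp::List::create(
    Rcpp::Named("p") = p_out, Rcpp::Named("stat") = stat_out,
    Rcpp::Named("rho") = rho_out, Rcpp::Named("log_odds") = beta_out,
    Rcpp::Named("boundary") = boundary_out, Rcpp::Named("code") = code_out,
    Rcpp::Named("n_case") = ncase_out, Rcpp::Named("n_control") = nctrl_out,
    Rcpp::Named("n_par") = npar_out);
}

// standalone NLL for cross-checks from R; par = (beta, tau)
// [[Rcpp::export(name = ".bb_nll")]]
double bb_nll_r(Rcpp::NumericVector par, Rcpp::NumericMatrix X,
                Rcpp::NumericVector m, Rcpp::NumericVector n) {
  vec p(par.begin(), par.size());
  mat Xa(X.begin(), X.nrow(), X.ncol());
  vec mv(m.begin(), m.size()), nv(n.begin(), n.size());
  vec g;
  return bb_nll(p, Xa, mv, nv, g, false);
}
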