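// Core numerics: generalized Poisson (GP2) log-pmf, hurdle log-likelihoods,
// GMM moment functions, and the simplex minimizer that drives all fitting.
// Everything here is deterministic; randomness lives on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PENALTY = 1e10;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log(1 - exp(-a)) for a > 0
static inline double log_one_minus_exp(double a) {
  return (a > M_LN2) ? std::log1p(-std::exp(-a)) : std::log(-std::expm1(-a));
}

// GP2 log pmf at integer y >= 0; caller guarantees mu > 0 and 1 + alpha*mu > 0.
// Returns -Inf where 1 + alpha*y <= 0 (support truncation under alpha < 0).
static inline double gp_logpmf(double y, double mu, double alpha) {
  const double am = 1.0 + alpha * mu;
  const double ay = 1.0 + alpha * y;
  if (ay <= 0.0) return R_NegInf;
  return y * std::log(mu / am) + (y - 1.0) * std::log(ay)
       - std::lgamma(y + 1.0) - mu * ay / am;
}

// ---------------------------------------------------------------------------
// Negative log-likelihoods. model: 0 = GP hurdle, 1 = Poisson hurdle (alpha
// fixed at 0, theta has no alpha slot), 2 = GP regression (no zero part).
// Infeasible parameter regions return a large finite penalty so that the
// unconstrained simplex search can proceed.
// ---------------------------------------------------------------------------
static double nll_eval(int model, const vec& theta, const vec& y,
                       const mat& X, const mat& Z) {
  const uword n = y.n_elem, px = X.n_cols;
  double alpha;
  vec beta, delta;
  if (model == 0) {          // GPHR: (alpha, beta, delta)
    alpha = theta(0);
    beta  = theta.subvec(1, px);
    delta = theta.subvec(px + 1, theta.n_elem - 1);
  } else if (model == 1) {   // PH: (beta, delta)
    alpha = 0.0;
    beta  = theta.subvec(0, px - 1);
    delta = theta.subvec(px, theta.n_elem - 1);
  } else {                   // GP: (alpha, beta)
    alpha = theta(0);
    beta  = theta.subvec(1, px);
  }

  vec mu = exp(X * beta);
  if (!mu.is_finite()) return PENALTY;
  if (alpha != 0.0) {
    if (min(1.0 + alpha * mu) <= 0.0) return PENALTY;
    if (alpha < 0.0 && (1.0 + alpha * y.max()) <= 0.0) return PENALTY;
  }

  double ll = 0.0;
  if (model == 2) {
    for (uword i = 0; i < n; ++i) ll += gp_logpmf(y(i), mu(i), alpha);
  } else {
    vec zd = Z * delta;
    for (uword i = 0; i < n; ++i) {
      if (y(i) == 0.0) {
        ll += -softplus(-zd(i));                       // log w_i
      } else {
        const double c0 = mu(i) / (1.0 + alpha * mu(i)); // -log g(0)
        ll += -softplus(zd(i))                         // log(1 - w_i)
            + gp_logpmf(y(i), mu(i), alpha)
            - log_one_minus_exp(c0);
      }
    }
  }
  if (!std::isfinite(ll)) return PENALTY;
  return -ll;
}

// [[Rcpp::export]]
double cpp_nll(int model, const arma::vec& theta, const arma::vec& y,
               const arma::mat& X, const arma::mat& Z) {
  return nll_eval(model, theta, y, X, Z);
}

// ---------------------------------------------------------------------------
// GMM moment functions for the GP hurdle model.
// g1 = r * mu, g2 = r * (mu (1+alpha mu)^2 + mu^2) with
// r = (1-w) / (1 - exp(-mu/(1+alpha mu))); g2_form = 1 switches the bracket
// to mu (1+alpha mu) + mu^2 (sensitivity variant).
// ---------------------------------------------------------------------------
static bool g1g2_eval(const vec& theta, const vec& y, const mat& X,
                      const mat& Z, int g2_form,
                      vec& w, vec& g1, vec& g2) {
  const uword px = X.n_cols;
  const double alpha = theta(0);
  const vec beta  = theta.subvec(1, px);
  const vec delta = theta.subvec(px + 1, theta.n_elem - 1);
  vec mu = exp(X * beta);
  if (!mu.is_finite()) return false;
  if (alpha != 0.0 && min(1.0 + alpha * mu) <= 0.0) return false;
  const vec zd = Z * delta;
  w = 1.0 / (1.0 + exp(-zd));
  const vec am = 1.0 + alpha * mu;
  const vec c0 = mu / am;
  const vec r  = (1.0 - w) / (1.0 - exp(-c0));
  g1 = r % mu;
  if (g2_form == 1)
    g2 = r % (mu % am + square(mu));
  else
    g2 = r % (mu % square(am) + square(mu));
  return g1.is_finite() && g2.is_finite();
}

// Per-observation moment rows h_i' (n x d). Stacked covariate vector is
// X_i = (x_i', z_i')'; optional augmented block z_i (1{y_i=0} - w_i).
// [[Rcpp::export]]
arma::mat cpp_moment_matrix(const arma::vec& theta, const arma::vec& y,
                            const arma::mat& X, const arma::mat& Z,
                            int g2_form, bool augment) {
  vec w, g1, g2;
  if (!g1g2_eval(theta, y, X, Z, g2_form, w, g1, g2))
    Rcpp::stop("infeasible parameter value in moment evaluation");
  const vec r1 = y - g1;
  const vec r2 = square(y) - g2;
  mat H = join_horiz(join_horiz(X.each_col() % r1, Z.each_col() % r1),
                     join_horiz(X.each_col() % r2, Z.each_col() % r2));
  if (augment) {
    vec z0 = conv_to<vec>::from(y == 0.0) - w;
    H = join_horiz(H, Z.each_col() % z0);
  }
  return H;
}

static double qn_eval(const vec& theta, const vec& y, const mat& X,
                      const mat& Z, const mat& W, int g2_form, bool augment) {
  vec w, g1, g2;
  if (!g1g2_eval(theta, y, X, Z, g2_form, w, g1, g2)) return PENALTY;
  const double n = (double) y.n_elem;
  const vec r1 = y - g1;
  const vec r2 = square(y) - g2;
  vec h = join_vert(join_vert(X.t() * r1, Z.t() * r1),
                    join_vert(X.t() * r2, Z.t() * r2)) / n;
  if (augment) {
    vec z0 = conv_to<vec>::from(y == 0.0) - w;
    h = join_vert(h, Z.t() * z0 / n);
  }
  const double q = dot(h, W * h);
  return std::isfinite(q) ? q : PENALTY;
}

// [[Rcpp::export]]
double cpp_qn(const arma::vec& theta, const arma::vec& y, const arma::mat& X,
              const arma::mat& Z, const arma::mat& W, int g2_form,
              bool augment) {
  return qn_eval(theta, y, X, Z, W, g2_form, augment);
}

// ---------------------------------------------------------------------------
// Nelder-Mead simplex minimizer with reflection (eta), expansion (gamma),
// contraction (xi) and shrink (kappa) coefficients; stops when the
// root-mean-square spread of the objective over the m best vertices falls
// below eps, or when the simplex diameter collapses, or at max_iter.
// ---------------------------------------------------------------------------
struct NMOut { vec x; double f; int iter; bool conv; };

template <typename F>
static NMOut nm_core(F fobj, const vec& x0, double eta, double gam, double xi,
                     double kap, double eps, int max_iter, double init_step) {
  const int m = (int) x0.n_elem;
  std::vector<vec> V(m + 1);
  std::vector<double> fv(m + 1);
  V[0] = x0;
  for (int i = 1; i <= m; ++i) {
    V[i] = x0;
    V[i](i - 1) += init_step * std::max(std::abs(x0(i - 1)), 1.0);
  }
  for (int i = 0; i <= m; ++i) fv[i] = fobj(V[i]);

  std::vector<int> idx(m + 1);
  int it = 0;
  bool conv = false;
  while (it < max_iter) {
    // stable ordering keeps ties deterministic
    std::iota(idx.begin(), idx.end(), 0);
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return fv[a] < fv[b]; });
    std::vector<vec> Vs(m + 1);
    std::vector<double> fs(m + 1);
    for (int i = 0; i <= m; ++i) { Vs[i] = V[idx[i]]; fs[i] = fv[idx[i]]; }
    V.swap(Vs); fv.swap(fs);

    double fbar = 0.0;
    for (int i = 0; i < m; ++i) fbar += fv[i];
    fbar /= m;
    double s2 = 0.0;
    for (int i = 0; i < m; ++i) s2 += (fv[i] - fbar) * (fv[i] - fbar);
    double diam = 0.0;
    for (int i = 1; i <= m; ++i)
      diam = std::max(diam, norm(V[i] - V[0], 2));
    if (std::sqrt(s2 / m) < eps || diam < eps * (1.0 + norm(V[0], 2))) {
      conv = true;
      break;
    }
    ++it;

    vec cen = zeros<vec>(m);
    for (int i = 0; i < m; ++i) cen += V[i];
    cen /= m;

    const vec xr = (1.0 + eta) * cen - eta * V[m];   // reflection
    const double fr = fobj(xr);

    if (fv[0] <= fr && fr <= fv[m - 1]) {            // accept reflection
      V[m] = xr; fv[m] = fr;
      continue;
    }
    if (fr < fv[0]) {                                // expansion
      const vec xe = (1.0 - gam) * cen + gam * xr;
      const double fe = fobj(xe);
      if (fe <= fr) { V[m] = xe; fv[m] = fe; }
      else          { V[m] = xr; fv[m] = fr; }
      continue;
    }
    if (fr <= fv[m]) {                               // outside contraction
      const vec xc = (1.0 - xi) * cen + xi * xr;
      const double fc = fobj(xc);
      if (fc <= fr) { V[m] = xc; fv[m] = fc; continue; }
    } else {                                         // inside contraction
      const vec xc = (1.0 + xi) * cen - xi * xr;
      const double fc = fobj(xc);
      if (fc <= fv[m]) { V[m] = xc; fv[m] = fc; continue; }
    }
    for (int i = 1; i <= m; ++i) {                   // shrink toward best
      V[i] = (1.0 - kap) * V[0] + kap * V[i];
      fv[i] = fobj(V[i]);
    }
  }

  int best = 0;
  for (int i = 1; i <= m; ++i) if (fv[i] < fv[best]) best = i;
  NMOut out;
  out.x = V[best]; out.f = fv[best]; out.iter = it; out.conv = conv;
  return out;
}

static Rcpp::List nm_result(const NMOut& r) {
  return Rcpp::List::create(
      Rcpp::Named("par") = Rcpp::NumericVector(r.x.begin(), r.x.end()),
      Rcpp::Named("value") = r.f,
      Rcpp::Named("n_iter") = r.iter,
      Rcpp::Named("converged") = r.conv);
}

// Generic entry point: minimizes an R function (used by nelder_mead()).
// [[Rcpp::export]]
Rcpp::List cpp_nelder_mead(Rcpp::Function f, const arma::vec& x0, double eta,
                           double gam, double xi, double kap, double eps,
                           int max_iter, double init_step) {
  auto fobj = [&f](const vec& x) -> double {
    Rcpp::NumericVector xr(x.begin(), x.end());
    return Rcpp::as<double>(f(xr));
  };
  return nm_result(nm_core(fobj, x0, eta, gam, xi, kap, eps, max_iter,
                           init_step));
}

// Fast path for likelihood fits: the objective never leaves C++.
// [[Rcpp::export]]
Rcpp::List cpp_fit_nll(int model, const arma::vec& y, const arma::mat& X,
                       const arma::mat& Z, const arma::vec& theta0,
                       double eta, double gam, double xi, double kap,
                       double eps, int max_iter, double init_step) {
  auto fobj = [&](const vec& th) { return nll_eval(model, th, y, X, Z); };
  return nm_result(nm_core(fobj, theta0, eta, gam, xi, kap, eps, max_iter,
                           init_step));
}

// Fast path for GMM fits.
// [[Rcpp::export]]
Rcpp::List cpp_fit_gmm(const arma::vec& y, const arma::mat& X,
                       const arma::mat& Z, const arma::mat& W,
                       const arma::vec& theta0, int g2_form, bool augment,
                       double eta, double gam, double xi, double kap,
                       double eps, int max_iter, double init_step) {
  auto fobj = [&](const vec& th) {
    return qn_eval(th, y, X, Z, W, g2_form, augment);
  };
  return nm_result(nm_core(fobj, theta0, eta, gam, xi, kap, eps, max_iter,
                           init_step));
}
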