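// Maximum-likelihood random-intercept linear mixed model, profiled over the
// variance ratio lambda = sigma2_u / sigma2_e.
//
// For V = I + lambda * Z Z' with Z a subject-indicator matrix, each
// subject's block inverts in closed form:
//   V_i^{-1} = I - c_i * J,   c_i = lambda / (1 + lambda * n_i)
//   log|V|   = sum_i log(1 + lambda * n_i)
// so GLS quantities reduce to per-subject column sums and the profile
// log-likelihood costs O(m p^2) per lambda evaluation. This keeps the
// nested leave-one-session-out loops (~1e5 fits per run) tractable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct SuffStats {
  mat XtX;    // p x p
  vec Xty;    // p
  double yty;
  mat S;      // m x p per-subject column sums of X
  vec t;      // m   per-subject sums of y
  vec ni;     // m   per-subject row counts
  double n;

  static SuffStats build(const mat& X, const vec& y, const uvec& subj,
                         unsigned int m) {
    SuffStats s;
    s.XtX = X.t() * X;
    s.Xty = X.t() * y;
    s.yty = dot(y, y);
    s.S.zeros(m, X.n_cols);
    s.t.zeros(m);
    s.ni.zeros(m);
    for (uword i = 0; i < X.n_rows; ++i) {
      s.S.row(subj(i)) += X.row(i);
      s.t(subj(i)) += y(i);
      s.ni(subj(i)) += 1.0;
    }
    s.n = (double)X.n_rows;
    return s;
  }

  // remove one row (for leave-one-out refits)
  void downdate(const rowvec& x, double yv, uword g) {
    XtX -= x.t() * x;
    Xty -= x.t() * yv;
    yty -= yv * yv;
    S.row(g) -= x;
    t(g) -= yv;
    ni(g) -= 1.0;
    n -= 1.0;
  }
  void update(const rowvec& x, double yv, uword g) {
    XtX += x.t() * x;
    Xty += x.t() * yv;
    yty += yv * yv;
    S.row(g) += x;
    t(g) += yv;
    ni(g) += 1.0;
    n += 1.0;
  }
};

struct FitResult {
  vec beta;
  vec u;          // per-subject BLUP intercepts
  double lambda, s2e, s2u, loglik;
  bool ok;
};

// profile log-likelihood at a given lambda; returns -inf if singular
double profile_ll(const SuffStats& s, double lambda, vec* beta_out,
                  double* rss_out) {
  vec c = lambda / (1.0 + lambda * s.ni);
  c.elem(find(s.ni <= 0.0)).zeros();
  mat A = s.XtX - s.S.t() * (s.S.each_col() % c);
  vec b = s.Xty - s.S.t() * (c % s.t);
  double q = s.yty - dot(c, square(s.t));
  vec beta;
  bool ok = solve(beta, A, b, solve_opts::no_approx);
  if (!ok) return -datum::inf;
  double rss = q - dot(b, beta);
  if (rss < 1e-12) rss = 1e-12;
  double ldet = 0.0;
  for (uword i = 0; i < s.ni.n_elem; ++i) {
    if (s.ni(i) > 0.0) ldet += std::log1p(lambda * s.ni(i));
  }
  double ll = -0.5 * s.n * (std::log(2.0 * datum::pi * rss / s.n) + 1.0) -
              0.5 * ldet;
  if (beta_out) *beta_out = beta;
  if (rss_out) *rss_out = rss;
  return ll;
}

// golden-section maximisation of the profile likelihood over log(lambda),
// compared against the lambda = 0 (pure fixed-effects / OLS) boundary.
// `lo`/`hi` bound log(lambda); leave-one-out sweeps pass a narrow window
// around the full-sample optimum (warm start).
FitResult fit_ml(const SuffStats& s, bool random_intercept,
                 double lo = -12.0, double hi = 16.0, int iters = 44) {
  FitResult r;
  r.ok = true;
  double best_lambda = 0.0;
  vec beta;
  double rss;
  double best_ll = profile_ll(s, 0.0, &beta, &rss);
  if (!std::isfinite(best_ll)) {
    r.ok = false;
    return r;
  }
  if (random_intercept) {
    const double gr = 0.6180339887498949;
    double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
    double f1 = profile_ll(s, std::exp(x1), nullptr, nullptr);
    double f2 = profile_ll(s, std::exp(x2), nullptr, nullptr);
    for (int it = 0; it < iters; ++it) {
      if (f1 < f2) {
        lo = x1; x1 = x2; f1 = f2;
        x2 = lo + gr * (hi - lo);
        f2 = profile_ll(s, std::exp(x2), nullptr, nullptr);
      } else {
        hi = x2; x2 = x1; f2 = f1;
        x1 = hi - gr * (hi - lo);
        f1 = profile_ll(s, std::exp(x1), nullptr, nullptr);
      }
    }
    double xb = 0.5 * (lo + hi);
    double lam = std::exp(xb);
    vec beta2;
    double rss2;
    double ll2 = profile_ll(s, lam, &beta2, &rss2);
    if (std::isfinite(ll2) && ll2 > best_ll) {
      best_ll = ll2;
      best_lambda = lam;
      beta = beta2;
      rss = rss2;
    }
  }
  r.lambda = best_lambda;
  r.beta = beta;
  r.s2e = rss / s.n;
  r.s2u = best_lambda * r.s2e;
  r.loglik = best_ll;
  // BLUP random intercepts: u_i = lambda * (t_i - s_i' beta) / (1 + lambda n_i)
  r.u = best_lambda * (s.t - s.S * beta) / (1.0 + best_lambda * s.ni);
  r.u.elem(find(s.ni <= 0.0)).zeros();
  return r;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_lme_fit(const arma::mat& X, const arma::vec& y,
                       const arma::uvec& subj, int n_subjects,
                       bool random_intercept) {
  SuffStats s = SuffStats::build(X, y, subj, (unsigned int)n_subjects);
  FitResult r = fit_ml(s, random_intercept);
  if (!r.ok) Rcpp::stop("singular fixed-effects design");
  return Rcpp::List::create(
      Rcpp::Named("beta") = r.beta, Rcpp::Named("u") = r.u,
      Rcpp::Named("sigma2_u") = r.s2u, Rcpp::Named("sigma2_e") = r.s2e,
      Rcpp::Named("lambda") = r.lambda, Rcpp::Named("loglik") = r.loglik);
}

// Inner leave-one-session-out sweep: for each candidate PC count k in
// `kgrid`, leave out each row in turn, refit on the rest (rank-one downdate
// of the sufficient statistics), and predict the held-out row using its
// subject's BLUP intercept when that subject still has training rows.
// Returns an n x length(kgrid) matrix of held-out predictions.
// [[Rcpp::export]]
arma::mat cpp_inner_loso(const arma::mat& P, const arma::vec& y,
                         const arma::uvec& subj, int n_subjects,
                         const arma::ivec& kgrid, bool intercept,
                         bool random_intercept) {
  const uword n = P.n_rows;
  arma::mat pred(n, kgrid.n_elem);
  pred.fill(datum::nan);
  for (uword gi = 0; gi < kgrid.n_elem; ++gi) {
    const uword k = (uword)kgrid(gi);
    mat X;
    if (intercept) {
      X = join_rows(ones<vec>(n), P.cols(0, k - 1));
    } else {
      X = P.cols(0, k - 1);
    }
    SuffStats s = SuffStats::build(X, y, subj, (unsigned int)n_subjects);
    // warm start: removing one row moves the optimum little, so the
    // leave-one-out searches run in a narrow window around the
    // full-sample estimate
    double lo = -12.0, hi = 16.0;
    int iters = 44;
    if (random_intercept) {
      FitResult full = fit_ml(s, true);
      if (full.ok) {
        double center = std::log(std::max(full.lambda, 1e-5));
        lo = std::max(-12.0, center - 2.5);
        hi = std::min(16.0, center + 2.5);
        iters = 26;
      }
    }
    for (uword i = 0; i < n; ++i) {
      rowvec xi = X.row(i);
      uword g = subj(i);
      s.downdate(xi, y(i), g);
      FitResult r = fit_ml(s, random_intercept, lo, hi, iters);
      if (r.ok) {
        double p = dot(xi, r.beta);
        if (s.ni(g) > 0.0) p += r.u(g);
        pred(i, gi) = p;
      }
      s.update(xi, y(i), g);
    }
  }
  return pred;
}
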