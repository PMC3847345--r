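// Gibbs sampler for Bayesian shrinkage regression (BayesA) with an
// optional latent-variable threshold extension for ordinal scores.
//
// Model:  y_i = b0 + sum_p X[i,p] * beta_p + e_i
//   beta_p ~ N(0, sigma2_m(marker(p)))     one variance per marker,
//   sigma2_m ~ scaled-Inv-chisq(nu_g, S2_g) shared by that marker's columns
//   e_i ~ N(0, sigma2_e), sigma2_e ~ scaled-Inv-chisq(nu_e, S2_e)
//   (nu_e = -2, S2_e = 0 gives the flat-prior update on sigma2_e)
// Ordinal mode: y latent, observed score s_i = m iff K_{m-1} < y_i <= K_m
//   with K_0 = -Inf, K_1 = 0, K_M = +Inf; free cut-points K_2..K_{M-1}
//   updated from their uniform full conditionals (Albert-Chib).
//
// All randomness comes from R's RNG so set.seed() governs the chain.
#include <Rcpp.h>
using namespace Rcpp;

// one draw from the scaled inverse chi-square: df * scale / chisq(df)
// [[Rcpp::export(name = ".cpp_rinvchisq")]]
NumericVector cpp_rinvchisq(int n, double df, double scale) {
  if (df <= 0) stop("scaled-inverse-chi-square draw needs positive df");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = df * scale / R::rchisq(df);
  return out;
}

static double rinvchisq1(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// truncated normal on (a, b] by inverse-CDF; falls back to clamping the
// mean when the interval mass underflows (extreme tails)
static double rtruncnorm1(double mu, double sd, double a, double b) {
  double pa = R_finite(a) ? R::pnorm(a, mu, sd, 1, 0) : 0.0;
  double pb = R_finite(b) ? R::pnorm(b, mu, sd, 1, 0) : 1.0;
  if (pb - pa < 1e-14) {
    // numerically empty interval: return the nearest admissible point
    double lo = R_finite(a) ? a : R_NegInf;
    double hi = R_finite(b) ? b : R_PosInf;
    double x = mu;
    double eps = 1e-8 * (1.0 + sd);
    if (x <= lo) x = lo + eps;
    if (x > hi) x = hi - eps;
    return x;
  }
  double u = R::runif(pa, pb);
  double x = R::qnorm(u, mu, sd, 1, 0);
  if (R_finite(a) && x <= a) x = a + 1e-12 * (1.0 + sd);
  if (R_finite(b) && x > b) x = b;
  return x;
}

// [[Rcpp::export(name = ".cpp_rtruncnorm")]]
NumericVector cpp_rtruncnorm(int n, double mu, double sd, double a, double b) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtruncnorm1(mu, sd, a, b);
  return out;
}

// regression coefficient full conditional:
//   beta ~ N( wtr / c, sigma2_e / c ),  c = wtw + sigma2_e / sigma2_b
// wtr is the inner product of the column with the partial residual
// (response minus all other terms). sigma2_b = Inf (flat prior, used for
// the intercept) drops the shrinkage term; wtw = 0 returns a prior draw.
static double draw_coef(double wtw, double wtr, double sigma2_e, double sigma2_b) {
  bool flat = !R_finite(sigma2_b);
  if (wtw <= 0.0) {
    if (flat) stop("flat-prior coefficient with empty column is improper");
    return R::norm_rand() * std::sqrt(sigma2_b);
  }
  double c = wtw + (flat ? 0.0 : sigma2_e / sigma2_b);
  double mean = wtr / c;
  double sd = std::sqrt(sigma2_e / c);
  return mean + sd * R::norm_rand();
}

// [[Rcpp::export(name = ".cpp_coef_draws")]]
NumericVector cpp_coef_draws(int n, double wtw, double wtr, double sigma2_e,
                             double sigma2_b) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_coef(wtw, wtr, sigma2_e, sigma2_b);
  return out;
}

// free cut-point update: K_m ~ U( max{y: s=m}, min{y: s=m+1} ) for
// m = 2..M-1; an empty category borrows the neighbouring cut-points as
// interval bounds so the chain stays defined.
static void draw_cutpoints(std::vector<double>& K, const NumericVector& y,
                           const IntegerVector& s, int M) {
  for (int m = 2; m <= M - 1; ++m) {
    double lo = R_NegInf, hi = R_PosInf;
    for (int i = 0; i < y.size(); ++i) {
      if (s[i] == m && y[i] > lo) lo = y[i];
      if (s[i] == m + 1 && y[i] < hi) hi = y[i];
    }
    if (!R_finite(lo)) lo = K[m - 1];          // category m empty
    if (!R_finite(hi)) hi = K[m + 1];          // category m+1 empty
    if (!R_finite(hi)) hi = lo + 1.0;          // m+1 == M and empty
    if (hi < lo) hi = lo;                      // safeguard; cannot occur with valid y
    K[m] = R::runif(lo, hi);
  }
}

// [[Rcpp::export(name = ".cpp_cutpoint_draw")]]
NumericVector cpp_cutpoint_draw(NumericVector K_free, NumericVector y,
                                IntegerVector s, int M) {
  // K_free holds K_1..K_{M-1}; returns an updated copy
  std::vector<double> K(M + 1);
  K[0] = R_NegInf; K[M] = R_PosInf;
  for (int m = 1; m <= M - 1; ++m) K[m] = K_free[m - 1];
  draw_cutpoints(K, y, s, M);
  NumericVector out(M - 1);
  for (int m = 1; m <= M - 1; ++m) out[m - 1] = K[m];
  return out;
}

// [[Rcpp::export(name = ".cpp_bayesa_gibbs")]]
List bayesa_gibbs(NumericMatrix X, IntegerVector marker_of_col,
                  NumericVector y_obs, IntegerVector score,
                  bool ordinal, int M,
                  double nu_g, double S2_g, double nu_e, double S2_e,
                  int n_iter, int burnin, int thin,
                  bool fix_sigma_e, bool save_latent) {
  const int n = X.nrow(), P = X.ncol();
  const int J = P > 0 ? max(marker_of_col) : 0;  // 1-based marker ids
  if (n_iter <= burnin) stop("total cycles must exceed burn-in");
  if (thin < 1) stop("thinning interval must be >= 1");
  const int ns = (n_iter - burnin) / thin;
  if (ns < 1) stop("MCMC schedule retains no samples");

  // residual-variance flat prior needs n + nu_e > 0
  if (!fix_sigma_e && nu_e + n <= 0)
    stop("too few observations for the residual-variance update (need n + nu_e > 0)");

  std::vector<double> wtw(P);
  for (int p = 0; p < P; ++p) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, p) * X(i, p);
    wtw[p] = s;
  }
  // columns per marker (for the per-marker variance df); columns must be
  // grouped contiguously by marker so the variance update can use ranges
  std::vector<int> Lj(J, 0);
  for (int p = 0; p < P; ++p) Lj[marker_of_col[p] - 1]++;
  for (int p = 1; p < P; ++p)
    if (marker_of_col[p] < marker_of_col[p - 1])
      stop("design columns must be grouped by marker");
  std::vector<int> col_start(J + 1, 0);
  for (int j = 0; j < J; ++j) col_start[j + 1] = col_start[j] + Lj[j];

  // state
  std::vector<double> beta(P, 0.0), sigma2_m(J, S2_g);
  double beta0 = 0.0, sigma2_e = 1.0;
  std::vector<double> K(M + 1);
  NumericVector y(n);
  if (ordinal) {
    K[0] = R_NegInf; K[1] = 0.0; K[M] = R_PosInf;
    for (int m = 2; m <= M - 1; ++m) K[m] = m - 1.0;  // equally spaced start
    for (int i = 0; i < n; ++i) {                     // category midpoints
      int s = score[i];
      double lo = (s == 1) ? -1.0 : K[s - 1];
      double hi = (s == M) ? K[M - 1] + 1.0 : K[s];
      y[i] = 0.5 * (lo + hi);
    }
  } else {
    y = clone(y_obs);
  }
  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - beta0;

  // retained samples
  NumericVector out_beta0(ns), out_sigma2e(ns);
  NumericMatrix out_beta(P, ns), out_sigma2m(J, ns);
  NumericMatrix out_cut(ordinal ? std::max(M - 1, 0) : 0, ordinal ? ns : 0);
  NumericMatrix out_latent((ordinal && save_latent) ? n : 0,
                           (ordinal && save_latent) ? ns : 0);

  RNGScope scope;
  int kept = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // -- latent variable update (ordinal mode)
    if (ordinal) {
      double sd = std::sqrt(sigma2_e);
      for (int i = 0; i < n; ++i) {
        double eta = y[i] - resid[i];
        int s = score[i];
        double ynew = rtruncnorm1(eta, sd, K[s - 1], K[s]);
        resid[i] += ynew - y[i];
        y[i] = ynew;
      }
    }
    // -- intercept (flat prior)
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += resid[i] + beta0;
      double b0new = draw_coef((double)n, s, sigma2_e, R_PosInf);
      double d = beta0 - b0new;
      for (int i = 0; i < n; ++i) resid[i] += d;
      beta0 = b0new;
    }
    // -- marker effects
    for (int p = 0; p < P; ++p) {
      double s2b = sigma2_m[marker_of_col[p] - 1];
      double wtr = 0.0;
      for (int i = 0; i < n; ++i) wtr += X(i, p) * resid[i];
      wtr += wtw[p] * beta[p];
      double bnew = draw_coef(wtw[p], wtr, sigma2_e, s2b);
      double d = beta[p] - bnew;
      if (d != 0.0) for (int i = 0; i < n; ++i) resid[i] += X(i, p) * d;
      beta[p] = bnew;
    }
    // -- cut-points (ordinal mode, M >= 3)
    if (ordinal && M >= 3) draw_cutpoints(K, y, score, M);
    // -- per-marker effect variances
    for (int j = 0; j < J; ++j) {
      double ssb = 0.0;
      for (int p = col_start[j]; p < col_start[j + 1]; ++p)
        ssb += beta[p] * beta[p];
      double df = nu_g + Lj[j];
      sigma2_m[j] = rinvchisq1(df, (nu_g * S2_g + ssb) / df);
    }
    // -- residual variance
    if (!fix_sigma_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += resid[i] * resid[i];
      double df = nu_e + n;
      sigma2_e = rinvchisq1(df, (nu_e * S2_e + sse) / df);
    }
    // -- retain
    if (iter > burnin && (iter - burnin) % thin == 0 && kept < ns) {
      out_beta0[kept] = beta0;
      out_sigma2e[kept] = sigma2_e;
      for (int p = 0; p < P; ++p) out_beta(p, kept) = beta[p];
      for (int j = 0; j < J; ++j) out_sigma2m(j, kept) = sigma2_m[j];
      if (ordinal) {
        for (int m = 1; m <= M - 1; ++m) out_cut(m - 1, kept) = K[m];
        if (save_latent)
          for (int i = 0; i < n; ++i) out_latent(i, kept) = y[i];
      }
      ++kept;
    }
  }

  List out = List::create(
    _["beta0"] = out_beta0, _["beta"] = out_beta,
    _["sigma2_marker"] = out_sigma2m, _["sigma2_e"] = out_sigma2e,
    _["retained"] = kept);
  if (ordinal) {
    out["cutpoints"] = out_cut;
    if (save_latent) out["latent"] = out_latent;
  }
  return out;
}
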