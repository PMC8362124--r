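// Gibbs sampler for the context-dependent latent-factor probit JSDM.
//
// Model: y_ij = 1(z_ij > 0), z_ij ~ N(mu_ij, 1),
//   mu_ij = x_i' beta_j + sum_h eta_ih (lambda_jh + lambdac_jh * c_i)
// where c_i is the (standardized) water-deficit value of plot i.
// Priors: beta_jk ~ N(0, beta_sd^2); eta_ih ~ N(0, 1); loadings under a
// multiplicative gamma process shrinkage prior shared between lambda and
// lambdac columns (local precisions phi, column precisions tau = cumprod(delta)).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Draw from standard normal truncated to (a, +Inf). Robust for large a
// (Robert 1995 exponential rejection); naive rejection when the region
// holds plenty of mass.
static double rtnorm_tail(double a) {
  double draw;
  if (a < 0.45) {
    do {
      draw = R::norm_rand();
    } while (draw <= a);
  } else {
    double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
    double x;
    do {
      x = a - std::log(R::unif_rand()) / lam;
    } while (std::log(R::unif_rand()) > -0.5 * (x - lam) * (x - lam));
    draw = x;
  }
  return draw;
}

// N(mu, 1) truncated to (0, Inf) when positive, to (-Inf, 0] otherwise.
static double rtnorm_probit(double mu, bool positive) {
  if (positive) return mu + rtnorm_tail(-mu);
  return mu - rtnorm_tail(mu);
}

// General truncated normal on the standardized scale (a, b), both finite.
static double rtnorm_interval(double a, double b) {
  // region comfortably straddling the mode: naive rejection
  if (a < 0.0 && b > 0.0 && (b - a) > 0.5) {
    double x;
    do {
      x = R::norm_rand();
    } while (x <= a || x >= b);
    return x;
  }
  // uniform accept-reject with the appropriate envelope constant
  double c = 0.0;
  if (a > 0.0) c = a * a;
  else if (b < 0.0) c = b * b;
  double x, u;
  do {
    x = a + (b - a) * R::unif_rand();
    u = R::unif_rand();
  } while (std::log(u) > 0.5 * (c - x * x));
  return x;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_rtruncnorm(int n, double mean, double sd,
                                   double lower, double upper) {
  if (sd <= 0.0) Rcpp::stop("`sd` must be positive");
  if (!(lower < upper)) Rcpp::stop("`lower` must be strictly below `upper`");
  Rcpp::NumericVector out(n);
  bool lo_fin = std::isfinite(lower), up_fin = std::isfinite(upper);
  double a = (lower - mean) / sd, b = (upper - mean) / sd;
  for (int i = 0; i < n; ++i) {
    double s;
    if (!lo_fin && !up_fin) s = R::norm_rand();
    else if (lo_fin && !up_fin) s = rtnorm_tail(a);
    else if (!lo_fin && up_fin) s = -rtnorm_tail(-b);
    else s = rtnorm_interval(a, b);
    out[i] = mean + sd * s;
  }
  return out;
}

static vec draw_mvn_prec(const mat& P, const vec& b, const char* where) {
  // sample from N(P^{-1} b, P^{-1}) via Cholesky of the precision
  mat U;
  if (!chol(U, P)) {
    Rcpp::stop("conditional precision not positive definite in %s update", where);
  }
  vec m = solve(trimatu(U), solve(trimatl(U.t()), b));
  vec zdraw(P.n_rows);
  for (uword i = 0; i < P.n_rows; ++i) zdraw(i) = R::norm_rand();
  return m + solve(trimatu(U), zdraw);
}

// [[Rcpp::export]]
Rcpp::List gibbs_chain(const arma::mat& Y, const arma::mat& X,
                       const arma::vec& cwd, int n_latent,
                       int n_burnin, int n_samples, int thin,
                       double beta_sd, double a1, double a2, double nu,
                       bool cwd_dependent, bool save_eta, bool prior_only) {
  const int n = X.n_rows, p = X.n_cols, S = Y.n_cols, k = n_latent;
  if (!prior_only && ((int)Y.n_rows != n || (int)cwd.n_elem != n))
    Rcpp::stop("dimension mismatch between Y, X and cwd");
  if (n_samples < 1 || thin < 1 || n_burnin < 0)
    Rcpp::stop("invalid MCMC schedule");

  // state (mildly dispersed random init so independent chains start apart)
  mat B(S, p), Lam(S, std::max(k, 1)), LamC(S, std::max(k, 1));
  mat H(n, std::max(k, 1)), Z(n, S, fill::zeros);
  mat phi(S, std::max(k, 1), fill::ones), phic(S, std::max(k, 1), fill::ones);
  vec delta(std::max(k, 1), fill::ones), tau(std::max(k, 1), fill::ones);
  B.imbue([]() { return 0.3 * R::norm_rand(); });
  Lam.imbue([]() { return 0.2 * R::norm_rand(); });
  if (cwd_dependent) LamC.imbue([]() { return 0.1 * R::norm_rand(); });
  else LamC.zeros();
  H.imbue([]() { return R::norm_rand(); });
  if (k == 0) { Lam.zeros(); LamC.zeros(); H.zeros(); }

  // constant pieces
  mat XtX = X.t() * X;
  mat Pbeta = XtX + eye(p, p) / (beta_sd * beta_sd);

  cube beta_draws(S, p, n_samples);
  cube lam_draws(S, std::max(k, 1), n_samples, fill::zeros);
  cube lamc_draws(S, std::max(k, 1), n_samples, fill::zeros);
  cube eta_draws;
  if (save_eta && k > 0) eta_draws.set_size(n, k, n_samples);

  const int total = n_burnin + n_samples * thin;
  int stored = 0;

  for (int iter = 0; iter < total; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();

    if (!prior_only) {
      // latent mean contribution of the factors
      mat LatMean(n, S, fill::zeros);
      mat Hc;
      if (k > 0) {
        Hc = H.each_col() % cwd;
        LatMean = H * Lam.t();
        if (cwd_dependent) LatMean += Hc * LamC.t();
      }
      mat Mu = X * B.t() + LatMean;

      // 1. truncated-normal update of latent scores z
      for (int j = 0; j < S; ++j)
        for (int i = 0; i < n; ++i)
          Z(i, j) = rtnorm_probit(Mu(i, j), Y(i, j) > 0.5);

      // 2. regression coefficients beta
      {
        mat R1 = Z - LatMean;          // n x S
        mat Xt_R1 = X.t() * R1;        // p x S
        for (int j = 0; j < S; ++j)
          B.row(j) = draw_mvn_prec(Pbeta, Xt_R1.col(j), "beta").t();
      }

      if (k > 0) {
        // 3. latent factor scores eta (prior N(0, I))
        mat R2 = Z - X * B.t();        // n x S
        mat A11 = Lam.t() * Lam;
        mat A12(k, k, fill::zeros), A22(k, k, fill::zeros);
        if (cwd_dependent) {
          A12 = Lam.t() * LamC;
          A22 = LamC.t() * LamC;
        }
        mat M1 = R2 * Lam;             // n x k
        mat M2 = cwd_dependent ? mat(R2 * LamC) : mat(n, k, fill::zeros);
        mat Ik = eye(k, k);
        for (int i = 0; i < n; ++i) {
          double c = cwd(i);
          mat P = Ik + A11;
          vec b = M1.row(i).t();
          if (cwd_dependent) {
            P += c * (A12 + A12.t()) + c * c * A22;
            b += c * M2.row(i).t();
          }
          H.row(i) = draw_mvn_prec(P, b, "eta").t();
        }

        // 4. joint update of (lambda_j, lambdac_j)
        Hc = H.each_col() % cwd;
        mat G11 = H.t() * H;
        mat T1 = H.t() * R2;           // k x S
        if (cwd_dependent) {
          mat G12 = H.t() * Hc;
          mat G22 = Hc.t() * Hc;
          mat T2 = Hc.t() * R2;
          mat G(2 * k, 2 * k);
          G.submat(0, 0, k - 1, k - 1) = G11;
          G.submat(0, k, k - 1, 2 * k - 1) = G12;
          G.submat(k, 0, 2 * k - 1, k - 1) = G12.t();
          G.submat(k, k, 2 * k - 1, 2 * k - 1) = G22;
          for (int j = 0; j < S; ++j) {
            vec dprec(2 * k);
            for (int h = 0; h < k; ++h) {
              dprec(h) = phi(j, h) * tau(h);
              dprec(k + h) = phic(j, h) * tau(h);
            }
            mat P = G + diagmat(dprec);
            vec b = join_cols(T1.col(j), T2.col(j));
            vec draw = draw_mvn_prec(P, b, "lambda");
            Lam.row(j) = draw.subvec(0, k - 1).t();
            LamC.row(j) = draw.subvec(k, 2 * k - 1).t();
          }
        } else {
          for (int j = 0; j < S; ++j) {
            vec dprec(k);
            for (int h = 0; h < k; ++h) dprec(h) = phi(j, h) * tau(h);
            mat P = G11 + diagmat(dprec);
            Lam.row(j) = draw_mvn_prec(P, T1.col(j), "lambda").t();
          }
        }
      }
    } else {
      // prior-only mode: sample beta, eta, loadings from their priors so
      // the hyperparameter sweep below operates on genuine prior draws
      B.imbue([&]() { return beta_sd * R::norm_rand(); });
      if (k > 0) {
        H.imbue([]() { return R::norm_rand(); });
        for (int j = 0; j < S; ++j)
          for (int h = 0; h < k; ++h) {
            Lam(j, h) = R::norm_rand() / std::sqrt(phi(j, h) * tau(h));
            if (cwd_dependent)
              LamC(j, h) = R::norm_rand() / std::sqrt(phic(j, h) * tau(h));
          }
      }
    }

    if (k > 0) {
      // 5. shrinkage hyperparameters (multiplicative gamma process)
      for (int j = 0; j < S; ++j)
        for (int h = 0; h < k; ++h) {
          double rate = 0.5 * (nu + tau(h) * Lam(j, h) * Lam(j, h));
          phi(j, h) = R::rgamma(0.5 * (nu + 1.0), 1.0 / rate);
          if (cwd_dependent) {
            double ratec = 0.5 * (nu + tau(h) * LamC(j, h) * LamC(j, h));
            phic(j, h) = R::rgamma(0.5 * (nu + 1.0), 1.0 / ratec);
          }
        }
      double rows_eff = cwd_dependent ? 2.0 * S : 1.0 * S;
      vec s(k);  // phi-weighted squared loadings per column
      for (int h = 0; h < k; ++h) {
        double sh = 0.0;
        for (int j = 0; j < S; ++j) {
          sh += phi(j, h) * Lam(j, h) * Lam(j, h);
          if (cwd_dependent) sh += phic(j, h) * LamC(j, h) * LamC(j, h);
        }
        s(h) = sh;
      }
      for (int l = 0; l < k; ++l) {
        double shape = (l == 0 ? a1 : a2) + 0.5 * rows_eff * (k - l);
        double rate = 1.0;
        for (int h = l; h < k; ++h) {
          double tau_minus = 1.0;
          for (int t = 0; t <= h; ++t)
            if (t != l) tau_minus *= delta(t);
          rate += 0.5 * tau_minus * s(h);
        }
        delta(l) = R::rgamma(shape, 1.0 / rate);
        tau = cumprod(delta);
      }
    }

    if (iter >= n_burnin && ((iter - n_burnin) % thin == 0)) {
      if (stored < n_samples) {
        beta_draws.slice(stored) = B;
        if (k > 0) {
          lam_draws.slice(stored) = Lam.cols(0, k - 1);
          lamc_draws.slice(stored) = LamC.cols(0, k - 1);
          if (save_eta) eta_draws.slice(stored) = H.cols(0, k - 1);
        }
        ++stored;
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("beta") = beta_draws,
      Rcpp::Named("lambda") = lam_draws,
      Rcpp::Named("lambda_cwd") = lamc_draws);
  if (save_eta && k > 0) out["eta"] = eta_draws;
  return out;
}
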