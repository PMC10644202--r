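#include <Rcpp.h>
using namespace Rcpp;

// Gibbs samplers for Bayesian whole-genome regression ("Bayesian alphabet").
// All randomness goes through R's RNG so set.seed() on the R side makes a
// chain bit-reproducible.

// scaled-inverse-chi-square draw: (ss + df0 * s0) / chisq(df0 + k)
static inline double rscinv(double ss, double df0, double s0, double k) {
  return (ss + df0 * s0) / R::rchisq(df0 + k);
}

// inverse-Gaussian(mu, lambda) via Michael–Schucany–Haas
static inline double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = R::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

enum Family { BRR = 0, BAYES_A = 1, BAYES_B = 2, BAYES_C = 3, BL = 4 };

static int family_code(const std::string &fam) {
  if (fam == "BRR") return BRR;
  if (fam == "BayesA") return BAYES_A;
  if (fam == "BayesB") return BAYES_B;
  if (fam == "BayesC") return BAYES_C;
  if (fam == "BL") return BL;
  stop("unknown family: %s", fam);
  return -1;
}

// [[Rcpp::export(name = ".gibbs_alphabet_cpp")]]
List gibbs_alphabet_cpp(NumericVector y, NumericMatrix X, std::string family,
                        int niter, int burnin, int thin,
                        double df_b, double scale_b,
                        double df_e, double scale_e,
                        double pi_excl,
                        double bl_shape, double bl_rate, double bl_lambda2_init,
                        bool fix_var_b, double var_b_fixed,
                        bool fix_var_e, double var_e_fixed,
                        IntegerVector active) {
  const int n = y.size();
  const int p = X.ncol();
  if (X.nrow() != n) stop("dimension mismatch between y and X");
  const int fam = family_code(family);

  // sufficient statistics per marker
  std::vector<double> x2(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    x2[j] = s;
  }

  double mu = mean(y);
  std::vector<double> b(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double varE = fix_var_e ? var_e_fixed : std::max(1e-8, var(y) * 0.5);
  double varB_common = fix_var_b ? var_b_fixed : scale_b; // BRR / BayesC
  std::vector<double> varB(p, fix_var_b ? var_b_fixed : scale_b); // per marker
  std::vector<int> incl(p, 1);
  std::vector<double> tau2(p, 1.0); // BL
  double lambda2 = bl_lambda2_init;

  const int nsave = (niter - burnin) / thin;
  std::vector<double> b_sum(p, 0.0);
  double mu_sum = 0.0;
  NumericVector varE_draws(nsave), varB_draws(nsave);
  std::vector<double> incl_freq(p, 0.0);
  int isave = 0;

  const double log_prior_odds = std::log((1.0 - pi_excl) / pi_excl);

  for (int it = 0; it < niter; ++it) {
    // intercept
    double se = 0.0;
    for (int i = 0; i < n; ++i) se += e[i];
    double mu_old = mu;
    mu = R::rnorm((se + n * mu) / n, std::sqrt(varE / n));
    double dmu = mu_old - mu;
    for (int i = 0; i < n; ++i) e[i] += dmu;

    // marker effects
    for (int k = 0; k < (int)active.size(); ++k) {
      int j = active[k];
      double vj;
      if (fam == BRR) vj = varB_common;
      else if (fam == BAYES_A) vj = varB[j];
      else if (fam == BAYES_B) vj = varB[j];
      else if (fam == BAYES_C) vj = varB_common;
      else vj = varE * tau2[j]; // BL
      if (vj < 1e-12) vj = 1e-12;

      // rhs = x_j' (partial residual) with own contribution restored
      const double *xj = &X(0, j);
      double *ep = e.data();
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += xj[i] * ep[i];
      double rhs = xe + x2[j] * b[j];

      double b_new;
      if (fam == BAYES_B || fam == BAYES_C) {
        // spike-and-slab indicator: x_j'r ~ N(0, v0) under exclusion,
        // N(0, v1) under inclusion
        double v0 = x2[j] * varE;
        double v1 = v0 + x2[j] * x2[j] * vj;
        double log_odds = log_prior_odds + 0.5 * (std::log(v0) - std::log(v1)) +
          0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double p_in = 1.0 / (1.0 + std::exp(-log_odds));
        incl[j] = (R::unif_rand() < p_in) ? 1 : 0;
        if (incl[j]) {
          double C = x2[j] + varE / vj;
          b_new = R::rnorm(rhs / C, std::sqrt(varE / C));
        } else {
          b_new = 0.0;
        }
      } else {
        double C = x2[j] + varE / vj;
        b_new = R::rnorm(rhs / C, std::sqrt(varE / C));
      }
      double db = b[j] - b_new;
      if (db != 0.0) for (int i = 0; i < n; ++i) ep[i] += xj[i] * db;
      b[j] = b_new;
    }

    // marker-variance updates
    if (!fix_var_b) {
      if (fam == BRR) {
        double ssb = 0.0;
        for (int j = 0; j < p; ++j) ssb += b[j] * b[j];
        varB_common = rscinv(ssb, df_b, scale_b, p);
      } else if (fam == BAYES_A) {
        for (int k = 0; k < (int)active.size(); ++k) {
          int j = active[k];
          varB[j] = rscinv(b[j] * b[j], df_b, scale_b, 1);
        }
      } else if (fam == BAYES_B) {
        for (int k = 0; k < (int)active.size(); ++k) {
          int j = active[k];
          if (incl[j]) varB[j] = rscinv(b[j] * b[j], df_b, scale_b, 1);
          else varB[j] = rscinv(0.0, df_b, scale_b, 0); // prior draw
        }
      } else if (fam == BAYES_C) {
        double ssb = 0.0; int nin = 0;
        for (int j = 0; j < p; ++j) if (incl[j]) { ssb += b[j] * b[j]; ++nin; }
        varB_common = rscinv(ssb, df_b, scale_b, nin);
      } else { // BL: Park–Casella latent scales + gamma-prior shrinkage rate
        double sum_tau2 = 0.0;
        for (int k = 0; k < (int)active.size(); ++k) {
          int j = active[k];
          double bj2 = std::max(b[j] * b[j], 1e-12);
          double m = std::sqrt(lambda2 * varE / bj2);
          double inv_tau2 = rinvgauss(m, lambda2);
          tau2[j] = 1.0 / std::max(inv_tau2, 1e-12);
          sum_tau2 += tau2[j];
        }
        lambda2 = R::rgamma(bl_shape + active.size(),
                            1.0 / (bl_rate + 0.5 * sum_tau2));
      }
    }

    // residual variance
    if (!fix_var_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      if (fam == BL) {
        // BL scales marker effects by varE; include b'D^-1 b term
        double ssb = 0.0;
        for (int k = 0; k < (int)active.size(); ++k) {
          int j = active[k];
          ssb += b[j] * b[j] / std::max(tau2[j], 1e-12);
        }
        varE = rscinv(sse + ssb, df_e, scale_e, n + active.size());
      } else {
        varE = rscinv(sse, df_e, scale_e, n);
      }
    }

    // store
    if (it >= burnin && ((it - burnin) % thin == 0) && isave < nsave) {
      mu_sum += mu;
      for (int j = 0; j < p; ++j) {
        b_sum[j] += b[j];
        incl_freq[j] += incl[j];
      }
      varE_draws[isave] = varE;
      if (fam == BRR || fam == BAYES_C) {
        varB_draws[isave] = varB_common;
      } else if (fam == BL) {
        double m = 0.0;
        for (int k = 0; k < (int)active.size(); ++k) m += varE * tau2[active[k]];
        varB_draws[isave] = active.size() ? m / active.size() : NA_REAL;
      } else {
        double m = 0.0;
        for (int k = 0; k < (int)active.size(); ++k) m += varB[active[k]];
        varB_draws[isave] = active.size() ? m / active.size() : NA_REAL;
      }
      ++isave;
    }
  }

  NumericVector beta_hat(p), pip(p);
  for (int j = 0; j < p; ++j) {
    beta_hat[j] = nsave ? b_sum[j] / nsave : NA_REAL;
    pip[j] = nsave ? incl_freq[j] / nsave : NA_REAL;
  }

  return List::create(
    _["mu"] = nsave ? mu_sum / nsave : NA_REAL,
    _["beta"] = beta_hat,
    _["inclusion_prob"] = pip,
    _["var_e_draws"] = varE_draws,
    _["var_b_draws"] = varB_draws,
    _["n_draws"] = nsave);
}
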