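// Metropolis-within-Gibbs sampler for the allele-frequency covariance model
// with isolating alpha terms. Loci are conditionally independent given the
// alpha parameters, so latent-frequency and mean blocks are proposed for all
// loci at once and accepted per locus.
//
// Parameterization:
//   Omega_ij = (1/alpha0) * exp(-(alphaD*D_ij + sum_k alphaE_k*E_k,ij)^alpha2)
//   Omega_ii = 1/alpha0 (+ 1e-8/alpha0 jitter)
//   theta_l ~ MVN(mu_l * 1, mu_l(1-mu_l) * Omega);  f = clamp(theta, 0, 1)
//   x_ls ~ Binomial(n_ls, f_ls)
// Priors: Exp(1) on alphaD and each alphaE, Gamma(1,1) on alpha0,
// Uniform(0.1, 2) on alpha2, Uniform(0,1) on mu_l.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// binomial log-likelihood of one locus column (without lchoose constant)
static double bin_col(const arma::vec &th, const arma::vec &x,
                      const arma::vec &n) {
  double s = 0.0;
  for (arma::uword i = 0; i < th.n_elem; ++i) {
    double f = th(i);
    if (f < 0.0) f = 0.0;
    if (f > 1.0) f = 1.0;
    double xi = x(i), ni = n(i);
    if (xi > 0.0) {
      if (f <= 0.0) return NEG_INF;
      s += xi * std::log(f);
    }
    if (ni - xi > 0.0) {
      if (f >= 1.0) return NEG_INF;
      s += (ni - xi) * std::log(1.0 - f);
    }
  }
  return s;
}

static bool build_chol(double a0, double aD, const arma::vec &aE, double a2,
                       const arma::mat &D, const std::vector<arma::mat> &E,
                       arma::mat &R, double &logdet) {
  arma::mat A = aD * D;
  for (size_t k = 0; k < E.size(); ++k) A += aE(k) * E[k];
  A.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  arma::mat Om = arma::exp(-arma::pow(A, a2)) / a0;
  Om.diag().fill(1.0 / a0 + 1e-8 / a0);
  if (!arma::chol(R, Om)) return false;
  logdet = 2.0 * arma::sum(arma::log(R.diag()));
  return true;
}

// per-locus quadratic forms (theta_l - mu_l)' Om^{-1} (theta_l - mu_l)
static arma::vec quads(const arma::mat &R, const arma::mat &C) {
  arma::mat Z = arma::solve(arma::trimatl(R.t()), C);
  return arma::sum(arma::square(Z), 0).t();
}

// [[Rcpp::export(name = ".alpha_mcmc_cpp")]]
List alpha_mcmc_cpp(const arma::mat &X, const arma::mat &Nm,
                    const arma::mat &D, List E_in, List init, int n_iter,
                    int adapt_end, int tune_interval, int thin,
                    double lchoose_const) {
  const int S = X.n_rows, L = X.n_cols;
  std::vector<arma::mat> E;
  for (int k = 0; k < E_in.size(); ++k)
    E.push_back(as<arma::mat>(E_in[k]));
  const int K = E.size();

  double a0 = as<double>(init["alpha0"]);
  double aD = as<double>(init["alphaD"]);
  arma::vec aE = as<arma::vec>(init["alphaE"]);
  double a2 = as<double>(init["alpha2"]);
  arma::vec mu = as<arma::vec>(init["mu"]);
  arma::mat Theta = as<arma::mat>(init["theta"]); // S x L

  arma::mat R;
  double logdet;
  if (!build_chol(a0, aD, aE, a2, D, E, R, logdet))
    stop("initial covariance not positive definite");
  arma::mat C = Theta;
  C.each_row() -= mu.t();
  arma::vec q = quads(R, C);
  arma::vec s = mu % (1.0 - mu);
  arma::vec bin(L);
  for (int l = 0; l < L; ++l) bin(l) = bin_col(Theta.col(l), X.col(l), Nm.col(l));

  // proposal scales and acceptance bookkeeping
  // blocks: 0 alpha0, 1 alphaD, 2..1+K alphaE_k, 2+K alpha2, 3+K mu, 4+K theta
  const int NB = 5 + K;
  arma::vec scale(NB);
  scale.fill(0.3);
  scale(2 + K) = 0.1;  // alpha2
  scale(3 + K) = 0.05; // mu
  scale(4 + K) = 0.1;  // theta
  arma::vec acc_win(NB, arma::fill::zeros), tot_win(NB, arma::fill::zeros);
  arma::vec acc_post(NB, arma::fill::zeros), tot_post(NB, arma::fill::zeros);

  const int n_save = n_iter / thin;
  arma::mat draws(n_save, 3 + K + 2); // alpha0, aD, aE..., a2, lp, iter
  int save_row = 0;

  RNGScope rng;

  // generic alpha-block update; returns delta-log-prior + jacobian handled by caller
  auto try_alpha = [&](double na0, double naD, const arma::vec &naE, double na2,
                       double dprior_jac, int block) {
    tot_win(block) += 1.0;
    arma::mat R2;
    double logdet2;
    if (!build_chol(na0, naD, naE, na2, D, E, R2, logdet2)) return false;
    arma::vec q2 = quads(R2, C);
    double dG = -0.5 * L * (logdet2 - logdet) -
                0.5 * arma::sum((q2 - q) / s);
    if (std::log(unif_rand()) < dG + dprior_jac) {
      R = R2;
      logdet = logdet2;
      q = q2;
      a0 = na0;
      aD = naD;
      aE = naE;
      a2 = na2;
      acc_win(block) += 1.0;
      return true;
    }
    return false;
  };

  for (int it = 1; it <= n_iter; ++it) {
    bool adapting = it <= adapt_end;

    // alpha0 (log-scale walk; Gamma(1,1) prior)
    {
      double na0 = a0 * std::exp(scale(0) * norm_rand());
      try_alpha(na0, aD, aE, a2, -(na0 - a0) + std::log(na0 / a0), 0);
    }
    // alphaD (log-scale walk; Exp(1) prior)
    {
      double naD = aD * std::exp(scale(1) * norm_rand());
      try_alpha(a0, naD, aE, a2, -(naD - aD) + std::log(naD / aD), 1);
    }
    // alphaE_k
    for (int k = 0; k < K; ++k) {
      arma::vec naE = aE;
      naE(k) = aE(k) * std::exp(scale(2 + k) * norm_rand());
      try_alpha(a0, aD, naE, a2, -(naE(k) - aE(k)) + std::log(naE(k) / aE(k)),
                2 + k);
    }
    // alpha2 (plain walk on (0.1, 2])
    {
      tot_win(2 + K) += 1.0;
      double na2 = a2 + scale(2 + K) * norm_rand();
      if (na2 > 0.1 && na2 <= 2.0) {
        arma::mat R2;
        double logdet2;
        if (build_chol(a0, aD, aE, na2, D, E, R2, logdet2)) {
          arma::vec q2 = quads(R2, C);
          double dG = -0.5 * L * (logdet2 - logdet) -
                      0.5 * arma::sum((q2 - q) / s);
          if (std::log(unif_rand()) < dG) {
            R = R2; logdet = logdet2; q = q2; a2 = na2;
            acc_win(2 + K) += 1.0;
          }
        }
      }
    }
    // mu blocks, all loci at once, accepted per locus
    {
      arma::vec mu2 = mu;
      for (int l = 0; l < L; ++l) mu2(l) += scale(3 + K) * norm_rand();
      arma::mat C2 = Theta;
      C2.each_row() -= mu2.t();
      arma::vec q2 = quads(R, C2);
      tot_win(3 + K) += L;
      for (int l = 0; l < L; ++l) {
        if (mu2(l) <= 0.0 || mu2(l) >= 1.0) continue;
        double s2 = mu2(l) * (1.0 - mu2(l));
        double d = -0.5 * S * (std::log(s2) - std::log(s(l))) -
                   0.5 * (q2(l) / s2 - q(l) / s(l));
        if (std::log(unif_rand()) < d) {
          mu(l) = mu2(l);
          s(l) = s2;
          q(l) = q2(l);
          C.col(l) = C2.col(l);
          acc_win(3 + K) += 1.0;
        }
      }
    }
    // theta blocks, all loci at once, accepted per locus
    {
      arma::mat Theta2 = Theta;
      for (int l = 0; l < L; ++l)
        for (int i = 0; i < S; ++i)
          Theta2(i, l) += scale(4 + K) * norm_rand();
      arma::mat C2 = Theta2;
      C2.each_row() -= mu.t();
      arma::vec q2 = quads(R, C2);
      tot_win(4 + K) += L;
      for (int l = 0; l < L; ++l) {
        double bin2 = bin_col(Theta2.col(l), X.col(l), Nm.col(l));
        if (bin2 == NEG_INF) continue;
        double d = -0.5 * (q2(l) - q(l)) / s(l) + bin2 - bin(l);
        if (std::log(unif_rand()) < d) {
          Theta.col(l) = Theta2.col(l);
          C.col(l) = C2.col(l);
          q(l) = q2(l);
          bin(l) = bin2;
          acc_win(4 + K) += 1.0;
        }
      }
    }

    // adaptation: tune toward 20-40% acceptance, frozen after adapt_end
    if (adapting && it % tune_interval == 0) {
      for (int b = 0; b < NB; ++b) {
        if (tot_win(b) > 0) {
          double rate = acc_win(b) / tot_win(b);
          if (rate > 0.4) scale(b) *= 1.3;
          else if (rate < 0.2) scale(b) /= 1.3;
          scale(b) = std::min(std::max(scale(b), 1e-4), 10.0);
        }
      }
      acc_win.zeros();
      tot_win.zeros();
    }
    if (!adapting) {
      acc_post += acc_win;
      tot_post += tot_win;
      acc_win.zeros();
      tot_win.zeros();
    }

    if (it % thin == 0 && save_row < n_save) {
      double lp = -0.5 * S * L * std::log(2.0 * M_PI) -
                  0.5 * (S * arma::sum(arma::log(s)) + L * logdet) -
                  0.5 * arma::sum(q / s) + arma::sum(bin) + lchoose_const -
                  aD - arma::sum(aE) - a0 + std::log(1.0 / 1.9);
      draws(save_row, 0) = a0;
      draws(save_row, 1) = aD;
      for (int k = 0; k < K; ++k) draws(save_row, 2 + k) = aE(k);
      draws(save_row, 2 + K) = a2;
      draws(save_row, 3 + K) = lp;
      draws(save_row, 4 + K) = it;
      ++save_row;
    }
  }

  arma::vec acc_rate(NB);
  for (int b = 0; b < NB; ++b)
    acc_rate(b) = tot_post(b) > 0 ? acc_post(b) / tot_post(b) : NA_REAL;

  return List::create(_["draws"] = draws, _["acc_rate"] = acc_rate,
                      _["scales"] = scale,
                      _["final_mu"] = mu, _["final_theta"] = Theta);
}
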