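// Adaptive random-walk Metropolis-within-Gibbs sampler for the hierarchical
// multinomial-logit discrete-choice model.
//
// Data layout: X is the standardized design matrix with one row per
// location, `nalt` consecutive rows per choice set, the *used* location
// first.  Each choice set belongs to one sampling unit (an individual owl in
// one season); each unit belongs to one hyper-group (species x season).
//
// Model:
//   P(used | set s) = exp(x_used' b_u) / sum_j exp(x_j' b_u)
//   b_u[t]  ~ Normal(mu_g[t], sigma_g[t])      (u in group g)
//   mu_g[t] ~ Normal(0, mu_prior_var)          (variance; vague by default)
//   sigma_g[t] ~ half-Normal(sigma_prior_scale)
//
// Updates: per-unit vector random-walk Metropolis on b_u; conjugate Gibbs on
// mu; log-scale random-walk Metropolis on sigma.  Proposal scales adapt
// during warmup by Robbins-Monro toward standard acceptance targets.
// Uses R's RNG so chains are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double unit_loglik(const arma::mat& X, const arma::vec& beta,
                          int row0, int nsets, int nalt) {
  // contiguous block of nsets*nalt rows starting at row0
  arma::vec u = X.rows(row0, row0 + nsets * nalt - 1) * beta;
  double ll = 0.0;
  for (int s = 0; s < nsets; ++s) {
    int a = s * nalt;
    double m = u[a];
    for (int j = 1; j < nalt; ++j) m = std::max(m, u[a + j]);
    double den = 0.0;
    for (int j = 0; j < nalt; ++j) den += std::exp(u[a + j] - m);
    ll += (u[a] - m) - std::log(den);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_run_chain(const arma::mat& X,
                   const arma::ivec& unit_nsets,   // sets per unit (contiguous)
                   const arma::ivec& unit_group,   // 0-based group of each unit
                   int nalt, int ngroup,
                   arma::mat beta,                 // U x T init
                   arma::mat mu,                   // G x T init
                   arma::mat sigma,                // G x T init (> 0)
                   int warmup, int ndraws,
                   double mu_prior_var, double sigma_prior_scale) {
  const int U = beta.n_rows, T = beta.n_cols, G = ngroup;
  // row offsets per unit
  std::vector<int> row0(U);
  {
    int acc = 0;
    for (int u = 0; u < U; ++u) { row0[u] = acc; acc += unit_nsets[u] * nalt; }
  }
  // group membership lists
  std::vector<std::vector<int>> members(G);
  for (int u = 0; u < U; ++u) members[unit_group[u]].push_back(u);

  arma::vec beta_step(U, arma::fill::value(0.2));
  arma::mat sig_step(G, T, arma::fill::value(0.4));
  arma::mat shift_step(G, T, arma::fill::value(0.5));
  arma::vec beta_ll(U);
  for (int u = 0; u < U; ++u)
    beta_ll[u] = unit_loglik(X, beta.row(u).t(), row0[u], unit_nsets[u], nalt);

  arma::cube mu_draws(G, T, ndraws), sigma_draws(G, T, ndraws);
  arma::cube beta_draws(U, T, ndraws);
  double beta_acc = 0.0, beta_try = 0.0;

  RNGScope scope;
  const int total = warmup + ndraws;
  for (int it = 0; it < total; ++it) {
    bool adapting = it < warmup;
    double gam = 1.0 / std::sqrt((double)(it + 1));

    // --- per-unit beta: vector RWM ---
    for (int u = 0; u < U; ++u) {
      int g = unit_group[u];
      arma::vec prop(T);
      for (int t = 0; t < T; ++t)
        prop[t] = beta(u, t) + beta_step[u] * norm_rand();
      double ll_prop = unit_loglik(X, prop, row0[u], unit_nsets[u], nalt);
      double lpr = 0.0;
      for (int t = 0; t < T; ++t) {
        lpr += R::dnorm(prop[t], mu(g, t), sigma(g, t), 1) -
               R::dnorm(beta(u, t), mu(g, t), sigma(g, t), 1);
      }
      double lr = ll_prop - beta_ll[u] + lpr;
      double acc = std::min(1.0, std::exp(lr));
      beta_try += 1.0;
      if (unif_rand() < acc) {
        beta.row(u) = prop.t();
        beta_ll[u] = ll_prop;
        beta_acc += 1.0;
      }
      if (adapting)
        beta_step[u] *= std::exp(gam * (acc - 0.234));
    }

    // --- mu: conjugate Gibbs per group x term ---
    for (int g = 0; g < G; ++g) {
      int n_g = (int)members[g].size();
      for (int t = 0; t < T; ++t) {
        double s2 = sigma(g, t) * sigma(g, t);
        double sum_b = 0.0;
        for (int k = 0; k < n_g; ++k) sum_b += beta(members[g][k], t);
        double prec = n_g / s2 + 1.0 / mu_prior_var;
        double mean = (sum_b / s2) / prec;
        mu(g, t) = mean + norm_rand() / std::sqrt(prec);
      }
    }

    // --- joint translation: shift mu_g[t] and all member betas together.
    // The beta | mu prior term is invariant, so the ratio is the likelihood
    // change plus the mu prior change; this lets the hyper-mean traverse its
    // (vague) prior quickly even when the likelihood is flat. ---
    for (int g = 0; g < G; ++g) {
      int n_g = (int)members[g].size();
      for (int t = 0; t < T; ++t) {
        double delta = shift_step(g, t) * norm_rand();
        double lr = R::dnorm(mu(g, t) + delta, 0.0,
                             std::sqrt(mu_prior_var), 1) -
                    R::dnorm(mu(g, t), 0.0, std::sqrt(mu_prior_var), 1);
        std::vector<double> ll_new(n_g);
        for (int k = 0; k < n_g; ++k) {
          int u = members[g][k];
          arma::vec prop = beta.row(u).t();
          prop[t] += delta;
          ll_new[k] = unit_loglik(X, prop, row0[u], unit_nsets[u], nalt);
          lr += ll_new[k] - beta_ll[u];
        }
        double acc = std::min(1.0, std::exp(lr));
        if (unif_rand() < acc) {
          mu(g, t) += delta;
          for (int k = 0; k < n_g; ++k) {
            int u = members[g][k];
            beta(u, t) += delta;
            beta_ll[u] = ll_new[k];
          }
        }
        if (adapting)
          shift_step(g, t) *= std::exp(gam * (acc - 0.234));
      }
    }

    // --- sigma: RWM on log scale, half-Normal(scale) prior ---
    for (int g = 0; g < G; ++g) {
      int n_g = (int)members[g].size();
      for (int t = 0; t < T; ++t) {
        double cur = sigma(g, t);
        double prop = cur * std::exp(sig_step(g, t) * norm_rand());
        double lp = 0.0;
        for (int k = 0; k < n_g; ++k) {
          double b = beta(members[g][k], t);
          lp += R::dnorm(b, mu(g, t), prop, 1) - R::dnorm(b, mu(g, t), cur, 1);
        }
        double sc2 = 2.0 * sigma_prior_scale * sigma_prior_scale;
        lp += (-prop * prop / sc2) - (-cur * cur / sc2);
        lp += std::log(prop) - std::log(cur);  // log-scale Jacobian
        double acc = std::min(1.0, std::exp(lp));
        if (unif_rand() < acc) sigma(g, t) = prop;
        if (adapting)
          sig_step(g, t) *= std::exp(gam * (acc - 0.44));
      }
    }

    if (!adapting) {
      int d = it - warmup;
      mu_draws.slice(d) = mu;
      sigma_draws.slice(d) = sigma;
      beta_draws.slice(d) = beta;
    }
  }

  return List::create(
    _["mu"] = mu_draws, _["sigma"] = sigma_draws, _["beta"] = beta_draws,
    _["beta_accept"] = beta_acc / std::max(beta_try, 1.0),
    _["beta_step"] = beta_step);
}
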