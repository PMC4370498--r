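#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical multi-species
// occupancy model.  Latent occurrence z is Gibbs-updated from its full
// conditional; species-level effects (occupancy intercept a_k, detection
// intercept b_k, distance slopes beta_kc) and the community
// hyper-parameters are updated by scalar adaptive random-walk Metropolis.
// Proposal scales adapt toward 30-45% acceptance during burn-in only, so
// the kept draws come from a fixed-kernel chain (detailed balance holds).
//
// Detection is constant within species (p_k = plogis(b_k)), so the
// observation likelihood depends on the data only through the per-site
// detection totals and survey counts.  Uses R's RNG throughout: chains are
// reproducible under set.seed() on the R side.

static inline double inv_logit(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// log density of the bivariate normal intercept pair (a, b)
static inline double log_bvn(double a, double b, double mu_a, double mu_b,
                             double sig_a, double sig_b, double rho) {
  if (sig_a <= 0.0 || sig_b <= 0.0 || std::fabs(rho) >= 1.0)
    return R_NegInf;
  double za = (a - mu_a) / sig_a, zb = (b - mu_b) / sig_b;
  double om = 1.0 - rho * rho;
  return -std::log(2.0 * M_PI) - std::log(sig_a) - std::log(sig_b)
         - 0.5 * std::log(om)
         - (za * za - 2.0 * rho * za * zb + zb * zb) / (2.0 * om);
}

// z-prior log likelihood for one species: sum_i z log psi + (1-z) log(1-psi)
// with psi_i = inv_logit(a + eta_i)
static double occ_loglik(double a, const std::vector<double>& eta,
                         const std::vector<int>& z) {
  double ll = 0.0;
  for (size_t i = 0; i < eta.size(); ++i) {
    double lp = a + eta[i];
    // log(psi) = -log1p(exp(-lp)); log(1-psi) = -log1p(exp(lp))
    if (z[i] == 1)
      ll += -R::log1pexp(-lp);
    else
      ll += -R::log1pexp(lp);
  }
  return ll;
}

struct AdaptScale {
  double ls;     // log proposal sd
  int tries, acc;
  AdaptScale() : ls(std::log(0.5)), tries(0), acc(0) {}
  void tally(bool accepted) { ++tries; if (accepted) ++acc; }
  void adapt(int batch) {
    if (tries == 0) return;
    double rate = (double)acc / tries;
    double delta = std::min(0.1, 1.0 / std::sqrt((double)batch + 1.0));
    if (rate > 0.375) ls += delta; else ls -= delta;
    ls = std::max(-8.0, std::min(4.0, ls));
    tries = 0; acc = 0;
  }
  double sd() const { return std::exp(ls); }
};

// [[Rcpp::export]]
List occ_mcmc_cpp(IntegerMatrix dets, IntegerVector J, NumericMatrix X,
                  NumericVector a_init, NumericVector b_init,
                  NumericMatrix beta_init, NumericVector hyper_init,
                  int n_iter, int n_burn, int n_keep,
                  double prior_mean_sd, double prior_sigma_max,
                  bool update_hyper, bool update_b) {
  const int S = dets.nrow(), K = dets.ncol(), C = X.ncol();
  const int n_hyper = 5 + 2 * C;
  const int n_par = n_hyper + 2 * K + K * C;

  // state
  std::vector<double> a(a_init.begin(), a_init.end());
  std::vector<double> b(b_init.begin(), b_init.end());
  std::vector< std::vector<double> > beta(K, std::vector<double>(C));
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c) beta[k][c] = beta_init(k, c);
  double mu_a = hyper_init[0], sig_a = hyper_init[1];
  double mu_b = hyper_init[2], sig_b = hyper_init[3];
  double rho = hyper_init[4];
  std::vector<double> mu_beta(C), sig_beta(C);
  for (int c = 0; c < C; ++c) {
    mu_beta[c] = hyper_init[5 + c];
    sig_beta[c] = hyper_init[5 + C + c];
  }

  // cached linear predictors eta_k = X beta_k and latent z
  std::vector< std::vector<double> > eta(K, std::vector<double>(S, 0.0));
  std::vector< std::vector<int> > z(K, std::vector<int>(S));
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < S; ++i) {
      double e = 0.0;
      for (int c = 0; c < C; ++c) e += X(i, c) * beta[k][c];
      eta[k][i] = e;
      z[k][i] = dets(i, k) > 0 ? 1 : 0;   // start at the forced minimum
    }
  }

  std::vector<AdaptScale> sc_a(K), sc_b(K), sc_beta(K * C), sc_h(n_hyper);
  std::vector<AdaptScale> sc_nc(C);   // non-centered slope-block moves

  NumericMatrix out(n_keep, n_par);
  IntegerMatrix zout(n_keep, S * K);
  std::vector<double> ll_cur(K);  // per-species z-prior loglik cache
  const int thin = std::max(1, (n_iter - n_burn) / n_keep);
  int kept = 0, batch = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    const bool adapting = it < n_burn;

    for (int k = 0; k < K; ++k) {
      const double p_k = inv_logit(b[k]);
      const double l1p = std::log1p(-p_k);

      // --- Gibbs update of z_ik ---
      for (int i = 0; i < S; ++i) {
        if (dets(i, k) > 0) { z[k][i] = 1; continue; }
        double psi = inv_logit(a[k] + eta[k][i]);
        double num = psi * std::exp(J[i] * l1p);
        double pr = num / (num + (1.0 - psi));
        z[k][i] = (unif_rand() < pr) ? 1 : 0;
      }

      // sufficient statistics of the detection likelihood given z
      double D_k = 0.0, Jz_k = 0.0;
      for (int i = 0; i < S; ++i)
        if (z[k][i] == 1) { D_k += dets(i, k); Jz_k += J[i]; }

      // --- occupancy intercept a_k ---
      // the z-prior log likelihood is cached across the a_k and beta_kc
      // updates and refreshed on every accepted move
      double ll_occ = occ_loglik(a[k], eta[k], z[k]);
      {
        double cur_ll = ll_occ
          + log_bvn(a[k], b[k], mu_a, mu_b, sig_a, sig_b, rho);
        double prop = a[k] + norm_rand() * sc_a[k].sd();
        double prop_occ = occ_loglik(prop, eta[k], z[k]);
        double prop_ll = prop_occ
          + log_bvn(prop, b[k], mu_a, mu_b, sig_a, sig_b, rho);
        bool accept = std::log(unif_rand()) < prop_ll - cur_ll;
        if (accept) { a[k] = prop; ll_occ = prop_occ; }
        if (adapting) sc_a[k].tally(accept);
      }

      // --- detection intercept b_k ---
      if (update_b) {
        double cur_ll = D_k * std::log(p_k) + (Jz_k - D_k) * l1p
          + log_bvn(a[k], b[k], mu_a, mu_b, sig_a, sig_b, rho);
        double prop = b[k] + norm_rand() * sc_b[k].sd();
        double pp = inv_logit(prop);
        double prop_ll = D_k * std::log(pp) + (Jz_k - D_k) * std::log1p(-pp)
          + log_bvn(a[k], prop, mu_a, mu_b, sig_a, sig_b, rho);
        bool accept = std::log(unif_rand()) < prop_ll - cur_ll;
        if (accept) b[k] = prop;
        if (adapting) sc_b[k].tally(accept);
      }

      // --- slopes beta_kc ---
      for (int c = 0; c < C; ++c) {
        double cur_ll = ll_occ
          + R::dnorm(beta[k][c], mu_beta[c], sig_beta[c], 1);
        double prop = beta[k][c] + norm_rand() * sc_beta[k * C + c].sd();
        double diff = prop - beta[k][c];
        std::vector<double> eta_prop(S);
        for (int i = 0; i < S; ++i) eta_prop[i] = eta[k][i] + X(i, c) * diff;
        double prop_occ = occ_loglik(a[k], eta_prop, z[k]);
        double prop_ll = prop_occ
          + R::dnorm(prop, mu_beta[c], sig_beta[c], 1);
        bool accept = std::log(unif_rand()) < prop_ll - cur_ll;
        if (accept) { beta[k][c] = prop; eta[k] = eta_prop; ll_occ = prop_occ; }
        if (adapting) sc_beta[k * C + c].tally(accept);
      }
      ll_cur[k] = ll_occ;
    }

    // --- community hyper-parameters ---
    // several sweeps per iteration: these updates cost O(K) against the
    // O(S K) species updates, and the community-level scales and rho are
    // the slowest-mixing parameters under scalar random walks
    if (update_hyper) for (int sweep = 0; sweep < 3; ++sweep) {
      // intercept block: mu_a, sig_a, mu_b, sig_b, rho
      double* pars[5] = { &mu_a, &sig_a, &mu_b, &sig_b, &rho };
      for (int h = 0; h < 5; ++h) {
        double cur = *pars[h];
        double prop = cur + norm_rand() * sc_h[h].sd();
        bool ok = true;
        if ((h == 1 || h == 3) && (prop <= 0.0 || prop > prior_sigma_max))
          ok = false;
        if (h == 4 && std::fabs(prop) >= 1.0) ok = false;
        if (ok) {
          double cur_ll = 0.0, prop_ll = 0.0;
          *pars[h] = cur;
          for (int k = 0; k < K; ++k)
            cur_ll += log_bvn(a[k], b[k], mu_a, mu_b, sig_a, sig_b, rho);
          *pars[h] = prop;
          for (int k = 0; k < K; ++k)
            prop_ll += log_bvn(a[k], b[k], mu_a, mu_b, sig_a, sig_b, rho);
          *pars[h] = cur;
          if (h == 0 || h == 2) {  // normal prior on the means
            cur_ll += R::dnorm(cur, 0.0, prior_mean_sd, 1);
            prop_ll += R::dnorm(prop, 0.0, prior_mean_sd, 1);
          }
          bool accept = std::log(unif_rand()) < prop_ll - cur_ll;
          if (accept) *pars[h] = prop;
          if (adapting) sc_h[h].tally(accept);
        } else if (adapting) sc_h[h].tally(false);
      }
      // slope hyper-parameters, one covariate at a time
      for (int c = 0; c < C; ++c) {
        {  // mu_beta[c]
          double cur = mu_beta[c];
          double prop = cur + norm_rand() * sc_h[5 + c].sd();
          double cur_ll = R::dnorm(cur, 0.0, prior_mean_sd, 1);
          double prop_ll = R::dnorm(prop, 0.0, prior_mean_sd, 1);
          for (int k = 0; k < K; ++k) {
            cur_ll += R::dnorm(beta[k][c], cur, sig_beta[c], 1);
            prop_ll += R::dnorm(beta[k][c], prop, sig_beta[c], 1);
          }
          bool accept = std::log(unif_rand()) < prop_ll - cur_ll;
          if (accept) mu_beta[c] = prop;
          if (adapting) sc_h[5 + c].tally(accept);
        }
        {  // sig_beta[c]
          double cur = sig_beta[c];
          double prop = cur + norm_rand() * sc_h[5 + C + c].sd();
          if (prop > 0.0 && prop <= prior_sigma_max) {
            double cur_ll = 0.0, prop_ll = 0.0;
            for (int k = 0; k < K; ++k) {
              cur_ll += R::dnorm(beta[k][c], mu_beta[c], cur, 1);
              prop_ll += R::dnorm(beta[k][c], mu_beta[c], prop, 1);
            }
            bool accept = std::log(unif_rand()) < prop_ll - cur_ll;
            if (accept) sig_beta[c] = prop;
            if (adapting) sc_h[5 + C + c].tally(accept);
          } else if (adapting) sc_h[5 + C + c].tally(false);
        }
      }
    }

    // --- interweaved non-centered move per slope block ---
    // Scalar updates of (mu_beta_c, sig_beta_c) mix poorly when the data
    // say little about covariate c (the hierarchical funnel: sig -> 0
    // pins every beta_kc to mu_beta_c).  This extra move reparameterizes
    // to eta_kc = (beta_kc - mu)/sig, holds the eta fixed, and proposes
    // (mu', log sig') jointly, rescaling every species slope
    // deterministically; only the z-prior likelihood and the hyper-priors
    // enter the ratio (the eta-normal terms are invariant, and the
    // log-scale proposal for the uniform-prior sig contributes the
    // Jacobian log sig' - log sig).
    if (update_hyper) for (int c = 0; c < C; ++c) {
      double step = sc_nc[c].sd();
      double mu_prop = mu_beta[c] + norm_rand() * step;
      double sig_prop = sig_beta[c] * std::exp(norm_rand() * step);
      if (sig_prop <= 0.0 || sig_prop > prior_sigma_max) {
        if (adapting) sc_nc[c].tally(false);
        continue;
      }
      double lr = R::dnorm(mu_prop, 0.0, prior_mean_sd, 1)
        - R::dnorm(mu_beta[c], 0.0, prior_mean_sd, 1)
        + std::log(sig_prop) - std::log(sig_beta[c]);
      double ratio = sig_prop / sig_beta[c];
      std::vector< std::vector<double> > eta_prop(K);
      std::vector<double> beta_prop(K), ll_prop(K);
      for (int k = 0; k < K; ++k) {
        beta_prop[k] = mu_prop + (beta[k][c] - mu_beta[c]) * ratio;
        double diff = beta_prop[k] - beta[k][c];
        eta_prop[k].resize(S);
        for (int i = 0; i < S; ++i)
          eta_prop[k][i] = eta[k][i] + X(i, c) * diff;
        ll_prop[k] = occ_loglik(a[k], eta_prop[k], z[k]);
        lr += ll_prop[k] - ll_cur[k];   // current side from the cache
      }
      bool accept = std::log(unif_rand()) < lr;
      if (accept) {
        mu_beta[c] = mu_prop;
        sig_beta[c] = sig_prop;
        for (int k = 0; k < K; ++k) {
          beta[k][c] = beta_prop[k];
          eta[k] = eta_prop[k];
          ll_cur[k] = ll_prop[k];
        }
      }
      if (adapting) sc_nc[c].tally(accept);
    }

    // batch adaptation of proposal scales (burn-in only)
    if (adapting && (it + 1) % 50 == 0) {
      ++batch;
      for (int k = 0; k < K; ++k) {
        sc_a[k].adapt(batch);
        sc_b[k].adapt(batch);
        for (int c = 0; c < C; ++c) sc_beta[k * C + c].adapt(batch);
      }
      for (int h = 0; h < n_hyper; ++h) sc_h[h].adapt(batch);
      for (int c = 0; c < C; ++c) sc_nc[c].adapt(batch);
    }

    // record thinned post burn-in draws
    if (it >= n_burn && ((it - n_burn) % thin == thin - 1) && kept < n_keep) {
      int col = 0;
      out(kept, col++) = mu_a;  out(kept, col++) = sig_a;
      out(kept, col++) = mu_b;  out(kept, col++) = sig_b;
      out(kept, col++) = rho;
      for (int c = 0; c < C; ++c) out(kept, col++) = mu_beta[c];
      for (int c = 0; c < C; ++c) out(kept, col++) = sig_beta[c];
      for (int k = 0; k < K; ++k) out(kept, col++) = a[k];
      for (int k = 0; k < K; ++k) out(kept, col++) = b[k];
      for (int k = 0; k < K; ++k)
        for (int c = 0; c < C; ++c) out(kept, col++) = beta[k][c];
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < S; ++i) zout(kept, k * S + i) = z[k][i];
      ++kept;
    }
  }

  return List::create(_["params"] = out, _["z"] = zout,
                      _["n_kept"] = kept, _["thin"] = thin);
}
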