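#include <Rcpp.h>
using namespace Rcpp;

// Truncated-sum negative log likelihood of the negative-binomial N-mixture
// model.  For each site the latent abundance N is marginalized over
// max(y) .. K:
//   log sum_N  NB(N; lam_i, alpha) * prod_j Binom(y_ij; N, p)
// The binomial-coefficient table Lch[N, i] = sum_j lchoose(N, y_ij) is
// parameter-free and precomputed once per fit (R side).  The NB log pmf is
// advanced by its ratio recurrence
//   log f(N+1) = log f(N) + log(N + alpha) - log(N + 1) + log(lam/(lam+alpha))
// so an evaluation costs flat arithmetic per (site, N), not a lgamma call.
//
// theta = (alpha0, beta_1..C, log alpha, eta); returns +1e10 on overflow so
// optimizers treat bad regions as uphill.

// [[Rcpp::export]]
double nmix_nll_cpp(NumericVector theta, NumericMatrix X, NumericMatrix Lch,
                    NumericVector Tot, NumericVector J, IntegerVector maxy,
                    int K) {
  const int S = X.nrow(), C = X.ncol();
  const double alpha = std::exp(theta[C + 1]);
  const double eta = theta[C + 2];
  if (!std::isfinite(alpha) || alpha <= 0.0) return 1e10;
  const double log_p = -std::log1p(std::exp(-eta));   // log plogis(eta)
  const double log_1mp = -std::log1p(std::exp(eta));  // log(1 - p)
  if (!std::isfinite(log_p) || !std::isfinite(log_1mp)) return 1e10;

  // shared across sites: log(N + alpha), log(N + 1) for N = 0..K-1
  std::vector<double> log_Na(K), log_N1(K);
  for (int N = 0; N < K; ++N) {
    log_Na[N] = std::log(N + alpha);
    log_N1[N] = std::log(N + 1.0);
  }

  std::vector<double> buf(K + 1);
  double nll = 0.0;
  for (int i = 0; i < S; ++i) {
    double lin = theta[0];
    for (int c = 0; c < C; ++c) lin += X(i, c) * theta[1 + c];
    double lam = std::exp(lin);
    if (!std::isfinite(lam)) return 1e10;
    const double log_ratio = std::log(lam) - std::log(lam + alpha);
    // log NB(0; lam, alpha) = alpha * log(alpha / (alpha + lam))
    double lp_nb = alpha * (std::log(alpha) - std::log(alpha + lam));
    const double obs = Tot[i] * log_p - Tot[i] * log_1mp;  // N-free part
    double best = R_NegInf;
    // terms past the mode eventually decay geometrically; once the
    // summand has fallen 60 nats below the running max for 30 straight
    // values of N the remaining tail is numerically zero and the sum can
    // stop early (the dominant saving when K is large)
    int drop = 0, N_stop = K;
    for (int N = 0; N <= K; ++N) {
      double t = (N >= maxy[i])
        ? lp_nb + Lch(N, i) + obs + N * J[i] * log_1mp
        : R_NegInf;
      buf[N] = t;
      if (t > best) { best = t; drop = 0; }
      else if (t < best - 60.0 && ++drop >= 30) { N_stop = N; break; }
      if (N < K) lp_nb += log_Na[N] - log_N1[N] + log_ratio;
    }
    if (!std::isfinite(best)) return 1e10;
    double s = 0.0;
    for (int N = maxy[i]; N <= N_stop; ++N) s += std::exp(buf[N] - best);
    nll -= best + std::log(s);
  }
  if (!std::isfinite(nll)) return 1e10;
  return nll;
}
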