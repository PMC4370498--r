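#' Community-level hyper-parameters of the multi-species occupancy model
#'
#' Species-level effects are random draws from community distributions:
#' occupancy and detection intercepts `(a_k, b_k)` are jointly bivariate
#' normal with means `mu_a`, `mu_b`, SDs `sigma_a`, `sigma_b` and
#' correlation `rho` (prevalent species tend to be easier to detect);
#' each distance coefficient `beta_ck ~ N(mu_beta[c], sigma_beta[c])`.
#' Richness conclusions rest on the `mu_beta` hyper-means: with
#' standardized distances, a negative `mu_beta[c]` means community
#' occupancy — and hence derived richness — increases with proximity to
#' feature class `c`.
#'
#' @param mu_a,sigma_a hyper-mean/SD of the occupancy intercepts
#'   (logit scale).
#' @param mu_b,sigma_b hyper-mean/SD of the detection intercepts
#'   (logit scale).
#' @param rho correlation between a species' occupancy and detection
#'   intercepts, in `[-1, 1]`.
#' @param mu_beta,sigma_beta length-5 hyper-means/SDs of the distance
#'   coefficients, ordered as `covariate_classes()`.
#' @return An object of class `community_hyperparams`.
#' @export
community_hyperparams <- function(mu_a = 0, sigma_a = 1,
                                  mu_b = 0, sigma_b = 1,
                                  rho = 0,
                                  mu_beta = rep(0, 5),
                                  sigma_beta = rep(1, 5)) {
  if (any(c(sigma_a, sigma_b, sigma_beta) < 0))
    stop("parameter error: hyper SDs must be nonnegative")
  if (abs(rho) > 1) stop("parameter error: |rho| must be <= 1")
  if (length(mu_beta) != length(sigma_beta))
    stop("mu_beta and sigma_beta must have equal length")
  structure(list(mu_a = mu_a, sigma_a = sigma_a, mu_b = mu_b,
                 sigma_b = sigma_b, rho = rho,
                 mu_beta = as.numeric(mu_beta),
                 sigma_beta = as.numeric(sigma_beta)),
            class = "community_hyperparams")
}

#' Occupancy probability from a species' logit-linear model
#'
#' `logit(psi) = a + beta_1 x_1 + ... + beta_5 x_5` over the standardized
#' distances to the five feature classes, inverted to a probability.
#'
#' @param effects list with `a` (occupancy intercept, logit scale) and
#'   `beta` (coefficient vector).
#' @param x standardized covariate vector, same length as `beta`.
#' @return occupancy probability in (0, 1).
#' @export
occupancy_probability <- function(effects, x) {
  if (length(x) != length(effects$beta))
    stop("covariate vector length must match number of coefficients")
  eta <- effects$a + sum(effects$beta * x)
  if (!is.finite(eta)) {
    if (is.na(eta)) stop("non-finite linear predictor")
    return(as.numeric(eta > 0))
  }
  plogis(eta)
}

#' Full conditional of the latent occurrence indicator z
#'
#' The Gibbs step for one (site, species) cell. A species detected at least
#' once is certainly present; otherwise occupancy given J detection-free
#' surveys is `psi (1-p)^J / (psi (1-p)^J + (1-psi))`.
#'
#' @param psi occupancy probability.
#' @param p per-survey detection probability.
#' @param n_surveys number of surveys J at the site.
#' @param n_detections surveys with a detection (0..J).
#' @return probability that z = 1.
#' @export
z_full_conditional <- function(psi, p, n_surveys, n_detections) {
  stopifnot(psi >= 0, psi <= 1, p >= 0, p <= 1, n_detections >= 0)
  if (n_detections > n_surveys)
    stop("logic error: more detections than surveys")
  if (n_detections > 0) return(1)
  num <- psi * (1 - p)^n_surveys
  den <- num + (1 - psi)
  if (den == 0) return(1)   # psi = 1: present with certainty
  num / den
}

#' Prior configuration for the community occupancy model
#'
#' Weakly informative defaults on the logit scale: hyper-means
#' `~ Normal(0, mean_sd)`, hyper-SDs `~ Uniform(0, sigma_max)`,
#' `rho ~ Uniform(-1, 1)`.
#'
#' @param mean_sd prior SD of every hyper-mean (default 10).
#' @param sigma_max upper bound of the uniform prior on every hyper-SD
#'   (default 10).
#' @return list of class `occupancy_priors`.
#' @export
occupancy_priors <- function(mean_sd = 10, sigma_max = 10) {
  stopifnot(mean_sd > 0, sigma_max > 0)
  structure(list(mean_sd = mean_sd, sigma_max = sigma_max),
            class = "occupancy_priors")
}

log_bvn <- function(a, b, mu_a, mu_b, sig_a, sig_b, rho) {
  # bivariate normal log density of the intercept pair
  if (sig_a <= 0 || sig_b <= 0 || abs(rho) >= 1) return(-Inf)
  za <- (a - mu_a) / sig_a
  zb <- (b - mu_b) / sig_b
  -log(2 * pi) - log(sig_a) - log(sig_b) - 0.5 * log(1 - rho^2) -
    (za^2 - 2 * rho * za * zb + zb^2) / (2 * (1 - rho^2))
}

#' Log joint density of the full hierarchical occupancy model
#'
#' Sums, term by term: the Bernoulli observation log-likelihood over
#' surveyed replicates given `z`; the `z` log-prior under `psi`; the
#' species-effects log-density under the bivariate-normal (intercepts) and
#' normal (slopes) hyper-distributions; and the hyper-prior log-densities.
#' A state with `z = 0` at a site where the species was detected has
#' density zero (`-Inf`).
#'
#' @param state list with `z` (site x species binary matrix), `a`, `b`
#'   (length-K intercept vectors), `beta` (K x 5 slope matrix), and
#'   `hyper` (a [community_hyperparams]).
#' @param data a `detection_history`.
#' @param covs a `site_covariates_std`.
#' @param priors an [occupancy_priors].
#' @return log joint density (finite for interior states).
#' @export
occupancy_log_joint <- function(state, data, covs, priors = occupancy_priors()) {
  dets <- detection_totals(data)
  J <- n_surveys(data)
  K <- ncol(dets)
  h <- state$hyper
  lj <- 0
  for (k in seq_len(K)) {
    psi <- plogis(state$a[k] + as.numeric(covs$X %*% state$beta[k, ]))
    p <- plogis(state$b[k])
    z <- state$z[, k]
    if (any(z == 0 & dets[, k] > 0)) return(-Inf)
    # observation likelihood at occupied sites; fixed zeros contribute 1
    lj <- lj + sum(z * (dets[, k] * log(p) + (J - dets[, k]) * log1p(-p)))
    lj <- lj + sum(z * log(psi) + (1 - z) * log1p(-psi))
    lj <- lj + log_bvn(state$a[k], state$b[k], h$mu_a, h$mu_b,
                       h$sigma_a, h$sigma_b, h$rho)
    lj <- lj + sum(dnorm(state$beta[k, ], h$mu_beta, h$sigma_beta, log = TRUE))
  }
  lj <- lj +
    sum(dnorm(c(h$mu_a, h$mu_b, h$mu_beta), 0, priors$mean_sd, log = TRUE)) +
    sum(dunif(c(h$sigma_a, h$sigma_b, h$sigma_beta), 0, priors$sigma_max,
              log = TRUE)) +
    dunif(h$rho, -1, 1, log = TRUE)
  lj
}

#' MCMC configuration for the occupancy sampler
#'
#' Desk-scale defaults: 3 chains of 20,000 iterations, the first half
#' discarded as burn-in, thinned to 2,000 kept draws per chain. The original
#' field configuration (3 x 100,000, half burn-in) is available by raising
#' `n_iter`.
#'
#' @param n_chains number of chains (>= 2 whenever Rhat is wanted).
#' @param n_iter iterations per chain.
#' @param n_burn burn-in iterations discarded (default half).
#' @param n_keep kept (thinned) draws per chain after burn-in.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 20000L,
                        n_burn = n_iter %/% 2L, n_keep = 2000L) {
  stopifnot(n_chains >= 1, n_iter > n_burn, n_keep >= 1)
  n_keep <- min(n_keep, n_iter - n_burn)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), n_keep = as.integer(n_keep)),
            class = "mcmc_config")
}

#' Fit the Bayesian multi-species occupancy model by MCMC
#'
#' Metropolis-within-Gibbs: the latent occurrence matrix `z` is updated by
#' Gibbs draws from [z_full_conditional]; species-level effects and the
#' community hyper-parameters by adaptive random-walk Metropolis (proposal
#' scales tuned toward 30-45% acceptance during burn-in, then frozen so the
#' kept draws target the exact posterior). Detection is modeled per species
#' (`p_k`), constant across sites and replicates.
#'
#' @param data a `detection_history` (from [binarize] or
#'   [simulate_community]).
#' @param covs a `site_covariates_std` (from [standardize_covariates]).
#' @param mcmc an [mcmc_config].
#' @param priors an [occupancy_priors].
#' @param seed integer seed; the same seed, data and configuration
#'   reproduce the chains exactly.
#' @param update_hyper set `FALSE` to hold the hyper-parameters fixed at
#'   `init_hyper` (used for small fixed-prior checks).
#' @param update_b set `FALSE` to hold detection intercepts fixed at their
#'   initial values.
#' @param init_hyper optional [community_hyperparams] initial state.
#' @param init_b optional length-K initial detection intercepts.
#' @return An object of class `posterior_chains`: per-chain matrices of
#'   parameter draws, thinned draws of `z`, acceptance rates and metadata.
#' @export
fit_community_occupancy <- function(data, covs, mcmc = mcmc_config(),
                                    priors = occupancy_priors(),
                                    seed = 1L,
                                    update_hyper = TRUE,
                                    update_b = TRUE,
                                    init_hyper = NULL,
                                    init_b = NULL) {
  stopifnot(inherits(data, "detection_history"),
            inherits(covs, "site_covariates_std"))
  dets <- detection_totals(data)
  storage.mode(dets) <- "integer"
  J <- as.integer(n_surveys(data))
  S <- nrow(dets); K <- ncol(dets)
  if (S < 2) stop("need at least 2 sites")
  if (K < 1) stop("need at least 1 species")
  X <- covs$X
  C <- ncol(X)
  if (is.null(init_hyper)) init_hyper <- community_hyperparams(
    sigma_a = 1, sigma_b = 1, sigma_beta = rep(1, C))
  if (length(init_hyper$mu_beta) != C)
    init_hyper <- within_hyper_resize(init_hyper, C)

  set.seed(seed)
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    # dispersed random initials per chain, drawn under the master seed
    naive_occ <- pmin(pmax(colMeans(dets > 0), 0.05), 0.95)
    init <- list(
      a = qlogis(naive_occ) + rnorm(K, 0, 0.5),
      b = if (is.null(init_b)) rnorm(K, -1, 0.5) else init_b,
      beta = matrix(rnorm(K * C, 0, 0.25), K, C),
      hyper = init_hyper)
    res <- occ_mcmc_cpp(dets, J, X, init$a, init$b, init$beta,
                        unlist_hyper(init$hyper, C),
                        mcmc$n_iter, mcmc$n_burn, mcmc$n_keep,
                        priors$mean_sd, priors$sigma_max,
                        update_hyper, update_b)
    res$params <- res$params[seq_len(res$n_kept), , drop = FALSE]
    res$z <- res$z[seq_len(res$n_kept), , drop = FALSE]
    colnames(res$params) <- occ_param_names(K, C)
    chains[[ch]] <- res
  }
  structure(list(chains = chains, param_names = occ_param_names(K, C),
                 n_species = K, n_sites = S, n_cov = C,
                 site_ids = data$site_ids,
                 species_names = data$species_names,
                 covariate_names = colnames(X),
                 mcmc = mcmc, priors = priors, seed = seed),
            class = "posterior_chains")
}

within_hyper_resize <- function(h, C) {
  h$mu_beta <- rep_len(h$mu_beta, C)
  h$sigma_beta <- rep_len(h$sigma_beta, C)
  h
}

unlist_hyper <- function(h, C) {
  c(h$mu_a, h$sigma_a, h$mu_b, h$sigma_b, h$rho,
    rep_len(h$mu_beta, C), rep_len(h$sigma_beta, C))
}

occ_param_names <- function(K, C) {
  c("mu_a", "sigma_a", "mu_b", "sigma_b", "rho",
    paste0("mu_beta[", seq_len(C), "]"),
    paste0("sigma_beta[", seq_len(C), "]"),
    paste0("a[", seq_len(K), "]"),
    paste0("b[", seq_len(K), "]"),
    paste0("beta[", rep(seq_len(K), each = C), ",",
           rep(seq_len(C), times = K), "]"))
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf(
    "posterior_chains: %d chains x %d kept draws, %d parameters (%d species, %d sites)\n",
    length(x$chains), nrow(x$chains[[1]]$params),
    length(x$param_names), x$n_species, x$n_sites))
  rh <- suppressWarnings(rhat_all(x))
  bad <- sum(rh >= 1.1, na.rm = TRUE)
  cat(sprintf("  max Rhat %.3f (%d parameter(s) >= 1.1)\n",
              max(rh, na.rm = TRUE), bad))
  invisible(x)
}

# draws of one parameter, one column per chain
param_draws <- function(chains, parameter) {
  sapply(chains$chains, function(ch) ch$params[, parameter])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic Rhat computed from the kept (post burn-in) draws:
#' with m chains of n draws, `W` the mean within-chain variance and `B/n`
#' the variance of the chain means, `Rhat = sqrt(((n-1)/n W + B/n) / W)`.
#' Values below 1.1 are conventionally taken as converged.
#'
#' @param chains a `posterior_chains`, or a numeric matrix with one column
#'   per chain.
#' @param parameter parameter name (ignored when `chains` is a matrix).
#' @return Rhat, or `NA` (with a warning) when every chain has zero
#'   within-chain variance.
#' @export
gelman_rubin <- function(chains, parameter = NULL) {
  draws <- if (is.matrix(chains)) chains else param_draws(chains, parameter)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2) stop("need at least 2 chains for Rhat")
  if (n < 2) stop("need at least 2 draws per chain for Rhat")
  W <- mean(apply(draws, 2, var))
  B_over_n <- var(colMeans(draws))
  if (W == 0) {
    warning("Rhat undefined: zero within-chain variance in all chains")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Rhat for every monitored parameter
#' @param chains a `posterior_chains`.
#' @return named numeric vector of Rhat values.
#' @export
rhat_all <- function(chains) {
  vapply(chains$param_names, function(p) {
    draws <- param_draws(chains, p)
    if (all(apply(draws, 2, var) == 0)) return(NA_real_)
    gelman_rubin(draws)
  }, numeric(1))
}

#' Derived species richness from the latent occurrence draws
#'
#' Richness is never modeled directly: every kept draw of the occurrence
#' matrix yields `N_i = sum_k z_ik` per site, and the posterior of richness
#' is the distribution of those sums. `N_i` is bounded by the number of
#' species modeled and can never fall below the number of species actually
#' detected at the site.
#'
#' @param chains a `posterior_chains`.
#' @return list of class `richness_posterior`: `draws` (total kept draws x
#'   sites) and a per-site `summary` (posterior mean and central 95%
#'   interval).
#' @export
derived_richness <- function(chains) {
  draws <- do.call(rbind, lapply(chains$chains, function(ch) {
    # z draws stored as kept x (S*K); row sums per site
    zs <- ch$z
    t(apply(zs, 1, function(zrow)
      rowSums(matrix(zrow, chains$n_sites, chains$n_species))))
  }))
  colnames(draws) <- chains$site_ids
  summ <- data.frame(
    site = chains$site_ids,
    mean = colMeans(draws),
    q025 = apply(draws, 2, quantile, 0.025),
    q975 = apply(draws, 2, quantile, 0.975),
    row.names = NULL)
  structure(list(draws = draws, summary = summ,
                 n_species = chains$n_species),
            class = "richness_posterior")
}

#' Posterior summary of the community hyper-effects
#'
#' For each distance covariate's hyper-mean `mu_beta[c]` (and the other
#' hyper-parameters): posterior mean, central 95% interval, and a
#' significance flag set when the interval excludes zero. With standardized
#' distances, a significantly negative hyper-mean means richness increases
#' with proximity to that feature class. Warns (never fails) if any
#' monitored Rhat is at or above 1.1.
#'
#' @param chains a `posterior_chains`.
#' @param check_rhat warn on unconverged parameters (default `TRUE`).
#' @return data.frame with columns `parameter`, `covariate`, `mean`,
#'   `q025`, `q975`, `significant`, `rhat`.
#' @export
summarize_community_effects <- function(chains, check_rhat = TRUE) {
  hyper_names <- c("mu_a", "sigma_a", "mu_b", "sigma_b", "rho",
                   grep("^mu_beta|^sigma_beta", chains$param_names,
                        value = TRUE))
  rh <- if (check_rhat) suppressWarnings(rhat_all(chains)) else NULL
  if (check_rhat && any(rh[hyper_names] >= 1.1, na.rm = TRUE))
    warning("Rhat >= 1.1 for: ",
            paste(hyper_names[which(rh[hyper_names] >= 1.1)], collapse = ", "),
            " - chains may not have converged")
  rows <- lapply(hyper_names, function(pn) {
    d <- as.numeric(param_draws(chains, pn))
    q <- quantile(d, c(0.025, 0.975))
    data.frame(parameter = pn, mean = mean(d), q025 = q[[1]], q975 = q[[2]],
               significant = q[[1]] > 0 | q[[2]] < 0,
               rhat = if (is.null(rh)) NA_real_ else rh[[pn]])
  })
  out <- do.call(rbind, rows)
  idx <- match(out$parameter, paste0("mu_beta[", seq_len(chains$n_cov), "]"))
  out$covariate <- ifelse(is.na(idx), NA, chains$covariate_names[idx])
  out[, c("parameter", "covariate", "mean", "q025", "q975", "significant",
          "rhat")]
}
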