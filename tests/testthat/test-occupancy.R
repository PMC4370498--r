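test_that("occupancy probability follows the logit-linear model", {
  expect_equal(occupancy_probability(list(a = 0, beta = rep(0, 5)),
                                     c(2, -1, 0, 3, 1)), 0.5)
  expect_equal(occupancy_probability(list(a = 2, beta = rep(0, 5)),
                                     rep(0, 5)), 1 / (1 + exp(-2)))
  # negative coefficient: occupancy falls with distance (rises with
  # proximity), the sign convention of standardized-distance models
  p1 <- occupancy_probability(list(a = 0, beta = c(-1, 0, 0, 0, 0)),
                              c(1, 0, 0, 0, 0))
  expect_equal(p1, 1 / (1 + exp(1)), tolerance = 1e-12)
  xs <- seq(-3, 3, by = 0.25)
  ps <- sapply(xs, function(x)
    occupancy_probability(list(a = 0, beta = c(-1, 0, 0, 0, 0)),
                          c(x, 0, 0, 0, 0)))
  expect_true(all(diff(ps) < 0))
  expect_error(occupancy_probability(list(a = NA, beta = rep(0, 5)),
                                     rep(0, 5)), "non-finite")
  expect_error(occupancy_probability(list(a = 0, beta = rep(0, 5)),
                                     rep(0, 3)), "length")
})

test_that("z full conditional matches Bayes rule", {
  expect_equal(z_full_conditional(0.3, 0.2, 5, 2), 1)   # any detection
  expect_equal(z_full_conditional(0.5, 0.5, 1, 0), 1 / 3)
  expect_equal(z_full_conditional(1, 0.7, 4, 0), 1)     # psi = 1
  # property: matches the unnormalized joint over z for random cases
  set.seed(1)
  for (r in 1:25) {
    psi <- runif(1); p <- runif(1); J <- sample(1:12, 1)
    joint1 <- psi * dbinom(0, J, p)        # z = 1, no detections in J trials
    joint0 <- (1 - psi)                    # z = 0
    expect_equal(z_full_conditional(psi, p, J, 0), joint1 / (joint1 + joint0),
                 tolerance = 1e-12)
  }
  expect_error(z_full_conditional(0.5, 0.5, 2, 3), "logic error")
})

test_that("log joint matches a hand-built single-cell computation", {
  # one site, one species, one survey with a detection, psi = p = 0.5:
  # data-dependent part (z-prior x observation) must be log 0.25
  det <- array(1L, dim = c(1, 1, 1))
  dh <- toy_history(det, matrix(TRUE, 1, 1))
  covs <- list(X = matrix(0, 1, 1))
  hyper <- community_hyperparams(mu_a = 0, sigma_a = 1, mu_b = 0,
                                 sigma_b = 1, rho = 0, mu_beta = 0,
                                 sigma_beta = 1)
  state <- list(z = matrix(1L, 1, 1), a = 0, b = 0,
                beta = matrix(0, 1, 1), hyper = hyper)
  pr <- occupancy_priors()
  lj <- occupancy_log_joint(state, dh, covs, pr)
  # the parameter-density terms, computed independently by hand:
  dens <- -log(2 * pi)                                   # N2((0,0); 0, I)
  dens <- dens + dnorm(0, 0, 1, log = TRUE)              # slope density
  dens <- dens + 3 * dnorm(0, 0, pr$mean_sd, log = TRUE) # mu_a, mu_b, mu_beta
  dens <- dens + 3 * dunif(1, 0, pr$sigma_max, log = TRUE)  # three sigmas
  dens <- dens + dunif(0, -1, 1, log = TRUE)             # rho
  expect_equal(lj - dens, log(0.25), tolerance = 1e-12)
})

test_that("doubling the data doubles the data-dependent part of log joint", {
  # rho = 0 so the parameter-density part is a sum of scalar normals we can
  # compute by hand and subtract
  hyper <- community_hyperparams(mu_a = 0.2, sigma_a = 1.1, mu_b = -0.4,
                                 sigma_b = 0.9, rho = 0,
                                 mu_beta = 0.1, sigma_beta = 0.8)
  a <- 0.3; b <- -0.2; bet <- -0.5
  pr <- occupancy_priors()
  lj_n <- function(n_sites) {
    det <- array(0L, dim = c(n_sites, 2, 1))
    det[, 1, 1] <- 1L                   # identical sites: 1 detection of 2
    occupancy_log_joint(
      list(z = matrix(1L, n_sites, 1), a = a, b = b,
           beta = matrix(bet, 1, 1), hyper = hyper),
      toy_history(det, matrix(TRUE, n_sites, 2)),
      list(X = matrix(0.7, n_sites, 1)), pr)
  }
  dens <- dnorm(a, 0.2, 1.1, log = TRUE) + dnorm(b, -0.4, 0.9, log = TRUE) +
    dnorm(bet, 0.1, 0.8, log = TRUE) +
    dnorm(0.2, 0, pr$mean_sd, TRUE) + dnorm(-0.4, 0, pr$mean_sd, TRUE) +
    dnorm(0.1, 0, pr$mean_sd, TRUE) +
    sum(dunif(c(1.1, 0.9, 0.8), 0, pr$sigma_max, TRUE)) +
    dunif(0, -1, 1, TRUE)
  expect_equal(lj_n(2) - dens, 2 * (lj_n(1) - dens), tolerance = 1e-10)
})

test_that("log joint is -Inf when z = 0 contradicts a detection", {
  det <- array(1L, dim = c(2, 1, 1))
  dh <- toy_history(det, matrix(TRUE, 2, 1))
  hyper <- community_hyperparams()
  state <- list(z = matrix(c(0L, 1L), 2, 1), a = 0, b = 0,
                beta = matrix(0, 1, 1), hyper = hyper)
  expect_equal(occupancy_log_joint(state, dh, list(X = matrix(0, 2, 1))),
               -Inf)
})

test_that("log joint equals a term-by-term brute-force oracle on a toy", {
  # 2 sites x 2 species, ragged surveys; the oracle enumerates every model
  # term with explicit loops and scalar densities
  set.seed(33)
  det <- array(0L, dim = c(2, 3, 2))
  det[1, 1, 1] <- 1L; det[1, 3, 1] <- 1L; det[2, 1, 2] <- 1L
  mask <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE))
  dh <- toy_history(det, mask)
  X <- matrix(rnorm(4), 2, 2)
  covs <- list(X = X)
  hyper <- community_hyperparams(mu_a = 0.3, sigma_a = 1.2, mu_b = -0.6,
                                 sigma_b = 0.8, rho = 0.4,
                                 mu_beta = c(-0.2, 0.1), sigma_beta = c(0.7, 1.1))
  state <- list(z = matrix(c(1L, 1L, 1L, 1L), 2, 2),
                a = c(0.2, -0.3), b = c(-0.5, 0.1),
                beta = matrix(rnorm(4, 0, 0.5), 2, 2), hyper = hyper)
  pr <- occupancy_priors()

  oracle <- function() {
    lj <- 0
    for (k in 1:2) {
      p_k <- 1 / (1 + exp(-state$b[k]))
      for (i in 1:2) {
        eta <- state$a[k]
        for (c_ in 1:2) eta <- eta + X[i, c_] * state$beta[k, c_]
        psi <- 1 / (1 + exp(-eta))
        z <- state$z[i, k]
        lj <- lj + ifelse(z == 1, log(psi), log(1 - psi))
        if (z == 1) {
          for (j in 1:3) {
            if (!mask[i, j]) next
            yij <- det[i, j, k]
            lj <- lj + ifelse(yij == 1, log(p_k), log(1 - p_k))
          }
        } else if (sum(det[i, mask[i, ], k]) > 0) return(-Inf)
      }
      # bivariate normal intercept density, from the definition
      S <- matrix(c(hyper$sigma_a^2,
                    hyper$rho * hyper$sigma_a * hyper$sigma_b,
                    hyper$rho * hyper$sigma_a * hyper$sigma_b,
                    hyper$sigma_b^2), 2, 2)
      v <- c(state$a[k] - hyper$mu_a, state$b[k] - hyper$mu_b)
      detS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
      lj <- lj - log(2 * pi) - 0.5 * log(detS) -
        0.5 * as.numeric(t(v) %*% solve(S) %*% v)
      for (c_ in 1:2)
        lj <- lj + dnorm(state$beta[k, c_], hyper$mu_beta[c_],
                         hyper$sigma_beta[c_], log = TRUE)
    }
    lj + dnorm(hyper$mu_a, 0, pr$mean_sd, TRUE) +
      dnorm(hyper$mu_b, 0, pr$mean_sd, TRUE) +
      sum(dnorm(hyper$mu_beta, 0, pr$mean_sd, TRUE)) +
      sum(dunif(c(hyper$sigma_a, hyper$sigma_b, hyper$sigma_beta),
                0, pr$sigma_max, TRUE)) +
      dunif(hyper$rho, -1, 1, TRUE)
  }
  expect_equal(occupancy_log_joint(state, dh, covs, pr), oracle(),
               tolerance = 1e-10)
})

test_that("Gelman-Rubin matches hand arithmetic and behaves at the null", {
  # hand-computed 2 chains x 3 draws
  draws <- cbind(c(1, 2, 3), c(2, 4, 6))
  n <- 3
  W <- (var(c(1, 2, 3)) + var(c(2, 4, 6))) / 2        # (1 + 4)/2 = 2.5
  B_over_n <- var(c(2, 4))                            # 2
  expected <- sqrt(((n - 1) / n * W + B_over_n) / W)
  expect_equal(gelman_rubin(draws), expected, tolerance = 1e-12)
  expect_equal(expected, sqrt((2 / 3 * 2.5 + 2) / 2.5), tolerance = 1e-12)

  # two long chains from the same distribution: Rhat within [1, 1.01]
  set.seed(5)
  null_draws <- cbind(rnorm(10000), rnorm(10000))
  rh <- gelman_rubin(null_draws)
  expect_gte(rh, sqrt((10000 - 1) / 10000))  # hard lower bound of the stat
  expect_lt(rh, 1.01)

  # deliberately divergent chains
  div <- cbind(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  expect_gt(gelman_rubin(div), 1.1)

  # zero within-chain variance
  expect_warning(rh0 <- gelman_rubin(cbind(rep(1, 50), rep(1, 50))),
                 "undefined")
  expect_true(is.na(rh0))
  expect_error(gelman_rubin(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("MCMC is reproducible and matches a grid posterior on a toy", {
  # 1 species, 2 sites, 1 covariate, fixed hyper-structure and detection
  det <- array(0L, dim = c(2, 3, 1))
  det[1, 1, 1] <- 1L                      # site 1: 1 detection in 2 surveys
  mask <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
  dh <- toy_history(det, mask)
  covs <- covs1(c(1, 2))
  x <- covs$X[, 1]
  p_fix <- 0.4
  hyper <- community_hyperparams(mu_a = 0, sigma_a = 1.5, mu_b = qlogis(p_fix),
                                 sigma_b = 1, rho = 0,
                                 mu_beta = 0, sigma_beta = 1.5)
  fit <- fit_community_occupancy(
    dh, covs, mcmc = mcmc_config(n_chains = 2, n_iter = 20000),
    seed = 11, update_hyper = FALSE, update_b = FALSE,
    init_hyper = hyper, init_b = qlogis(p_fix))
  fit_same <- fit_community_occupancy(
    dh, covs, mcmc = mcmc_config(n_chains = 2, n_iter = 20000),
    seed = 11, update_hyper = FALSE, update_b = FALSE,
    init_hyper = hyper, init_b = qlogis(p_fix))
  expect_identical(fit$chains[[1]]$params, fit_same$chains[[1]]$params)

  # brute-force grid posterior over (intercept, slope), z marginalized
  grid <- seq(-7, 7, length.out = 200)
  J <- c(2, 3); dtc <- c(1, 0)
  post <- matrix(0, 200, 200)
  psi_fun <- function(a, s, xi) plogis(a + s * xi)
  lik_site <- function(a, s, i) {
    psi <- psi_fun(a, s, x[i])
    psi * p_fix^dtc[i] * (1 - p_fix)^(J[i] - dtc[i]) +
      (1 - psi) * (dtc[i] == 0)
  }
  for (ia in 1:200) for (is in 1:200) {
    a <- grid[ia]; s <- grid[is]
    post[ia, is] <- dnorm(a, 0, 1.5) * dnorm(s, 0, 1.5) *
      lik_site(a, s, 1) * lik_site(a, s, 2)
  }
  post <- post / sum(post)
  grid_psi <- sapply(1:2, function(i) {
    m <- outer(grid, grid, function(a, s) psi_fun(a, s, x[i]))
    sum(post * m)
  })
  a_draws <- as.numeric(sapply(fit$chains, function(ch) ch$params[, "a[1]"]))
  s_draws <- as.numeric(sapply(fit$chains, function(ch)
    ch$params[, "beta[1,1]"]))
  mcmc_psi <- sapply(1:2, function(i) mean(plogis(a_draws + s_draws * x[i])))
  expect_lt(max(abs(mcmc_psi - grid_psi)), 0.02)
})

test_that("derived richness sums the occurrence draws and is bounded", {
  # minimal chains object: 2 chains x 3 kept draws, 2 sites, 4 species
  pn <- occ_param_names(4, 1)
  pm <- matrix(rnorm(3 * length(pn)), 3, length(pn),
               dimnames = list(NULL, pn))
  z1 <- rbind(c(1, 0, 0, 1, 1, 0, 1, 1),   # draw 1: sites x species flat
              c(1, 1, 1, 1, 0, 0, 1, 0),
              c(0, 0, 1, 0, 1, 1, 1, 1))
  z2 <- z1[c(2, 1, 3), ]
  ch <- fake_chains(list(pm, pm), list(z1, z2), n_sites = 2, n_species = 4,
                    n_cov = 1)
  rich <- derived_richness(ch)
  # z columns are species-major: site 1 occupies columns 1,3,5,7
  expect_equal(unname(rich$draws[1, ]),
               c(sum(z1[1, c(1, 3, 5, 7)]), sum(z1[1, c(2, 4, 6, 8)])))
  expect_true(all(rich$draws >= 0 & rich$draws <= 4))
  # mean posterior richness is exactly the mean over draws (derived)
  expect_equal(rich$summary$mean, unname(colMeans(rich$draws)))
})

test_that("community effect summary flags intervals that exclude zero", {
  pn <- occ_param_names(2, 5)
  set.seed(9)
  mk <- function() {
    m <- matrix(rnorm(500 * length(pn)), 500, length(pn),
                dimnames = list(NULL, pn))
    m[, "mu_beta[5]"] <- rnorm(500, -1.5, 0.2)   # clearly negative
    m[, "mu_beta[2]"] <- rnorm(500, 0, 0.3)      # straddles zero
    m
  }
  ch <- fake_chains(list(mk(), mk()), n_sites = 2, n_species = 2, n_cov = 5)
  eff <- summarize_community_effects(ch, check_rhat = FALSE)
  expect_true(eff$significant[eff$parameter == "mu_beta[5]"])
  expect_false(eff$significant[eff$parameter == "mu_beta[2]"])
  expect_equal(eff$covariate[eff$parameter == "mu_beta[5]"], "c5")
})

test_that("negating a covariate column flips its recovered hyper-effect", {
  des <- small_design(seed = 15, n_transects = 10)
  hyper <- community_hyperparams(mu_a = 0, sigma_a = 0.8, mu_b = 0,
                                 sigma_b = 0.6, rho = 0.3,
                                 mu_beta = c(-1.2, 0, 0, 0, 0),
                                 sigma_beta = rep(0.4, 5))
  sim <- simulate_community(hyper, des, n_species = 8, seed = 16)
  covs <- sim$covariates
  covs_neg <- covs
  covs_neg$X[, 1] <- -covs_neg$X[, 1]
  cfg <- mcmc_config(n_chains = 2, n_iter = 6000, n_keep = 1000)
  f1 <- fit_community_occupancy(sim$detections, covs, cfg, seed = 17)
  f2 <- fit_community_occupancy(sim$detections, covs_neg, cfg, seed = 17)
  e1 <- summarize_community_effects(f1, check_rhat = FALSE)
  e2 <- summarize_community_effects(f2, check_rhat = FALSE)
  m1 <- e1$mean[e1$parameter == "mu_beta[1]"]
  m2 <- e2$mean[e2$parameter == "mu_beta[1]"]
  expect_lt(m1, 0)
  expect_gt(m2, 0)
  expect_equal(m1, -m2, tolerance = 0.15)
})
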