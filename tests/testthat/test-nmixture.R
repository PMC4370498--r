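test_that("negative-binomial pmf uses the mean/overdispersion convention", {
  # normalization
  expect_equal(sum(negbin_pmf(0:2000, lam = 3, alpha = 1)), 1,
               tolerance = 1e-10)
  # closed form at zero: (alpha/(alpha+lam))^alpha; lam = alpha = 1 -> 0.5
  expect_equal(negbin_pmf(0, 1, 1), 0.5, tolerance = 1e-12)
  expect_equal(negbin_pmf(0, 2, 3), (3 / 5)^3, tolerance = 1e-12)
  # moments: Var = lam + lam^2/alpha
  n <- 0:4000
  pm <- negbin_pmf(n, 4, 2)
  expect_equal(sum(n * pm), 4, tolerance = 1e-8)
  expect_equal(sum(n^2 * pm) - sum(n * pm)^2, 4 + 16 / 2, tolerance = 1e-6)
  # Poisson limit
  expect_lt(max(abs(negbin_pmf(0:15, 3, 1e6) - dpois(0:15, 3))), 1e-4)
  expect_error(negbin_pmf(0, -1, 1), "positive")
  expect_error(negbin_pmf(-2, 1, 1), "nonnegative")
})

test_that("truncation bound respects the data and the tail tolerance", {
  # a dataset whose largest census held 29 birds keeps K >= 29 even when
  # the plausible abundance is tiny
  counts <- survey_counts(array(c(29L, 0L), c(1, 2, 1)), matrix(TRUE, 1, 2))
  expect_gte(choose_truncation_K(counts, lam_upper = 0.5, alpha = 1), 29)
  # tail property
  K <- choose_truncation_K(5, lam_upper = 20, alpha = 1.5, tol = 1e-8)
  expect_lt(pnbinom(K, size = 1.5, mu = 20, lower.tail = FALSE), 1e-8)
  # shrinking tol never shrinks K
  Ks <- sapply(c(1e-4, 1e-6, 1e-8, 1e-10),
               function(t) choose_truncation_K(5, 20, 1.5, tol = t))
  expect_true(all(diff(Ks) >= 0))
})

test_that("site marginal equals direct enumeration and its closed forms", {
  # p = 1: counts pin N exactly, marginal reduces to the NB mass
  expect_equal(site_log_marginal(c(4, 4), lam = 3, p = 1, alpha = 2, K = 60),
               dnbinom(4, size = 2, mu = 3, log = TRUE), tolerance = 1e-12)
  # naive direct-summation oracle (no log-space tricks)
  expect_equal(site_log_marginal(c(2, 0, 1), lam = 2, p = 0.4, alpha = 1,
                                 K = 50),
               naive_site_marginal(c(2, 0, 1), 2, 0.4, 1, 50),
               tolerance = 1e-10)
  # all-zero counts: log sum_N NB(N) (1-p)^(N J)
  yz <- c(0, 0, 0)
  direct <- log(sum(dnbinom(0:100, size = 1.2, mu = 3) * (1 - 0.3)^(3 * 0:100)))
  expect_equal(site_log_marginal(yz, 3, 0.3, 1.2, 100), direct,
               tolerance = 1e-10)
  # p -> 1 with all-zero counts tends to log NB(0)
  expect_equal(site_log_marginal(yz, 3, 1 - 1e-12, 1.2, 100),
               dnbinom(0, size = 1.2, mu = 3, log = TRUE), tolerance = 1e-6)
  expect_error(site_log_marginal(c(5, 1), 2, 0.4, 1, K = 3), "truncation")
})

test_that("model negative log likelihood matches a brute-force oracle", {
  covs <- toy_covs(3)
  counts <- survey_counts(array(c(2L, 1L, 0L,  0L, 3L, 1L), c(3, 2, 1)),
                          matrix(TRUE, 3, 2), site_ids = covs$site)
  params <- nmixture_params(alpha0 = 0.8, beta = c(-0.4, 0.2, 0, 0.1, -0.3),
                            alpha_disp = 1.3, eta = qlogis(0.35))
  nll <- nmixture_negloglik(params, counts, covs, K = 55)
  oracle <- 0
  for (i in 1:3) {
    lam <- exp(params$alpha0 + sum(covs$X[i, ] * params$beta))
    oracle <- oracle - naive_site_marginal(counts$counts[i, , 1], lam,
                                           plogis(params$eta), 1.3, 55)
  }
  expect_equal(nll, oracle, tolerance = 1e-10)
})

test_that("likelihood is additive over sites and replicate-exchangeable", {
  covs <- toy_covs(6)
  set.seed(2)
  y <- matrix(rpois(18, 2), 6, 3)
  counts <- survey_counts(array(y, c(6, 3, 1)), matrix(TRUE, 6, 3),
                          site_ids = covs$site)
  params <- nmixture_params(alpha0 = 1, beta = c(-0.3, 0, 0.2, 0, -0.2),
                            alpha_disp = 1, eta = qlogis(0.4))
  # split sites into two disjoint halves with their own covariate objects
  sub <- function(idx) {
    list(counts = survey_counts(array(y[idx, , drop = FALSE],
                                      c(length(idx), 3, 1)),
                                matrix(TRUE, length(idx), 3)),
         covs = structure(list(X = covs$X[idx, , drop = FALSE]),
                          class = "site_covariates_std"))
  }
  a <- sub(1:3); b <- sub(4:6)
  expect_equal(nmixture_negloglik(params, counts, covs, 60),
               nmixture_negloglik(params, a$counts, a$covs, 60) +
                 nmixture_negloglik(params, b$counts, b$covs, 60),
               tolerance = 1e-8)
  # permuting replicates within a site leaves the likelihood unchanged
  yperm <- y[, c(3, 1, 2)]
  cperm <- survey_counts(array(yperm, c(6, 3, 1)), matrix(TRUE, 6, 3))
  expect_equal(nmixture_negloglik(params, counts, covs, 60),
               nmixture_negloglik(params, cperm, covs, 60),
               tolerance = 1e-10)
})

test_that("truncation-stable: raising K leaves the log likelihood put", {
  des <- small_design(seed = 20)
  sim <- simulate_counts(
    nmixture_params(alpha0 = 1.5, beta = c(-0.5, 0, 0.3, 0, -0.4),
                    alpha_disp = 1, eta = qlogis(0.3)), des, seed = 21)
  covs <- sim$covariates
  fit <- fit_nmixture(sim$counts, covs, seed = 5, n_starts = 2)
  pars <- nmixture_params(
    alpha0 = fit$coefficients$estimate[1],
    beta = fit$coefficients$estimate[2:6],
    alpha_disp = fit$alpha_disp,
    eta = fit$coefficients$estimate[8])
  ll1 <- nmixture_negloglik(pars, sim$counts, covs, fit$K)
  ll2 <- nmixture_negloglik(pars, sim$counts, covs, fit$K + 200L)
  expect_lt(abs(ll1 - ll2), 1e-6)
  expect_gte(fit$K, max(sim$counts$counts))
})

test_that("negating a covariate negates its coefficient only", {
  des <- small_design(seed = 22)
  sim <- simulate_counts(
    nmixture_params(alpha0 = 1.8, beta = c(-0.6, 0, 0, 0, 0.4),
                    alpha_disp = 1.5, eta = qlogis(0.25)), des, seed = 23)
  covs <- sim$covariates
  covs_neg <- covs
  covs_neg$X[, 1] <- -covs_neg$X[, 1]
  f1 <- fit_nmixture(sim$counts, covs, seed = 7, n_starts = 2)
  f2 <- fit_nmixture(sim$counts, covs_neg, seed = 7, n_starts = 2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(f1$coefficients$estimate[2], -f2$coefficients$estimate[2],
               tolerance = 1e-3)
  expect_equal(f1$coefficients$estimate[3:6], f2$coefficients$estimate[3:6],
               tolerance = 1e-3)
})

test_that("all-zero counts are refused as unidentifiable", {
  covs <- toy_covs(4)
  z <- survey_counts(array(0L, c(4, 2, 1)), matrix(TRUE, 4, 2))
  expect_error(fit_nmixture(z, covs), "zero total count")
  params <- nmixture_params()
  expect_error(nmixture_negloglik(params, z, covs, 30), "zero total count")
})

test_that("Wald inference reproduces published-table arithmetic", {
  # estimate -0.295, SE 0.161: z = -1.832, p about 0.067, one star
  tab <- data.frame(parameter = "primary_roads", estimate = -0.295,
                    se = 0.161)
  w <- wald_inference(tab)
  expect_equal(w$z, -0.295 / 0.161, tolerance = 1e-12)
  expect_gte(w$p, 0.066); expect_lte(w$p, 0.068)
  expect_equal(w$stars, "*")
  # estimate 0.607, SE 0.249: p about 0.0147, two stars
  w2 <- wald_inference(data.frame(parameter = "fences", estimate = 0.607,
                                  se = 0.249))
  expect_equal(w2$p, 2 * pnorm(-0.607 / 0.249), tolerance = 1e-12)
  expect_lt(abs(w2$p - 0.0147), 5e-4)
  expect_equal(w2$stars, "**")
  # zero estimate: p = 1, no stars
  w3 <- wald_inference(data.frame(parameter = "x", estimate = 0, se = 0.5))
  expect_equal(w3$p, 1)
  expect_equal(w3$stars, "")
})

test_that("star thresholds are exactly the 0.1 / 0.05 / 0.01 legend", {
  expect_equal(significance_stars(c(0.009, 0.01, 0.049, 0.05, 0.09, 0.1,
                                    0.11, NA)),
               c("***", "***", "**", "**", "*", "*", "", ""))
})

test_that("detection interval is a back-transformed logit Wald interval", {
  mk_fit <- function(eta, se_eta, boundary = FALSE) {
    structure(list(coefficients = data.frame(
      parameter = c("(Intercept)", "eta"),
      estimate = c(0, eta), se = c(1, se_eta)),
      boundary = boundary), class = "nmixture_fit")
  }
  ci <- detection_probability_ci(mk_fit(-2, 0.3))
  expect_equal(ci$p_hat, plogis(-2))
  expect_equal(ci$lower, plogis(-2 - qnorm(0.975) * 0.3), tolerance = 1e-12)
  expect_equal(ci$upper, plogis(-2 + qnorm(0.975) * 0.3), tolerance = 1e-12)
  expect_true(ci$lower < ci$p_hat && ci$p_hat < ci$upper)
  # SE = 0 collapses the interval to the point estimate
  ci0 <- detection_probability_ci(mk_fit(-2, 0))
  expect_equal(ci0$lower, ci0$p_hat)
  expect_equal(ci0$upper, ci0$p_hat)
  # monotone in the logit-scale bounds
  wide <- detection_probability_ci(mk_fit(-2, 1))
  expect_lt(wide$lower, ci$lower); expect_gt(wide$upper, ci$upper)
  # boundary flag propagates
  expect_false(detection_probability_ci(mk_fit(-2, 0.3, TRUE))$reliable)
})

test_that("most influential covariate: largest |estimate| with p <= 0.1", {
  covs5 <- c("primary_roads", "secondary_roads", "fences", "settlements",
             "cities")
  mk <- function(est, se) {
    wald_inference(data.frame(parameter = covs5, estimate = est, se = se))
  }
  # a strongly negative city effect beats a slightly smaller road effect
  t1 <- mk(c(-1.048, 0.132, -0.036, 0.237, -1.104),
           c(0.424, 0.506, 0.619, 0.293, 0.346))
  expect_equal(most_influential_effect(t1), "cities")
  # a large but non-significant coefficient is skipped in favor of the
  # largest qualifying one
  t2 <- mk(c(0.420, -0.453, -0.765, -0.739, -0.726),
           c(0.309, 0.405, 0.491, 0.287, 0.303))
  expect_equal(most_influential_effect(t2), "settlements")
  # nothing qualifies
  t3 <- mk(rep(0.1, 5), rep(1, 5))
  expect_true(is.na(most_influential_effect(t3)))
})
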