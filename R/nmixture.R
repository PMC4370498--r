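#' Parameters of the negative-binomial N-mixture model
#'
#' Latent site abundance `N_i ~ NegBin(lambda_i, alpha)` in the
#' mean/overdispersion parameterization (`Var = lambda + lambda^2/alpha`;
#' larger `alpha` means closer to Poisson), with
#' `log(lambda_i) = alpha0 + beta' x_i` over the five standardized
#' distances, and counts `y_ij ~ Binomial(N_i, p)` with a constant
#' detection probability `p = plogis(eta)`.
#'
#' Negative-binomial conventions differ between software; this package
#' always uses the size-`alpha` ("ecological") convention above, which is
#' `dnbinom(size = alpha, mu = lambda)` in R.
#'
#' @param alpha0 abundance intercept (log scale).
#' @param beta coefficients of the standardized distances (primary roads,
#'   secondary roads, fences, settlements, cities).
#' @param alpha_disp overdispersion, > 0.
#' @param eta detection intercept (logit scale).
#' @return An object of class `nmixture_params`.
#' @export
nmixture_params <- function(alpha0 = 0, beta = rep(0, 5), alpha_disp = 1,
                            eta = 0) {
  if (!is.finite(alpha_disp) || alpha_disp <= 0)
    stop("parameter error: alpha_disp must be positive")
  if (!all(is.finite(c(alpha0, beta, eta))))
    stop("parameter error: alpha0, beta, eta must be finite")
  structure(list(alpha0 = alpha0, beta = as.numeric(beta),
                 alpha_disp = alpha_disp, eta = eta),
            class = "nmixture_params")
}

#' Negative-binomial probability mass, mean/overdispersion form
#'
#' @param n nonnegative integer(s).
#' @param lam mean, > 0.
#' @param alpha overdispersion, > 0; `Var = lam + lam^2/alpha`.
#' @return `P(N = n)`.
#' @export
negbin_pmf <- function(n, lam, alpha) {
  if (any(lam <= 0) || any(alpha <= 0))
    stop("parameter error: lam and alpha must be positive")
  if (any(n < 0) || any(n != round(n)))
    stop("parameter error: n must be a nonnegative integer")
  dnbinom(n, size = alpha, mu = lam)
}

#' Choose the truncation bound for the latent-abundance sum
#'
#' The marginal likelihood sums the infinite latent mixture over
#' `N = 0, 1, 2, ...`; in practice the sum is truncated at a bound `K`
#' that (a) is never below the maximum observed count and (b) leaves
#' negative-binomial upper-tail mass below `tol` at the largest plausible
#' abundance mean.
#'
#' @param counts a [survey_counts] (single species), or a numeric maximum
#'   observed count.
#' @param lam_upper largest plausible abundance mean.
#' @param alpha overdispersion at which the tail is evaluated.
#' @param tol upper-tail mass allowed beyond `K` (default 1e-8).
#' @return integer truncation bound `K`.
#' @export
choose_truncation_K <- function(counts, lam_upper, alpha, tol = 1e-8) {
  stopifnot(tol > 0, lam_upper > 0, alpha > 0)
  max_count <- if (inherits(counts, "survey_counts")) {
    max(counts$counts[rep(counts$replicate_mask,
                          times = dim(counts$counts)[3])])
  } else max(counts)
  K_tail <- qnbinom(tol, size = alpha, mu = lam_upper, lower.tail = FALSE)
  max(as.integer(max_count), as.integer(K_tail) + 1L)
}

#' Site contribution to the marginal log likelihood
#'
#' `log sum_{N = max(y)}^{K} NegBin(N; lam, alpha) prod_j Binom(y_j; N, p)`
#' over the site's surveyed replicates, evaluated stably in log space.
#'
#' @param y observed counts over the site's surveyed replicates.
#' @param lam abundance mean at the site.
#' @param p detection probability.
#' @param alpha overdispersion.
#' @param K truncation bound, at least `max(y)`.
#' @return log marginal likelihood of the site's counts.
#' @export
site_log_marginal <- function(y, lam, p, alpha, K) {
  if (K < max(y)) stop("truncation error: K below the maximum observed count")
  N <- seq.int(max(y), K)
  terms <- dnbinom(N, size = alpha, mu = lam, log = TRUE)
  for (yj in y) terms <- terms + dbinom(yj, N, p, log = TRUE)
  m <- max(terms)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(terms - m)))
}

# Per-fit constants of the vectorized likelihood: the binomial-coefficient
# table sum_j lchoose(N, y_ij) for N = 0..K (parameter-free), plus the count
# sufficient statistics.
nmix_prepare <- function(counts, X, K) {
  d <- dim(counts$counts)
  if (d[3] != 1L) stop("single-species counts required (see select_species)")
  y <- matrix(counts$counts[, , 1], d[1], d[2])
  mask <- counts$replicate_mask
  Tot <- rowSums(y * mask)
  if (sum(Tot) == 0)
    stop("species with zero total count: abundance model unidentifiable")
  J <- rowSums(mask)
  maxy <- apply(y * mask, 1, max)
  Ns <- 0:K
  # lchoose(N, y) is -Inf for y > N, zeroing impossible N in the sum
  Lch <- vapply(seq_len(d[1]), function(i) {
    yi <- y[i, mask[i, ]]
    rowSums(matrix(lchoose(rep(Ns, length(yi)), rep(yi, each = K + 1)),
                   K + 1, length(yi)))
  }, numeric(K + 1))
  list(y = y, mask = mask, Tot = Tot, J = J, maxy = maxy, K = K,
       Lch = Lch, X = X, S = d[1])
}

# negative log likelihood on the optimizer scale
# theta = (alpha0, beta_1..C, log alpha_disp, eta); compiled hot path
nmix_nll_theta <- function(theta, prep) {
  nmix_nll_cpp(theta, prep$X, prep$Lch, prep$Tot, prep$J,
               as.integer(prep$maxy), prep$K)
}

# analytic gradient of the same (compiled); see src/nmix_grad.cpp
nmix_grad_theta <- function(theta, prep) {
  nmix_nll_grad_cpp(theta, prep$X, prep$Lch, prep$Tot, prep$J,
                    as.integer(prep$maxy), prep$K)$gradient
}

#' Negative log likelihood of the N-mixture model
#'
#' Sum over sites of minus [site_log_marginal] with
#' `lambda_i = exp(alpha0 + beta' x_i)`.
#'
#' @param params an [nmixture_params].
#' @param counts single-species [survey_counts].
#' @param covs a `site_covariates_std`.
#' @param K truncation bound for the latent sum.
#' @return negative log likelihood.
#' @export
nmixture_negloglik <- function(params, counts, covs, K) {
  stopifnot(inherits(params, "nmixture_params"))
  prep <- nmix_prepare(counts, covs$X, K)
  theta <- c(params$alpha0, params$beta, log(params$alpha_disp), params$eta)
  nmix_nll_theta(theta, prep)
}

#' Fit a negative-binomial N-mixture model by maximum likelihood
#'
#' Minimizes the truncated-sum marginal negative log likelihood over
#' `(alpha0, beta, log alpha_disp, eta)` by quasi-Newton search from
#' several starting points (N-mixture likelihoods can be multimodal in the
#' abundance/detection trade-off), keeps the best optimum, and derives
#' standard errors from the inverse observed information (finite-difference
#' Hessian). The truncation bound is checked after fitting and raised
#' (with a refit) until the log likelihood is stable.
#'
#' @param counts a [survey_counts]; multi-species input requires `species`.
#' @param covs a `site_covariates_std`.
#' @param species species name or `"total"` when `counts` has several
#'   species.
#' @param K truncation bound, or `"auto"` (default): max count + 100,
#'   then verified by [choose_truncation_K] at the fitted parameters.
#' @param n_starts number of optimizer starts (default 5; the first is
#'   moment-informed, the rest draw random detection guesses).
#' @param seed seed for the random starts.
#' @param tol tail-mass tolerance for the truncation check.
#' @return An object of class `nmixture_fit`: a coefficient table
#'   (estimate, SE, z, p, stars), the detection probability with its 95%
#'   interval, log likelihood, `K`, convergence and boundary flags, and
#'   the most influential covariate.
#' @export
fit_nmixture <- function(counts, covs, species = NULL, K = "auto",
                         n_starts = 5L, seed = 1L, tol = 1e-8) {
  stopifnot(inherits(counts, "survey_counts"),
            inherits(covs, "site_covariates_std"))
  if (!is.null(species)) counts <- select_species(counts, species)
  if (dim(counts$counts)[3] != 1L)
    stop("multi-species counts: pass `species` (a name or \"total\")")
  X <- covs$X
  C <- ncol(X)
  d <- dim(counts$counts)
  y <- matrix(counts$counts[, , 1], d[1], d[2])
  max_count <- max(y[counts$replicate_mask])
  if (sum(y[counts$replicate_mask]) == 0)
    stop("species with zero total count: abundance model unidentifiable")

  K_use <- if (identical(K, "auto")) max_count + 100L else as.integer(K)
  if (K_use < max_count) stop("truncation error: K below the maximum count")

  set.seed(seed)
  mean_count <- mean(rowSums(y * counts$replicate_mask) /
                       rowSums(counts$replicate_mask))
  p_guesses <- c(0.25, runif(max(0, n_starts - 1), 0.02, 0.8))[seq_len(n_starts)]
  starts <- lapply(seq_len(n_starts), function(s) {
    p0 <- p_guesses[s]
    th <- c(log(max(mean_count, 0.1) / p0), rep(0, C), 0, qlogis(p0))
    if (s > 1) th <- th + c(rnorm(1, 0, 0.5), rnorm(C, 0, 0.2),
                            rnorm(1, 0, 0.5), 0)
    th
  })

  run_opt <- function(prep) {
    fits <- lapply(starts, function(th0) {
      tryCatch(optim(th0, nmix_nll_theta, gr = nmix_grad_theta, prep = prep,
                     method = "BFGS", control = list(maxit = 500)),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("fit error: all optimizer starts failed")
    fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  }

  prep <- nmix_prepare(counts, X, K_use)
  best <- run_opt(prep)
  # truncation stability: raise K until the tail at the fitted optimum is
  # negligible, refitting if the bound moves; near-boundary fits (p -> 0,
  # lambda -> infinity) would demand an unbounded K, so growth stops at
  # K_cap and such fits carry the boundary flag below
  K_cap <- 8192L
  for (rep_ in 1:3) {
    lam_hat <- exp(best$par[1] + X %*% best$par[1 + seq_len(C)])
    K_need <- choose_truncation_K(max_count, max(lam_hat),
                                  exp(best$par[C + 2]), tol)
    if (K_need <= K_use || K_use >= K_cap) break
    K_use <- min(max(K_need, 2L * K_use), K_cap)
    prep <- nmix_prepare(counts, X, K_use)
    best <- run_opt(prep)
  }

  H <- tryCatch(optimHess(best$par, nmix_nll_theta, prep = prep),
                error = function(e) NULL)
  vcov <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vcov)) {
    dg <- diag(vcov)
    ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
  } else rep(NA_real_, length(best$par))

  p_hat <- plogis(best$par[C + 3])
  alpha_hat <- exp(best$par[C + 2])
  boundary <- p_hat < 1e-4 || p_hat > 1 - 1e-4 || alpha_hat > 1e4
  grad <- num_gradient(function(t) nmix_nll_theta(t, prep), best$par)
  converged <- best$convergence == 0 && max(abs(grad)) < 0.1 && !boundary

  par_names <- c("(Intercept)", colnames(X), "log_alpha", "eta")
  coefs <- data.frame(parameter = par_names, estimate = best$par, se = se)
  fit <- structure(
    list(coefficients = coefs, vcov = vcov,
         loglik = -best$value, K = K_use,
         p_hat = p_hat, alpha_disp = alpha_hat,
         converged = converged, boundary = boundary,
         species = counts$species_names,
         covariate_names = colnames(X),
         n_sites = d[1]),
    class = "nmixture_fit")
  fit$inference <- wald_inference(fit)
  fit$detection <- detection_probability_ci(fit)
  fit$most_influential <- most_influential_effect(fit)
  fit
}

num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Significance stars at the 0.1 / 0.05 / 0.01 thresholds
#' @param p p-value(s).
#' @return character: `***` for p <= 0.01, `**` for p <= 0.05, `*` for
#'   p <= 0.1, empty otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.01, "***", ifelse(p <= 0.05, "**",
                                         ifelse(p <= 0.1, "*", ""))))
}

#' Wald tests for the fitted coefficients
#'
#' `z = estimate / SE`, two-sided p-value from the standard normal, stars
#' at the 0.1 / 0.05 / 0.01 thresholds.
#'
#' @param fit an `nmixture_fit`, or a data.frame with `estimate` and `se`
#'   columns (e.g. a published coefficient table).
#' @return data.frame with `estimate`, `se`, `z`, `p`, `stars`.
#' @export
wald_inference <- function(fit) {
  tab <- if (inherits(fit, "nmixture_fit")) fit$coefficients else fit
  z <- ifelse(tab$se > 0, tab$estimate / tab$se, NA_real_)
  p <- 2 * pnorm(-abs(z))
  cbind(tab, z = z, p = p, stars = significance_stars(p))
}

#' Detection probability with its 95% Wald interval
#'
#' Wald interval for the detection intercept on the logit scale,
#' back-transformed, so the bounds always fall in (0, 1) and bracket the
#' estimate.
#'
#' @param fit an `nmixture_fit`.
#' @param level confidence level (default 0.95).
#' @return data.frame with `p_hat`, `lower`, `upper`, `reliable` (FALSE
#'   when the fit sat on a boundary or the SE was unavailable).
#' @export
detection_probability_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "nmixture_fit"))
  i <- match("eta", fit$coefficients$parameter)
  eta <- fit$coefficients$estimate[i]
  se <- fit$coefficients$se[i]
  zq <- qnorm(1 - (1 - level) / 2)
  reliable <- is.finite(se) && !fit$boundary
  lo <- if (is.finite(se)) plogis(eta - zq * se) else NA_real_
  hi <- if (is.finite(se)) plogis(eta + zq * se) else NA_real_
  data.frame(p_hat = plogis(eta), lower = lo, upper = hi,
             reliable = reliable)
}

#' Most influential covariate of a fitted abundance model
#'
#' Among the distance coefficients with Wald `p <= 0.1`, the one with the
#' largest absolute standardized estimate; `NA` when no coefficient
#' reaches p <= 0.1. This is the rule that singles out one feature class
#' per species in the reported tables (the gate matters: a large but
#' non-significant coefficient never wins).
#'
#' @param fit an `nmixture_fit`, or a [wald_inference]-style table whose
#'   `parameter` column names the covariates.
#' @return covariate name, or `NA_character_`.
#' @export
most_influential_effect <- function(fit) {
  tab <- if (inherits(fit, "nmixture_fit")) fit$inference else fit
  covs <- tab[!tab$parameter %in% c("(Intercept)", "log_alpha", "eta"), ]
  covs <- covs[!is.na(covs$p) & covs$p <= 0.1, ]
  if (!nrow(covs)) return(NA_character_)
  covs$parameter[which.max(abs(covs$estimate))]
}

#' @export
print.nmixture_fit <- function(x, ...) {
  cat(sprintf("N-mixture fit (%s): %d sites, K = %d, logLik = %.2f%s\n",
              x$species, x$n_sites, x$K, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- x$inference
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("detection p = %.5f (%.5f, %.5f)\n",
              x$detection$p_hat, x$detection$lower, x$detection$upper))
  if (!is.na(x$most_influential))
    cat("most influential covariate:", x$most_influential, "\n")
  invisible(x)
}
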