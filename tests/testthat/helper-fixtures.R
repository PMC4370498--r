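# Shared fixture builders. Everything is generated in code; no data files.

# tiny ragged multi-species count object built by hand
toy_counts <- function() {
  counts <- array(0L, dim = c(2, 3, 2))
  counts[1, 1, 1] <- 2L; counts[1, 2, 1] <- 1L
  counts[1, 1, 2] <- 0L; counts[1, 2, 2] <- 3L
  counts[2, 1, 1] <- 0L; counts[2, 1, 2] <- 4L
  mask <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  survey_counts(counts, mask, site_ids = c("A", "B"),
                species_names = c("condor", "caracara"))
}

# small standardized covariate table with deterministic values
toy_covs <- function(n = 6) {
  df <- data.frame(
    site = paste0("s", seq_len(n)),
    d_primary_km = seq(1, 5, length.out = n),
    d_secondary_km = c(seq(2, 0.5, length.out = n - 1), 3),
    d_fence_km = (seq_len(n) %% 3) + 0.5,
    d_settlement_km = rev(seq(0.5, 4, length.out = n)),
    d_city_km = seq(6, 20, length.out = n))
  standardize_covariates(site_covariates(df))
}

# a smaller survey design for fast simulation-based tests
small_design <- function(seed = 1, n_transects = 8, replicate_range = c(2, 12),
                         n_sites_target = NULL) {
  generate_design(design_config(n_transects = n_transects,
                                replicate_range = replicate_range,
                                n_sites_target = n_sites_target),
                  seed = seed)
}

# single-covariate standardized covariates built directly (bypasses the
# five-column table for 1-covariate toys)
covs1 <- function(x) {
  X <- matrix((x - mean(x)) / sd(x), ncol = 1,
              dimnames = list(NULL, "primary_roads"))
  structure(list(site = paste0("s", seq_along(x)),
                 raw = matrix(x, ncol = 1), X = X,
                 center = mean(x), scale = sd(x)),
            class = "site_covariates_std")
}

# naive direct-summation N-mixture site marginal (independent oracle: no
# log-space tricks, plain dnbinom/dbinom products)
naive_site_marginal <- function(y, lam, p, alpha, K) {
  s <- 0
  for (N in 0:K)
    s <- s + dnbinom(N, size = alpha, mu = lam) * prod(dbinom(y, N, p))
  log(s)
}

# detection history built by hand from a binary site x replicate x species
# array and mask
toy_history <- function(det, mask) {
  structure(list(detections = det, replicate_mask = mask,
                 site_ids = paste0("s", seq_len(dim(det)[1])),
                 species_names = paste0("sp", seq_len(dim(det)[3]))),
            class = "detection_history")
}

# minimal posterior_chains object wrapping given parameter draw matrices
# (one matrix per chain) and optional z draws
fake_chains <- function(param_mats, z_list = NULL, n_sites = 1,
                        n_species = 1, n_cov = 5) {
  chains <- lapply(seq_along(param_mats), function(i) {
    list(params = param_mats[[i]],
         z = if (is.null(z_list)) NULL else z_list[[i]])
  })
  structure(list(chains = chains,
                 param_names = colnames(param_mats[[1]]),
                 n_species = n_species, n_sites = n_sites, n_cov = n_cov,
                 site_ids = paste0("s", seq_len(n_sites)),
                 species_names = paste0("sp", seq_len(n_species)),
                 covariate_names = paste0("c", seq_len(n_cov))),
            class = "posterior_chains")
}
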