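#' Study-design configuration for the synthetic landscape
#'
#' Describes the transect-based point-count layout the generator emulates:
#' transects perpendicular to a primary road (one every `transect_spacing_km`
#' along it, alternating sides), with points at fixed offsets from the road
#' (1, 2, 3 and 5 km by default, i.e. successive spacings of 1, 1, 1 and
#' 2 km), a city at a fixed map position, and scattered secondary roads,
#' fences and settlements. Each site is surveyed a variable number of times.
#'
#' @param n_transects number of transects (default 22).
#' @param points_per_transect points per transect (default 4).
#' @param offsets_km point offsets from the primary road, km; strictly
#'   increasing and positive.
#' @param transect_spacing_km distance between neighbouring transects, km.
#' @param city_xy city position `(x, y)` in km; the road is the line x = 0,
#'   transects sit at y = spacing, 2*spacing, ... The default puts the city
#'   on the road 6 km before the first transect, so city distance varies
#'   smoothly along the road.
#' @param secondary_road_intensity,fence_intensity,settlement_intensity
#'   intensities (features per km^2) of the homogeneous Poisson processes
#'   that place each feature class; distance is to the nearest feature.
#' @param replicate_range integer `c(min, max)` surveys per site (default
#'   2 to 12); drawn uniformly.
#' @param n_sites_target optional: subsample the generated sites down to
#'   this many (e.g. 77 from a 22 x 4 grid of 88 candidates).
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_transects = 22L,
                          points_per_transect = 4L,
                          offsets_km = c(1, 2, 3, 5),
                          transect_spacing_km = 1,
                          city_xy = c(0, -6),
                          secondary_road_intensity = 0.08,
                          fence_intensity = 0.4,
                          settlement_intensity = 0.03,
                          replicate_range = c(2L, 12L),
                          n_sites_target = NULL) {
  cfg <- list(n_transects = as.integer(n_transects),
              points_per_transect = as.integer(points_per_transect),
              offsets_km = as.numeric(offsets_km),
              transect_spacing_km = transect_spacing_km,
              city_xy = as.numeric(city_xy),
              secondary_road_intensity = secondary_road_intensity,
              fence_intensity = fence_intensity,
              settlement_intensity = settlement_intensity,
              replicate_range = as.integer(replicate_range),
              n_sites_target = if (is.null(n_sites_target)) NULL
                               else as.integer(n_sites_target))
  if (cfg$n_transects < 1L) stop("n_transects must be >= 1")
  if (length(cfg$offsets_km) != cfg$points_per_transect)
    stop("offsets_km must have one entry per point on a transect")
  if (any(cfg$offsets_km <= 0) || any(diff(cfg$offsets_km) <= 0))
    stop("offsets_km must be positive and strictly increasing")
  if (cfg$replicate_range[1] < 1L ||
      cfg$replicate_range[2] < cfg$replicate_range[1])
    stop("replicate_range must satisfy 1 <= min <= max")
  if (any(c(cfg$secondary_road_intensity, cfg$fence_intensity,
            cfg$settlement_intensity) <= 0))
    stop("feature intensities must be positive")
  if (length(cfg$city_xy) != 2 || any(!is.finite(cfg$city_xy)))
    stop("config error: city_xy must be a finite (x, y) position")
  structure(cfg, class = "design_config")
}

# n points of a homogeneous Poisson process on [x1,x2] x [y1,y2];
# guaranteed nonempty so nearest-feature distances are always defined.
rpoispp_box <- function(intensity, box) {
  area <- (box[2] - box[1]) * (box[4] - box[3])
  n <- max(1L, rpois(1, intensity * area))
  cbind(runif(n, box[1], box[2]), runif(n, box[3], box[4]))
}

nearest_dist <- function(sites, pts) {
  apply(sites, 1, function(s)
    sqrt(min((pts[, 1] - s[1])^2 + (pts[, 2] - s[2])^2)))
}

#' Generate a synthetic study design: site covariates and replicate schedule
#'
#' Lays the transect grid on a plane (primary road = the line x = 0),
#' places the city and the random feature classes, and computes each site's
#' distance to the nearest feature of every class. `d_primary` equals the
#' point's offset from the road by construction; `d_city` is the Euclidean
#' distance to the city position.
#'
#' @param config a [design_config].
#' @param seed integer RNG seed; the same seed reproduces the design
#'   bit-for-bit.
#' @return A list of class `survey_design` with elements `covariates`
#'   (a [site_covariates]), `replicates` (surveys per site), and `xy`
#'   (site coordinates, km).
#' @export
generate_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  set.seed(seed)
  tr <- seq_len(config$n_transects)
  y <- tr * config$transect_spacing_km
  side <- ifelse(tr %% 2 == 0, -1, 1)      # alternate sides of the road
  xy <- do.call(rbind, lapply(tr, function(t)
    cbind(side[t] * config$offsets_km, y[t])))
  d_primary <- rep(config$offsets_km, times = config$n_transects)

  pad <- 5
  box <- c(min(xy[, 1]) - pad, max(xy[, 1]) + pad,
           min(xy[, 2]) - pad, max(xy[, 2]) + pad)
  sec <- rpoispp_box(config$secondary_road_intensity, box)
  fen <- rpoispp_box(config$fence_intensity, box)
  set_ <- rpoispp_box(config$settlement_intensity, box)

  df <- data.frame(
    site = sprintf("t%02dp%d", rep(tr, each = config$points_per_transect),
                   rep(seq_len(config$points_per_transect),
                       times = config$n_transects)),
    d_primary_km = d_primary,
    d_secondary_km = nearest_dist(xy, sec),
    d_fence_km = nearest_dist(xy, fen),
    d_settlement_km = nearest_dist(xy, set_),
    d_city_km = sqrt((xy[, 1] - config$city_xy[1])^2 +
                       (xy[, 2] - config$city_xy[2])^2))

  keep <- seq_len(nrow(df))
  if (!is.null(config$n_sites_target) &&
      config$n_sites_target < nrow(df))
    keep <- sort(sample(keep, config$n_sites_target))
  df <- df[keep, , drop = FALSE]
  xy <- xy[keep, , drop = FALSE]
  reps <- sample(seq(config$replicate_range[1], config$replicate_range[2]),
                 nrow(df), replace = TRUE)
  structure(list(covariates = site_covariates(df), replicates = reps,
                 xy = xy, config = config, seed = seed),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("survey_design: %d sites, %d-%d replicates each\n",
              nrow(x$covariates), min(x$replicates), max(x$replicates)))
  invisible(x)
}

#' Simulate a multi-species detection history from the community model
#'
#' The generative side of the community occupancy model. Species-level
#' occupancy and detection intercepts `(a_k, b_k)` are drawn jointly
#' bivariate-normal with correlation `rho`; the five slope coefficients are
#' drawn from their normal hyper-distributions. Occupancy is
#' `psi_ik = plogis(a_k + x_i' beta_k)` on standardized distances, the
#' latent occurrence `z_ik ~ Bern(psi_ik)`, and detections occur only where
#' `z = 1` and a survey took place, with species detection probability
#' `p_k = plogis(b_k)` constant across sites and replicates.
#'
#' @param hyper a [community_hyperparams].
#' @param design a `survey_design` from [generate_design].
#' @param n_species number of species in the community.
#' @param seed RNG seed.
#' @return list of class `community_simulation`: `detections` (a
#'   [binarize]-style `detection_history`), `truth` (realized species
#'   effects, latent `z`, and the hyper-parameters used), `covariates`
#'   (standardized).
#' @export
simulate_community <- function(hyper, design, n_species = 11L, seed = 1L) {
  stopifnot(inherits(hyper, "community_hyperparams"),
            inherits(design, "survey_design"))
  set.seed(seed)
  std <- standardize_covariates(design$covariates)
  S <- nrow(std$X); K <- as.integer(n_species)
  jmax <- max(design$replicates)
  mask <- outer(design$replicates, seq_len(jmax), ">=")

  # (a_k, b_k) jointly bivariate normal with correlation rho
  z1 <- rnorm(K); z2 <- rnorm(K)
  a <- hyper$mu_a + hyper$sigma_a * z1
  b <- hyper$mu_b + hyper$sigma_b *
    (hyper$rho * z1 + sqrt(1 - hyper$rho^2) * z2)
  beta <- sapply(seq_len(5), function(c)
    rnorm(K, hyper$mu_beta[c], hyper$sigma_beta[c]))
  beta <- matrix(beta, K, 5)

  psi <- plogis(sweep(std$X %*% t(beta), 2, a, "+"))   # S x K
  z <- matrix(rbinom(S * K, 1L, psi), S, K)
  p <- plogis(b)
  det <- array(0L, dim = c(S, jmax, K))
  for (k in seq_len(K)) {
    yk <- matrix(rbinom(S * jmax, 1L, p[k]), S, jmax)
    det[, , k] <- yk * z[, k] * mask
  }
  dh <- structure(
    list(detections = det, replicate_mask = mask,
         site_ids = std$site, species_names = paste0("sp", seq_len(K))),
    class = "detection_history")
  structure(
    list(detections = dh,
         truth = list(a = a, b = b, beta = beta, z = z, psi = psi,
                      p = p, hyper = hyper),
         covariates = std, seed = seed),
    class = "community_simulation")
}

#' Simulate single-species repeated counts from the N-mixture model
#'
#' The generative side of the abundance model: latent site abundance
#' `N_i ~ NegBin(lambda_i, alpha)` (mean `lambda_i`, overdispersion `alpha`,
#' `Var = lambda + lambda^2/alpha`), with
#' `log(lambda_i) = alpha0 + x_i' beta` on standardized distances, and each
#' survey's count a binomial thinning `y_ij ~ Binomial(N_i, p)`.
#'
#' @param params an [nmixture_params].
#' @param design a `survey_design` from [generate_design].
#' @param seed RNG seed.
#' @param species_name label for the simulated species.
#' @return list of class `abundance_simulation`: `counts` (a
#'   [survey_counts]), `truth` (latent `N`, `lambda`, and the parameters),
#'   `covariates` (standardized).
#' @export
simulate_counts <- function(params, design, seed = 1L,
                            species_name = "sim_species") {
  stopifnot(inherits(params, "nmixture_params"),
            inherits(design, "survey_design"))
  set.seed(seed)
  std <- standardize_covariates(design$covariates)
  S <- nrow(std$X)
  jmax <- max(design$replicates)
  mask <- outer(design$replicates, seq_len(jmax), ">=")
  lambda <- as.numeric(exp(params$alpha0 + std$X %*% params$beta))
  N <- rnbinom(S, size = params$alpha_disp, mu = lambda)
  p <- plogis(params$eta)
  y <- matrix(rbinom(S * jmax, rep(N, jmax), p), S, jmax) * mask
  counts <- survey_counts(array(y, dim = c(S, jmax, 1L)), mask,
                          std$site, species_name)
  structure(
    list(counts = counts,
         truth = list(N = N, lambda = lambda, params = params),
         covariates = std, seed = seed),
    class = "abundance_simulation")
}
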