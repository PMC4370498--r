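#' Run configuration for the simulate / fit / diagnose pipeline
#'
#' A flat key-value configuration naming the input CSVs, the model to fit,
#' sampler/optimizer settings and the seed. Round-trips through a plain
#' `key = value` text file ([read_run_config] / [write_run_config]);
#' values supplied here override file values.
#'
#' @param model `"occupancy"` or `"nmixture"`.
#' @param counts,covariates input CSV paths (omit when `simulate = TRUE`).
#' @param out_dir output directory, created if absent.
#' @param seed integer seed recorded in every output artifact.
#' @param simulate simulate inputs first instead of reading them.
#' @param species species to fit (nmixture), `"total"` allowed.
#' @param n_chains,n_iter MCMC settings (occupancy).
#' @param n_starts optimizer starts (nmixture).
#' @param n_species,n_sites simulated community size (when `simulate`).
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(model = c("occupancy", "nmixture"),
                       counts = NULL, covariates = NULL,
                       out_dir = "results", seed = 1L,
                       simulate = FALSE, species = "total",
                       n_chains = 3L, n_iter = 20000L, n_starts = 5L,
                       n_species = 11L, n_sites = 77L,
                       log_level = "info") {
  model <- match.arg(model)
  structure(list(model = model, counts = counts, covariates = covariates,
                 out_dir = out_dir, seed = as.integer(seed),
                 simulate = isTRUE(simulate) || identical(simulate, "TRUE"),
                 species = species,
                 n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_starts = as.integer(n_starts),
                 n_species = as.integer(n_species),
                 n_sites = as.integer(n_sites),
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path key-value text file, one `key = value` per line; `#` starts
#'   a comment.
#' @param ... overrides applied on top of the file's values.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(lapply(kv, function(x) x[2]), vapply(kv, `[[`, "", 1))
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  writeLines(paste(names(config)[keep], unlist(config[keep]), sep = " = "),
             path)
  invisible(path)
}

pipe_log <- function(config, log_file, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (!identical(config$log_level, "quiet")) message(msg)
  cat(msg, "\n", file = log_file, append = TRUE)
}

#' Run the full pipeline: (simulate) -> fit -> diagnose -> report
#'
#' Executes the configured stages, writes every output table under
#' `config$out_dir`, and finishes with a manifest listing each artifact
#' with its MD5 content hash, so any output is traceable to a config and
#' seed. Rhat at or above 1.1 and boundary estimates are logged as
#' prominent warnings, never silently passed. A stage failure raises an
#' error naming the stage.
#'
#' @param config a [run_config].
#' @return (invisibly) list with the fitted object and the manifest
#'   data.frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  cat("", file = log_file)
  artifacts <- character(0)
  put <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write.csv(df, path, row.names = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  pipe_log(config, log_file, "model=", config$model, " seed=", config$seed)

  if (config$simulate) {
    stage("simulate", {
      design <- generate_design(
        design_config(n_sites_target = config$n_sites), seed = config$seed)
      if (config$model == "occupancy") {
        sim <- simulate_community(
          community_hyperparams(mu_a = -0.5, sigma_a = 1, mu_b = -1,
                                sigma_b = 0.75, rho = 0.5,
                                mu_beta = c(-0.3, 0, 0, 0, -0.8),
                                sigma_beta = rep(0.4, 5)),
          design, n_species = config$n_species, seed = config$seed)
        counts_obj <- structure(
          list(counts = sim$detections$detections,
               replicate_mask = sim$detections$replicate_mask,
               site_ids = sim$detections$site_ids,
               species_names = sim$detections$species_names),
          class = "survey_counts")
      } else {
        sim <- simulate_counts(
          nmixture_params(alpha0 = 2.5, beta = c(-0.5, 0, 0.3, 0, -0.4),
                          alpha_disp = 1, eta = qlogis(0.1)),
          design, seed = config$seed)
        counts_obj <- sim$counts
      }
      config$counts <- put(long_counts_df(counts_obj), "sim_counts.csv")
      config$covariates <- put(as.data.frame(design$covariates),
                                "sim_covariates.csv")
      pipe_log(config, log_file, "simulated ", nrow(design$covariates),
               " sites")
    })
  }

  if (is.null(config$covariates) || !file.exists(config$covariates))
    stop("pipeline stage 'inputs' failed: covariates file not found: ",
         if (is.null(config$covariates)) "<unset>" else config$covariates)
  if (is.null(config$counts) || !file.exists(config$counts))
    stop("pipeline stage 'inputs' failed: counts file not found: ",
         if (is.null(config$counts)) "<unset>" else config$counts)

  counts <- stage("read", read_counts_csv(config$counts))
  covs <- stage("read", standardize_covariates(
    read_covariates_csv(config$covariates)))

  result <- NULL
  if (config$model == "occupancy") {
    fit <- stage("fit-occupancy", fit_community_occupancy(
      binarize(counts), covs,
      mcmc = mcmc_config(n_chains = config$n_chains, n_iter = config$n_iter),
      seed = config$seed))
    eff <- stage("diagnose", summarize_community_effects(fit,
                                                         check_rhat = FALSE))
    rh <- suppressWarnings(rhat_all(fit))
    if (any(rh >= 1.1, na.rm = TRUE))
      pipe_log(config, log_file, "WARNING: Rhat >= 1.1 for ",
               sum(rh >= 1.1, na.rm = TRUE), " parameter(s)")
    rich <- derived_richness(fit)
    put(cbind(eff, seed = config$seed), "community_effects.csv")
    put(cbind(rich$summary, seed = config$seed), "site_richness.csv")
    put(data.frame(parameter = names(rh), rhat = unname(rh),
                   seed = config$seed), "rhat.csv")
    result <- fit
  } else {
    fit <- stage("fit-nmixture", fit_nmixture(
      counts, covs, species = config$species, seed = config$seed,
      n_starts = config$n_starts))
    if (fit$boundary)
      pipe_log(config, log_file,
               "WARNING: boundary estimate, SEs unreliable")
    put(cbind(fit$inference, seed = config$seed), "nmixture_coefficients.csv")
    put(cbind(fit$detection, species = fit$species, seed = config$seed),
        "detection_probability.csv")
    result <- fit
  }

  artifacts <- c(artifacts, log_file)
  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         seed = config$seed)
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  pipe_log(config, log_file, "done: ", length(artifacts), " artifact(s)")
  invisible(list(result = result, manifest = manifest))
}

long_counts_df <- function(x) {
  d <- dim(x$counts)
  ij <- which(x$replicate_mask, arr.ind = TRUE)
  out <- do.call(rbind, lapply(seq_len(d[3]), function(k)
    data.frame(site = x$site_ids[ij[, 1]], replicate = ij[, 2],
               species = x$species_names[k],
               count = x$counts[cbind(ij[, 1], ij[, 2], k)])))
  out[order(match(out$site, x$site_ids), out$replicate), ]
}
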