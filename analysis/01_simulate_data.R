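#!/usr/bin/env Rscript
# Step 1: lay out the synthetic study landscape and simulate both kinds of
# survey data with known ground truth.
#
# The design mirrors the field protocol: 22 transects 1 km apart,
# perpendicular to a primary road, with point-count sites 1, 2, 3 and 5 km
# from the road (88 candidate points subsampled to the 77 surveyed sites),
# each site visited 2-12 times. Distances to five classes of human
# construction are the covariates of every model downstream.
#
# Outputs (results/data/): detection histories and single-species counts in
# the long CSV format, the covariate table, and the simulation truth.

library(occumix)

seed <- 20251001L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- generate_design(design_config(n_sites_target = 77), seed = seed)
cat("Design:", nrow(design$covariates), "sites,",
    sum(design$replicates), "surveys in total\n")
write_covariates_csv(design$covariates, file.path(out, "site_covariates.csv"))

## Community detection histories (11 species), moderate community-level
## proximity effects on city and primary-road distance
hyper <- community_hyperparams(
  mu_a = -0.5, sigma_a = 1, mu_b = -1, sigma_b = 0.75, rho = 0.5,
  mu_beta = c(-0.3, 0, 0, 0, -0.8), sigma_beta = rep(0.4, 5))
community <- simulate_community(hyper, design, n_species = 11, seed = seed)
dh <- community$detections
det_counts <- survey_counts(dh$detections, dh$replicate_mask,
                            dh$site_ids, dh$species_names)
write_counts_csv(det_counts, file.path(out, "community_detections.csv"))
write.csv(data.frame(species = dh$species_names,
                     a = community$truth$a, b = community$truth$b,
                     p = community$truth$p, community$truth$beta),
          file.path(out, "community_truth_effects.csv"), row.names = FALSE)
cat("Community: mean occupancy", round(mean(community$truth$z), 3),
    "| mean detection probability", round(mean(community$truth$p), 3), "\n")

## Single-species repeated counts from the N-mixture generative model
params <- nmixture_params(alpha0 = 2.5, beta = c(-0.5, 0, 0.3, 0, -0.4),
                          alpha_disp = 1, eta = qlogis(0.1))
abund <- simulate_counts(params, design, seed = seed + 1L)
write_counts_csv(abund$counts, file.path(out, "species_counts.csv"))
write.csv(data.frame(site = design$covariates$site, N = abund$truth$N,
                     lambda = abund$truth$lambda),
          file.path(out, "abundance_truth.csv"), row.names = FALSE)
cat("Abundance: latent N ranges", min(abund$truth$N), "-",
    max(abund$truth$N), "| total birds counted",
    sum(abund$counts$counts[abund$counts$replicate_mask]), "\n")
cat("Wrote", length(list.files(out)), "files under", out, "\n")
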