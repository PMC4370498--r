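# occumix

Detection-corrected hierarchical models for repeated point counts of birds
of prey, built around a Patagonian steppe study design: 77 sites along 22
transects perpendicular to a primary road, each surveyed 2–12 times, with
per-site distances (km) to five classes of human construction — primary
roads, secondary roads, fences, human settlements, cities — as predictors.

Raw counts confound presence/abundance with detectability, so the package
separates the two processes in both standard ways:

**Community richness — Bayesian multi-species occupancy model.** For site
*i* and species *k*,

    z_ik ~ Bern(psi_ik)                     (ecological process)
    y_ijk | z_ik ~ Bern(p_k * z_ik)         (observation process)
    logit(psi_ik) = a_k + beta_1k x_i1 + ... + beta_5k x_i5

Species-level effects are draws from community hyper-distributions
(`beta_ck ~ N(mu_beta_c, sigma_beta_c)`), with occupancy and detection
intercepts `(a_k, b_k)` jointly bivariate normal with correlation `rho`.
Fitting is Metropolis-within-Gibbs MCMC (compiled core; exact Gibbs for the
latent `z`), with Gelman–Rubin Rhat diagnostics. Site richness is the
derived quantity `N_i = sum_k z_ik` over posterior draws; conclusions about
richness drivers compare the `mu_beta` hyper-means.

**Single-species abundance — negative-binomial N-mixture model.**

    N_i ~ NegBin(lambda_i, alpha)           Var = lambda + lambda^2/alpha
    y_ij ~ Binomial(N_i, p)
    log(lambda_i) = alpha0 + beta_1 x_i1 + ... + beta_5 x_i5

fitted by truncated-sum maximum likelihood (analytic-gradient BFGS,
multi-start), with Wald tests, significance stars at p ≤ 0.1/0.05/0.01, a
back-transformed logit-scale interval for the detection probability, and a
"most influential covariate" rule (largest |estimate| among coefficients
with p ≤ 0.1).

Distances are standardized (mean 0, SD 1), so in every output a **negative
coefficient means the response increases with proximity** to that feature
class.

A synthetic-data module generates landscapes and surveys from the exact
study geometry with known ground truth, so both fitting routes are
validated by parameter recovery without any external data.

## Worked example

Simulate repeated counts at the study scale and fit the abundance model
(truth: `alpha0 = 2.5`, `beta = (-0.5, 0, 0.3, 0, -0.4)`, overdispersion 1,
detection probability 0.1):

```r
library(occumix)
design <- generate_design(design_config(n_sites_target = 77), seed = 7)
covs   <- standardize_covariates(design$covariates)
sim    <- simulate_counts(
  nmixture_params(alpha0 = 2.5, beta = c(-0.5, 0, 0.3, 0, -0.4),
                  alpha_disp = 1, eta = qlogis(0.1)),
  design, seed = 11)
fit <- fit_nmixture(sim$counts, covs, seed = 3)
fit
```

```
N-mixture fit (sim_species): 77 sites, K = 1246, logLik = -618.80
       parameter estimate    se     z        p stars
     (Intercept)    2.139 0.495  4.32 1.58e-05   ***
   primary_roads   -0.518 0.138 -3.75 1.80e-04   ***
 secondary_roads   -0.332 0.124 -2.68 7.42e-03   ***
          fences    0.325 0.131  2.47 1.35e-02    **
     settlements    0.056 0.138  0.41 6.83e-01      
          cities   -0.345 0.122 -2.82 4.75e-03   ***
       log_alpha    0.334 0.238  1.40 1.61e-01      
             eta   -2.026 0.551 -3.68 2.35e-04   ***
detection p = 0.11647 (0.04286, 0.27958)
most influential covariate: primary_roads
```

Read: the primary-roads coefficient −0.518 (truth −0.5) is negative, so
abundance rises toward the road; it is the largest-magnitude significant
standardized effect, hence "most influential". The detection probability is
recovered as 0.12 (truth 0.10) and the latent-abundance truncation bound K
was chosen automatically so the likelihood is stable to further increases.

The community model runs the same way on detection histories:

```r
hyper <- community_hyperparams(mu_a = -0.5, sigma_a = 1, mu_b = -1,
                               sigma_b = 0.75, rho = 0.5,
                               mu_beta = c(-0.3, 0, 0, 0, -0.8),
                               sigma_beta = rep(0.4, 5))
com <- simulate_community(hyper, design, n_species = 11, seed = 21)
cfit <- fit_community_occupancy(com$detections, covs, seed = 99)
summarize_community_effects(cfit)    # hyper-means, 95% CIs, significance
derived_richness(cfit)$summary       # per-site posterior richness
```

## Analysis workflow

The `analysis/` scripts run the full narrative on synthetic data and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R     # design + both data types + truth
Rscript analysis/02_fit_nmixture.R      # abundance model vs truth
Rscript analysis/03_fit_occupancy.R     # community model, richness, Rhat
Rscript analysis/04_diagnostics.R       # recovery report, fitted curves
```

Each fitting step goes through `run_pipeline()`, which writes a manifest
with an MD5 hash per artifact and logs any Rhat ≥ 1.1 or boundary estimate
as a prominent warning.

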