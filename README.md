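# rnmsom

Hierarchical multispecies Royle–Nichols models for camera-trap surveys
across hunting-management strata.

## What this is for

Camera-trap grids in Amazonian sustainable-use reserves are routinely
deployed to ask whether local hunting rules — here, a river bank where
hunting with dogs is allowed versus one where it is not — and distance
from the community affect wildlife. The data are detection histories for
dozens of species at a handful of stations, most species detected
rarely. `rnmsom` provides the complete inferential chain for that
design, aimed at quantitative ecologists and reserve-monitoring
programs:

1. **Detection histories** — collapse timestamped records into
   species × station occasion counts (5-day bins of a 49-day deployment
   by default), standardize covariates.
2. **Multispecies Royle–Nichols model** — for species *i* at station
   *j*,

   ```
   Z_ij ~ Poisson(lambda_ij)        latent abundance (habitat-use intensity)
   Y_ij ~ Binomial(V_j, p_ij)       detections over V_j occasions
   p_ij = 1 - (1 - r_ij)^Z_ij       abundance-induced detection
   ```

   with covariates (scaled distance, hunting stratum, interaction) on
   `log lambda` (Model 1, "abundance") or on `logit r` (Model 2,
   "detection"), species-level coefficients drawn from community normal
   hyperdistributions, and Dorazio–Royle data augmentation (`n_aug`
   all-zero species with inclusion indicators `w_i ~ Bernoulli(omega)`)
   so richness can exceed the observed species count. Fitting is by a
   purpose-built Metropolis-within-Gibbs sampler (Rcpp kernel for the
   exact enumeration of `Z`); see the methods vignette for the sampler
   design.
3. **Derived posteriors** — per-draw, per-site species richness,
   aggregated abundance `sum_i w_i Z_ij`, and aggregated biomass
   `sum_i w_i Z_ij m_i` (body masses from the shipped 29-species trait
   table).
4. **Mixed-model stage** — Bayesian Gaussian LMMs
   (`summary ~ distance + stratum + (1 | station)`) fitted by a
   conjugate Gibbs sampler, with the 95%-credible-interval support rule
   and Gelman–Rubin convergence diagnostics throughout.

A synthetic-community generator reproduces the study design exactly
(2 strata × 10 stations, distances 0.54–5.1 km, 29 species + 10
augmented, 49 days in 5-day occasions), so the whole chain is testable
by parameter recovery with no field data.

## Worked example

```r
library(rnmsom)

sim <- simulate_community(simulation_scenario(seed = 1), n_aug = 10)
sim$history
#> Detection history: 39 species (10 augmented) x 20 stations, V = 10 occasions
#> Total detections: 1006; species with >= 1 detection: 29

fit <- fit_msom(sim$history, sim$stations,
                rn_model_spec("abundance", n_aug = 10),
                rn_mcmc_config(n_chains = 3, n_iter = 5000,
                               burn_in = 2500, thin = 5, seed = 1))
summary(fit, include_species = FALSE)
#>               parameter    mean     sd    q2.5     q50  q97.5 rhat
#> 1              mu_beta0 -0.4170 0.3683 -1.2469 -0.4025  0.227 1.00
#> 2          mu_beta_dist  0.3429 0.1342  0.0840  0.3442  0.595 1.00
#> 3          mu_beta_dogs -0.5101 0.1630 -0.8517 -0.5020 -0.198 1.00
#> 4     mu_beta_dist_dogs  0.0494 0.1206 -0.1763  0.0519  0.292 1.01
#> 5            mu_logit_r -1.8114 0.1716 -2.2034 -1.7906 -1.542 1.03
#> ...                                                  (hyper-SDs, omega)
```

The community hypermeans recover the generating values (−0.5, 0.3,
−0.4, 0 on the log scale; −1.8 on the logit-detection scale): the
community-level distance effect on abundance is positive and its 95%
interval excludes zero, the hunting-with-dogs effect is negative and
supported, and the interaction is not supported. Every Rhat is at or
below 1.1.

Downstream, the richness LMM on the derived site summaries:

```r
site <- derive_site_summaries(fit, data.frame(
    code = sim$species_params$code,
    mass_kg = rep_len(focal_species()$mass_kg, 29)))
lmm <- fit_lmm(prepare_lmm_data(site, sim$stations, "richness"),
               rn_mcmc_config(n_chains = 3, n_iter = 10000,
                              burn_in = 5000, thin = 5, seed = 1))
summary(lmm)
#>            effect  mean   lo95   hi95 rhat supported direction
#> 1       intercept 15.91 14.591 17.079 1.03      TRUE  positive
#> 2 distance_scaled  1.74  0.675  2.812 1.08      TRUE  positive
#> 3    dogs_allowed -2.35 -3.874 -0.705 1.03      TRUE  negative
```

Estimated richness rises with distance from the community and drops by
about 2.4 species where hunting with dogs is allowed — the direction of
effect the synthetic community was built with.

`run_pipeline()` chains all stages (both model variants, three LMMs,
effect tables ordered by body mass with an `All.sp` community row, a
stratified record-count summary, and a JSON run manifest that flags any
monitored Rhat > 1.1). A shell wrapper lives at
`inst/scripts/run_pipeline.R`.

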