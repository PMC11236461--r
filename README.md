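# fragsar

Simulation-based benchmarking of species-richness and beta-diversity
estimators for fragmented landscapes, under imperfect detection and
incomplete spatial sampling.

## Who this is for

Ecologists and biostatisticians who fit species-area relationships
(SARs) or beta-diversity regressions to field survey data and want to
know how much imperfect detection distorts the fitted coefficients — and
whether asymptotic richness estimators or multi-species occupancy models
(MSOMs) actually fix it.

## What it does

`fragsar` simulates fragmented-landscape communities with known truth,
samples them the way field crews do, estimates diversity three ways, and
scores every estimator:

1. **Community simulator** — 25 patches spanning 25-20,000 ha
   (`Beta4(1, 4)` areas), 200 species from a log-normal abundance
   distribution inflated to a density of 500 individuals/ha, species-
   specific area responses `beta_i = 5 * Beta(alpha_i, 5)` with
   `alpha_i` ramping over `[0.1, alpha_max]` by inverse abundance rank,
   and capacity-constrained assignment of individuals in groups of 100.
2. **Sampling simulator** — logit-normal detection probabilities
   `logit(theta_i) ~ N(logit(mu), sigma)`, 5.93-ha transects placed
   proportionally to patch area up to a 16-transect cap, availability
   `n = round(N * pi_p)`, and `V` repeated binomial survey visits.
3. **Estimators** — observed pooled counts; bias-corrected Chao1 and the
   two-assemblage Hill q = 0 Sorensen decomposition (`2 - gamma/alpha`);
   and a data-augmented hierarchical MSOM
   (`omega ~ Bern(Omega)`, `z ~ Bern(omega * psi)`,
   `y ~ Binom(V, z * theta)`, `logit(psi) = delta0 + delta1 * x`)
   fitted by an adaptive Metropolis-within-Gibbs sampler with
   Gelman-Rubin convergence checks.
4. **Trend models & scoring** — ln-ln OLS SARs
   (`ln S = c + z ln Area`), logit-link quasi-binomial GLMs of pairwise
   Sorensen on `ln(dArea + 1)`, and bias / accuracy / precision per
   parameter x method x scenario over a factorial design (3 x 3 x 3 x 3
   = 81 combinations; 35 communities x 10 sampled datasets each in the
   full profile).

See `vignettes/estimator-benchmarking.Rmd` for the model details and
every numerical choice.

## Worked example

```r
library(fragsar)

land <- simulate_landscape(alpha_max = 8, seed = 7)
land
#> Fragmented landscape: 25 patches (25-20000 ha), 200 species, 51546000 individuals
#>   alpha_max = 8, density = 500 individuals/ha

truth <- community_parameters(land$patch_areas, m = land$N)
round(c(z = truth$z_value, c = truth$c_value), 3)
#>     z     c
#> 0.303 2.587

svy <- sample_landscape(land, mu = 0.2, sigma = 1.0, V = 6, seed = 8)
obs <- fit_sar(observed_richness(svy), land$patch_areas)
chao <- fit_sar(chao_richness_by_patch(svy$pooled), land$patch_areas)
round(c(true_z = truth$z_value, obs_z = obs$z_value, chao_z = chao$z_value), 3)
#> true_z  obs_z chao_z
#>  0.303  0.302  0.304
```

At this favourable detection scenario (mean detection 0.2, six visits)
the observed-count slope sits just below the true z-value — the sampled
fraction of the largest patches is small enough that low-abundance
species are never available there — while the asymptotic Chao estimate
recovers the deficit. A full scenario sweep aggregates this over
replicate sampled datasets:

```r
res <- run_experiment(experiment_config_desk(master_seed = 1))
subset(res$performance, parameter == "z_value")
#>     mu sigma alpha_max V scenario_id parameter   method      bias  accuracy
#> 11 0.2     1         8 6          S8   z_value     chao -0.000451 -0.000764
#> 12 0.2     1         8 6          S8   z_value observed -0.000973 -0.001309
```

Both routes underestimate the SAR slope (negative `bias`); the observed
route about twice as severely as the Chao correction. Biases grow an
order of magnitude at the low-detection scenarios (`mu_grid = 0.005`).

A command-line interface wraps the same pipeline:

```sh
Rscript -e 'fragsar::fragsar_cli()' simulate --alpha-max 8 --seed 7 --out land/
Rscript -e 'fragsar::fragsar_cli()' sample --landscape land/ --mu 0.2 --sigma 1 --out svy/
Rscript -e 'fragsar::fragsar_cli()' estimate --landscape land/ --survey svy/ --method all --out est/
Rscript -e 'fragsar::fragsar_cli()' run --seed 1 --out experiment/
```

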