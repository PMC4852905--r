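# scrsearch

Bayesian sex-specific spatially explicit capture–recapture (SECR) for
**unstructured search-encounter surveys**: observers drive freely through a
study area logging GPS tracks, photograph every individually recognisable
animal they find, and the package turns tracks + sightings + a habitat mask
into a posterior for population density, with sex-specific movement scales
and a full map of where the animals are.

It is aimed at wildlife ecologists estimating densities of low-density,
individually identifiable species (large carnivores are the motivating
case) where camera-trap grids are impractical and search effort is
inherently patchy.

## The model

Each animal has a latent activity centre on a habitat-masked grid of
0.65 km pixels (the state space, searched area + buffer). The searched
area is discretised into 1 km "trap" pixels; a trap is active on a day if
it was searched that day, and the kilometres driven in trap *j* on day *k*
enter as an effort covariate. Detection is Bernoulli per
individual × trap × day with a complementary log-log probability

    cloglog(pi_ijk) = log(lam0) + beta_eff * log(EFFORT_jk)
                      + beta_sex * SEX_i - (d_ij / sigma_sex)^(2 * theta)

so `1 - exp(-lam0)` is the probability of sighting an animal per km driven
through its activity-centre pixel, `sigma_F`/`sigma_M` are sex-specific
movement scales (km), and `theta` interpolates the detection kernel between
negative-exponential (0.5) and Gaussian (1). Abundance uses data
augmentation: `N_super ~ Bin(M, psi)` over `M = n + n_z` real-plus-padded
histories, latent sexes are Bernoulli(`psi_sex`), and density is
`D = 100 * N_super / suitable_area` per 100 km². Four a priori variants
fix or free `beta_sex` and `theta`; inference is
Metropolis–Hastings-within-Gibbs MCMC with Gelman–Rubin convergence
diagnostics, a Freeman–Tukey posterior predictive check, and a pixel-level
posterior density surface.

Because raw data of this kind are rarely public, the package includes a
first-class synthetic-survey generator (landscape, habitat mask, correlated
random-walk search tracks, population, encounters) used throughout the
tests and reproducibility script.

## Worked example

Simulate a survey at the bundled study scale (92 daily occasions, five
vehicles, ~8,400 km of patchy effort, 42.6% unsuitable habitat), fit the
full sex-specific model, and summarise:

```r
library(scrsearch)

sim <- simulate_survey(cheetah_scenario(), seed = 1)
enc <- build_encounter_array(sim$sightings, sim$effort)
enc
#> encounter_data: 23 individuals (14 F, 9 M), 55 detection cells over 784 traps x 92 occasions

mmdm(sim$sightings, group = "sex")$mmdm
#>         F         M
#>  1.705592 11.963089

fit <- run_chains(enc, sim$space, M = 335, variant = model_variant(1),
                  config = sampler_config(iterations = 3000, burnin = 1000,
                                          thin = 2, chains = 4, seed = 2))
summarize_posterior(fit)
#> Model 1: 4000 retained samples, max PSRF 1.048, Bayesian p-value NA
#>  parameter      mean        sd  psrf
#>       lam0  0.005093  0.002829 1.014
#>   beta_eff -0.016160  0.177400 1.001
#>   beta_sex -0.299900  0.555600 1.030
#>    sigma_F  3.287000  0.954100 1.004
#>    sigma_M  9.854000  2.750000 1.034
#>      theta  0.775000  0.143500 1.048
#>        psi  0.276400  0.070970 1.007
#>    psi_sex  0.187400  0.073820 1.001
#>    N_super 92.040000 22.570000 1.008
#>          D  4.387000  1.076000 1.008
#>  sex_ratio  5.276000  2.791000    NA
```

The posterior mean density (4.4 animals / 100 km² of suitable habitat;
the scenario's truth, 6.2, sits inside the posterior spread) comes with
its posterior SD, the `sigma` rows say males range ~3× further than
females (truth: 8 vs 3 km), and `sex_ratio` is the implied number of
females per male (truth 5.2 at `psi_sex = 0.162`). A per-pixel
expected-density map and model-adequacy check:

```r
pv <- bayesian_pvalue(fit, seed = 3)
pv$p_value
#> [1] 0.405                               # inside (0.15, 0.85): adequate
surf <- density_surface(fit)           # animals per km^2 per 0.65 km pixel
write_ascii_grid(surf$grid, "density_surface.asc")
```

File-based workflows use the same machinery through
`run_simulate()` / `run_fit()` / `run_report()` (CSV tracks and
sightings, ESRI ASCII habitat mask; per-chain draw CSVs, summary table,
diagnostics JSON and density grid out), or the thin command-line wrapper
in `inst/scripts/scrsearch`.

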