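---
title: "Sex-specific SECR for search-encounter data: model and methods"
author: "scrsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific SECR for search-encounter data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scrsearch)
```

## The estimation problem

`scrsearch` estimates the density of individually recognisable animals from
an *unstructured* search-encounter survey: observers drive through a study
area, record their GPS track continuously, and photograph every animal they
find. Unlike a camera-trap grid there are no fixed detectors, so detection
effort varies continuously in space and time and must be reconstructed from
the tracks themselves. The package was built around the design of an
intensive three-month cheetah survey (five vehicles, daily occasions,
thousands of kilometres of driving), but nothing in the code is specific to
cheetahs: any species whose individuals can be identified from sightings
fits the framework.

The approach is spatially explicit capture-recapture (SECR) with data
augmentation, fitted by Markov chain Monte Carlo:

* **Traps.** The searched area is discretised into square "trap" pixels
  (default 1 km side). A trap is *active* on a day if any search effort
  fell inside it that day; the kilometres driven in pixel $j$ on occasion
  $k$ form the effort covariate $\mathrm{EFFORT}_{jk}$.
* **State space.** Candidate activity centres live on a finer grid
  (default 650 m side, 0.4225 km$^2$ pixels) covering the searched area
  plus a buffer. Pixels of unsuitable habitat are masked out: they can hold
  no activity centre and contribute no area to density.
* **Observation model.** Detection of individual $i$ in trap $j$ on
  occasion $k$ is Bernoulli with a complementary log-log probability
  $$\mathrm{cloglog}(\pi_{ijk}) = \log\lambda_0
    + \beta_{\mathrm{eff}}\,\log(\mathrm{EFFORT}_{jk})
    + \beta_{\mathrm{sex}}\,\mathrm{SEX}_i
    - f\!\big(d_{ij}\mid\theta,\sigma_{\mathrm{sex}(i)}\big),$$
  where $d_{ij}$ is the distance from $i$'s activity centre to the trap
  centroid. The cloglog link means hazards add over effort, so
  $1 - \exp(-\lambda_0)$ is the probability of a sighting per kilometre
  driven through the activity centre's pixel.
* **Detection kernel.** $f(d) = (d/\sigma)^{2\theta}$ with
  $\theta \in [0.5, 1]$: $\exp(-f)$ is a negative exponential in $d$ at
  $\theta = 0.5$ (activity tightly concentrated at the centre) and Gaussian
  at $\theta = 1$ (diffuse space use). The literature rarely writes this
  hybrid kernel explicitly; we chose the parameterisation in which
  $\sigma$ keeps kilometre units for every $\theta$ and both limit shapes
  are exact. Alternative scalings such as $d^{2\theta}/(2\sigma^2)$ only
  relabel $\sigma$; comparisons of $\sigma$ across implementations must
  account for this.
* **Sexes.** Movement scale is sex-specific ($\sigma_F$, $\sigma_M$) in
  *all* model variants; $\beta_{\mathrm{sex}}$ shifts the cloglog
  intercept for males. Sexes of detected individuals must be observed;
  sexes of augmented individuals are latent Bernoulli($\psi_{\mathrm{sex}}$)
  variables, and the implied sex ratio is
  $(1-\psi_{\mathrm{sex}})/\psi_{\mathrm{sex}}$ females per male.
* **Data augmentation.** The $n$ detected histories are padded with
  $n_z$ all-zero histories to size $M = n + n_z$; individual $i$ is in the
  population iff a latent indicator $z_i = 1$, with
  $z_i \sim \mathrm{Bernoulli}(\psi)$ and
  $[N_{\mathrm{super}} \mid M, \psi] \sim \mathrm{Bin}(M, \psi)$.
  Density is $D = 100\,N_{\mathrm{super}}/A_{\mathrm{suitable}}$ per
  100 km$^2$. $M$ should be set so the posterior of $\psi$ stays inside
  (0.2, 0.8); `run_chains()` warns when it does not.

Four a priori model variants are supported (`model_variant()`):
1 = $\beta_{\mathrm{sex}}$ and $\theta$ both free; 2 = $\beta_{\mathrm{sex}}
\equiv 0$; 3 = both fixed ($\theta = 0.75$); 4 = $\theta$ fixed. The fixed
$\theta$ value is configurable.

## Priors

Flat improper priors on $\log\lambda_0$, $\beta_{\mathrm{eff}}$ and
$\beta_{\mathrm{sex}}$; Uniform(0.5, 1) on $\theta$; Beta(1, 1) on $\psi$;
Beta(1, 1) on $\psi_{\mathrm{sex}}$ (chosen by symmetry with $\psi$ — no
other choice is forced by the model).

The movement scales deserve a note. A flat prior on $\sigma$ over
$[0, \infty)$ makes the posterior *improper* whenever the likelihood does
not vanish as $\sigma \to \infty$ — which happens in practice, because at
very large $\sigma$ the kernel saturates at 1 everywhere and the
likelihood flattens into a ridge traded off against a small $\lambda_0$.
We therefore implement the $\sigma$ prior as Uniform$[0, \sigma_{\max}]$
with $\sigma_{\max}$ equal to the diagonal of the state space: movement
scales larger than the landscape are not estimable from, or meaningful
for, these data, and the bound keeps the posterior proper without
informative content in the region the data can reach.

## From raw data to model inputs

**Effort rasterization** (`rasterize_effort()`). Each segment between
consecutive GPS fixes contributes its Euclidean length to the trap pixel
containing the segment *midpoint*, on the occasion of the segment's start.
With fixes every few seconds, segments are far shorter than a pixel and
the midpoint rule differs negligibly from exact polyline clipping while
keeping the code simple. Occasions are calendar days (trap "activity" is
"was this pixel searched today"); segments spanning midnight are split at
the day boundary by linear interpolation in time. Consecutive fixes more
than `max_gap_s` apart (default one hour) are treated as separate
recording sessions — a vehicle parked overnight must not donate a
straight-line "drive" across the map. Fixes outside the trap grid are
dropped with a warning. Total assigned effort equals total within-session
track length to floating precision, and the test suite asserts it.

**Encounter histories** (`build_encounter_array()`). Repeated sightings of
one individual in the same pixel on the same day collapse to a single 1:
the observation model is Bernoulli per cell, and survey protocols avoid
re-driving a route within a day, so multiplicity carries no extra
information. A sighting in a trap-day with *no* recorded effort (e.g. a
tourist report the team drove to, with the logger off) keeps the
detection; effort in that cell is floored at a configurable 0.1 km and the
imputation is logged — the detection proves a searcher was present, so
treating the trap as inactive would contradict the data, and the
likelihood would be undefined.

**Coordinates.** All inputs are planar projected kilometres. Conversion
from geographic coordinates is a pre-processing concern outside the model,
which is purely Euclidean. Rasters follow the ESRI ASCII grid convention
(row-major from the north-west corner).

## The sampler

`run_chains()` is a Metropolis-Hastings-within-Gibbs sampler. Each sweep
updates, in order: the free detection parameters (one-at-a-time Gaussian
random walks on transformed scales: $\log\lambda_0$, raw $\beta$s,
$\log\sigma$, logit-rescaled $\theta$, with the appropriate Jacobians);
the activity centres; the inclusion indicators $z$; the latent sexes and
$\psi_{\mathrm{sex}}$; and finally $\psi$. Running the conjugate steps
last keeps the recorded $N_{\mathrm{super}} = \sum_i z_i$ consistent
within an iteration.

* **Activity centres** are proposed uniformly among suitable pixels in a
  square window (default half-width 10 pixels) around the current pixel.
  Near mask edges the windows of the current and proposed pixels can
  contain different numbers of suitable pixels, so the Hastings ratio
  includes the forward/reverse window-count ratio. A global-uniform
  proposal would mix poorly at realistic state-space sizes.
* **$z$ update:** for undetected individuals,
  $\Pr(z_i = 1 \mid \cdot) = \psi q_i / (\psi q_i + 1 - \psi)$ with $q_i$
  the probability of an all-zero history at the individual's centre and
  sex. Detected individuals keep $z = 1$.
* **Sex update:** augmented individuals draw sex with odds
  $\psi_{\mathrm{sex}} L_i(M) : (1-\psi_{\mathrm{sex}}) L_i(F)$, where
  $L_i$ is the all-zero-history likelihood if $z_i = 1$ and 1 otherwise;
  $\psi_{\mathrm{sex}}$ then has a conjugate Beta update over included
  individuals.
* **Adaptation** (burn-in only): proposal scales follow a Robbins-Monro
  recursion toward ~35% acceptance and the activity-centre window adapts
  toward 20-60%; everything is frozen after burn-in so the retained draws
  come from a fixed, detailed-balanced kernel.
* **Initialization:** detected individuals start at the nearest suitable
  pixel to the centroid of their detections; augmented centres are uniform;
  $\sigma$s start at half the per-sex mean maximum distance moved (floored
  at 0.5 km); $\lambda_0$ at detections per total effort km; $\psi$ at
  $n/M$; $\theta$ at 0.75. A non-finite initial likelihood triggers
  bounded re-initialization of the augmented centres, then an error.
* **Numerical guards:** $\log(1-\pi)$ is computed as $-h$ and $\log\pi$ as
  `log(-expm1(-h))` for hazard $h$; the logit coordinate of $\theta$ is
  clamped to $[-30, 30]$ so rounding can never place $\theta$ exactly on
  the closed boundary of $(0.5, 1)$, where the Jacobian is undefined.
* **Determinism:** per-chain seeds derive from the single master seed;
  identical configurations are bit-identical, which the tests assert.

Defaults mirror a realistic production run: 11,000 iterations, 1,000
burn-in, thinning 2 (hence 5,000 retained per chain), 8 chains. All are
configurable, and the test suite and acceptance script use shorter chains
(stated below).

## Diagnostics, adequacy, and the density surface

* `gelman_rubin()` implements the classic potential scale reduction factor
  $\sqrt{((L-1)/L\,W + B/L)/W}$; identical constant chains return 1 by
  convention. The convergence verdict in `diagnostics_report()` is
  max PSRF < 1.2 across monitored quantities.
* `bayesian_pvalue()` is a posterior predictive check with a Freeman-Tukey
  discrepancy on *individual encounter totals*:
  $T = \sum_{i: z_i = 1} (\sqrt{y_{i\cdot}} - \sqrt{e_{i\cdot}})^2$, with a
  replicate data set simulated per evaluated draw and
  $p = \Pr(T^{\mathrm{rep}} \ge T^{\mathrm{obs}})$. The statistic could
  alternatively be summed over traps as well; the per-individual total is
  this package's fixed choice and is recorded in the report. Adequacy
  verdict: $p \in (0.15, 0.85)$.
* `density_surface()` divides the posterior mean count of included
  activity centres per pixel by the pixel area; summing the surface times
  pixel area returns the posterior mean of $N_{\mathrm{super}}$ exactly
  (a test asserts this conservation).

## The synthetic-data generator

Real search-encounter data sets of this kind are rarely public, so the
generator (`simulate_survey()`) is first-class, tested code that emulates
the statistical structure the estimator assumes: a masked landscape with
blob-shaped unsuitable patches; activity centres uniform on suitable
pixels with Bernoulli($\psi_{\mathrm{sex}}$) sexes; searcher-days as
correlated random walks with constant fix spacing, optionally biased
toward patrol centres near the middle of the area (the `hotspot` flag) to
produce the spatially patchy effort characteristic of unstructured
surveys; and detections drawn independently per active cell from the same
cloglog model the estimator fits.

The bundled scenario (`cheetah_scenario()`, stored as a versioned YAML
file under `extdata`) reproduces the design quantities of the motivating
survey: 92 daily occasions, five vehicles, ~8,400 km of patchy effort,
42.58% unsuitable habitat, a strongly female-biased population
($\psi_{\mathrm{sex}} = 0.162$), $\sigma_F = 3$ km $< \sigma_M = 8$ km,
and $\lambda_0 = 0.004$ per km. Its landscape (28 km searched extent with
a 16 km buffer) is deliberately smaller than the ~20,000 km$^2$ original
so an end-to-end fit stays cheap; the population size (130) was tuned once
so the *expected* detected-individual count is ≈25 with ≈55 sightings,
matching the survey's information content. A consequence of compressing
the landscape while holding effort and counts fixed is that the fixture's
true density (~6/100 km$^2$) is several times the motivating study's
(~1.3/100 km$^2$); the fixture reproduces the survey's *sample sizes and
structure*, not its absolute density.

What the generator does **not** emulate: animal movement within the survey
(activity centres are static; there is no telemetry-like autocorrelation),
behavioural responses to capture, unmodelled individual heterogeneity, or
the true spatial autocorrelation of real search tracks (the random-walk
parameters are not calibrated to any data set). Passing tests on
synthetic data therefore demonstrate the estimator is correct *under its
own assumptions* — the exact-enumeration and likelihood oracles show the
machinery computes the intended posterior — but they cannot certify
robustness to the violations real data bring.

## Test and acceptance problem sizes

The distribution checks use deliberately small configurations chosen to
run comfortably on one CPU:

* the exact-posterior oracle uses $M = 3$, $J = 4$, $K = 2$, six suitable
  pixels, with detection parameters frozen, one chain of 60,000
  iterations, and batch-means Monte-Carlo standard errors;
* the parameter-recovery study uses 20 replicates of a 20 × 20 km searched
  area (2 km trap pixels, 1 km state-space pixels, 4 km buffer, 20%
  unsuitable), $N = 40$, $K = 30$, two vehicles driving 50 km/day,
  $\lambda_0 = 0.1$, $\sigma_F = 2$, $\sigma_M = 5$, fitted with Model 1
  and 2 chains × 4,000 iterations. The search intensity was chosen so
  detected females average ~2.5 captures — single-capture females leave
  $\sigma_F$ essentially unidentified and the posterior then legitimately
  supports a "rare but wide-ranging" ridge, which is a property of sparse
  data, not of the sampler;
* the reproducibility script fits the bundled study-scale scenario with
  $M = 335$ and 3 chains × 2,500 iterations.

## Known limitations

* Closure is assumed; there are no open-population dynamics.
* No behavioural (trap-response) effects, no continuous activity-centre
  support, and no model selection beyond the adequacy check — the four
  variants are compared on equal footing, as in the motivating analysis.
* With few detections per individual, $D$ and $\psi_{\mathrm{sex}}$ are
  strongly negatively correlated in the posterior and $\sigma$ for the
  sparser sex mixes slowly; inspect the PSRF table and widen $M$ or run
  longer chains when in doubt.
* The effort floor for off-effort sightings is a pragmatic imputation; its
  value (0.1 km) is configurable and flagged in the fit metadata.
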