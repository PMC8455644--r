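---
title: "Estimating conspecific negative density dependence from stem maps"
author: "forestcndd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating conspecific negative density dependence from stem maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcndd)
```

## The scientific problem

The Janzen–Connell hypothesis proposes that specialized natural enemies
accumulating near conspecific adults suppress conspecific recruitment,
freeing space for other species and thereby maintaining diversity.  A
single census of a stem-mapped forest plot contains a static snapshot of
this process: quadrats dense in conspecific adults should hold *fewer*
saplings of that species than their adult density alone would predict.
`forestcndd` implements the quadrat-based estimator of this effect —
conspecific negative density dependence (CNDD) — together with the
statistical layer needed to relate it to diversity and environmental
gradients across a network of plots, and a synthetic-forest generator
that makes every stage verifiable by parameter recovery.

## The recruitment model

For one focal species in one plot, stems are split into adults and
saplings and binned into square quadrats (10 × 10 m and 20 × 20 m).  With
$S_i$ the focal saplings, $A_i$ the focal adults, and $a_i$, $s_i$ the
heterospecific adults and saplings in quadrat $i$, the Ricker recruitment
model with negative-binomial error is

$$\mu_i = A_i \exp\left(r + \mathrm{CNDD}\,A_i +
  \mathrm{HNDD}_{adult}\,a_i + \mathrm{HNDD}_{sap}\,s_i\right),
  \qquad S_i \sim \mathrm{NegBin}(\mu_i, \gamma),$$

where $r$ is the recruitment rate at low conspecific density, CNDD is
the per-conspecific-adult effect on recruitment (more negative =
stronger density dependence), the HNDD terms are the heterospecific
analogues, and $\gamma$ is the negative-binomial size parameter in the
$\mathrm{Var} = \mu + \mu^2/\gamma$ parameterization.  The model allows
overcompensation: recruitment first rises and then falls with adult
density when CNDD < 0.

Some modelling choices deserve comment:

* **Zero-adult quadrats.**  Under the model, $\mu_i = 0$ whenever
  $A_i = 0$, so quadrats without conspecific adults carry either zero or
  infinite likelihood.  The default `"drop"` policy excludes them from
  the focal species' likelihood.  A `"floor"` policy
  ($\mu_i = (A_i + \varepsilon) e^{\eta_i}$) is available for
  sensitivity analysis; the policy used is recorded in every output.
* **Fitting.**  `fit_ricker()` maximizes the joint likelihood over
  $(r, \mathrm{CNDD}, \mathrm{HNDD}_{adult}, \mathrm{HNDD}_{sap},
  \log\gamma)$ by multi-start BFGS (5 starts: a Poisson-GLM/moment
  informed start plus jittered copies under fixed sub-seeds; analytic
  score; gradient tolerance `reltol = 1e-10`).  Standard errors come
  from the inverse observed information (numerical Hessian); the
  `converged` flag additionally requires positive-definite curvature, so
  confounded designs (e.g. constant $A_i$, where $r$ and CNDD are not
  separately identifiable) are flagged instead of returning arbitrary
  numbers.
* **Staging.**  Saplings are trees with DBH below 15 cm (DBH = GBH/π).
  If fewer than 20% of a species' individuals in a plot would be adults,
  the threshold falls back to 10 cm and then 5 cm.  The scope of this
  rule is each species within each plot by default (the per-plot variant
  is available), and each tree's adult/sapling status uses its own
  species' threshold, also when counted as a heterospecific.  A
  sapling-cap sensitivity run (10 cm definition) is obtained with
  `stage_threshold_policy(thresholds = c(10, 5))`.
* **Exclusion rules.**  Species whose adults or saplings occupy fewer
  than 10 quadrats, whose CNDD standard error exceeds 4 (strictly), or
  whose fit did not converge are excluded; reasons are kept in an
  exclusion ledger.  The occupancy rule is read as "both occupancies
  must reach 10" (the `"either"` reading is available by configuration).
* **Plot aggregation.**  Plot-level CNDD is the arithmetic mean of the
  retained species' CNDD estimates.  HNDD means are reported alongside
  but, because heterospecific effects are weak and near zero, downstream
  analyses consume CNDD only.

### Sign convention

The raw coefficient is most negative where density dependence is
strongest.  Analyses and outputs therefore also carry
`cndd_strength = -mean_cndd`, so that *larger values mean stronger
density dependence*; correlations and GLMs in the gradient layer use
this strength scale.  Both columns are present in every summary table.

## Statistical layer

* `spearman_correlation()` — Pearson correlation of average ranks with
  the two-sided t-approximation p-value; used for all
  CNDD/diversity/gradient correlation tables (overall, within forest
  types, old-growth only), with the linear-model $r^2$ reported for the
  overall fits.
* `fit_poisson_glm()` / `interaction_lr_test()` — log-link Poisson GLMs
  of species number on gradient × CNDD, compared by the chi-square
  likelihood-ratio test (additive vs interaction), with the deviance
  pseudo-$R^2$ ($1 - D_{res}/D_{null}$) reported for the nested sequence
  ENV → ENV + CNDD → ENV × CNDD.  Significance marks follow the
  convention `*` for $P \le 0.05$ and `x` for $P \le 0.1$.  No
  multiple-testing correction is applied anywhere in this layer, a
  deliberate match to the analysis this package reproduces; treat
  marginal stars accordingly.
* `species_level_correlations()` — per-species correlations across plots
  (species present in at least six plots), plus the pooled correlation
  of species-plot CNDD strength with log basal area.
* Snow depth enters as $\ln(x+1)$ because of its strong skew; latitude
  is not offered as a gradient since it is nearly collinear with
  temperature in the emulated design.

## Spatial aggregation diagnostics

Aggregated species concentrate conspecifics in few quadrats, which is
both ecologically interesting and a potential confounder of
quadrat-based CNDD, so each species' pattern (≥ 25 individuals in a
plot) is classified with the inhomogeneous pair correlation function
$g(r)$:

* `estimate_intensity()` — Gaussian kernel surface (SD 30 m, 2 m grid),
  each kernel renormalized by its mass inside the window, so the surface
  integrates to the point count (checked to 1%).
* `pcf_inhom()` — kernel estimator of $g(r)$ with Epanechnikov kernel
  (half-width $0.15/\sqrt{\lambda}$, Stoyan's rule of thumb), Ripley
  isotropic edge-correction weights computed in closed form for
  rectangular windows, divisor $2\pi r |W|$, and per-pair weights
  $1/(\lambda(x_i)\lambda(x_j))$; implemented in C++ with an r grid of
  513 values on (0, 25] m.
* `gof_envelope_test()` — 199 simulations of the inhomogeneous Poisson
  null with the intensity estimated **once** from the observed pattern;
  the DCLF statistic $u = \sum_r (g(r) - \bar g_{-}(r))^2\,\Delta r$
  over $r \le 20$ m (each pattern's reference mean excludes itself), and
  the exchangeable-rank p-value $(1 + \#\{u_{sim} \ge u_{obs}\})/200$,
  whose smallest attainable value is 0.005.  A significant pattern is
  called aggregated or regular by the sign of its mean PCF deviation.
  One subtlety: the observed surface is only the *simulation* intensity;
  each pattern's own PCF uses that pattern's own intensity estimate
  (count/area in the homogeneous case, its own kernel surface
  otherwise).  Normalizing every pattern by one fixed intensity would
  push each realization's count fluctuation, $(m/n)^2$, straight into
  $\hat g$, inflating the null distribution of $u$ and with it the
  test's power loss against clustering.
* `plot_aggregation_summary()` — the proportion of eligible species
  classified significantly aggregated ($P \le 0.05$) per plot, joined to
  the plot summary.

The distance range of the goodness-of-fit statistic (up to 20 m, the
larger quadrat size) and the PCF smoothing settings are conventional
defaults, exposed in the configuration.

## The synthetic forest generator

`generate_multiplot_dataset()` creates a plot network whose statistical
structure matches what the analysis assumes, with fully known truth:

* 32 plots of 100 × 100 m (the real networks' 0.8–1.2 ha plots do not
  publish per-site rectangles, so a square hectare is assumed), a latent
  altitude gradient uniform on 33–1730 m with temperature decreasing,
  precipitation increasing with temperature, and snow depth increasing
  with altitude (Gaussian noise on each; only the sign structure of
  these couplings is intended, not their exact magnitudes).
* A log-series species pool (300 species, weights $x^k/k$ with
  $x = 0.995$); each plot draws its richness from a log-linear model
  (below), samples that many species from the pool, gives each one
  founder adult and distributes the remaining adults multinomially.
  The founder guarantees that realized richness equals generated
  richness, keeping the richness GLM well-specified.
* True plot-mean CNDD is linear in standardized altitude
  ($-0.21 + 0.12\,z_{alt}$, i.e. roughly $-0.41$ to $-0.01$ with density
  dependence strongest at low altitude); species deviate around the plot
  mean with SD 0.04.  Recruitment rates are uniform on (0.3, 0.8),
  heterospecific coefficients are 0, and $\gamma = 3$.
* Adults are placed as a Thomas cluster process (parents
  $8\times10^{-4}$/m², offspring SD 7 m) — mild intraspecific
  aggregation like real stem maps.  This matters statistically: it is
  the within-plot variation in per-quadrat adult counts that identifies
  CNDD, and uniformly placed adults of mid-abundance species generate
  almost none.  Conditioning a cluster pattern on its abundance is done
  by inflating the offspring intensity and thinning uniformly — both
  operations leave the Thomas $g(r)$ unchanged, whereas superposing
  extra independent realizations (the obvious alternative) dilutes
  clustering and would bias the spatial stage's oracle tests.
* Sapling counts are drawn per quadrat directly from the
  Ricker/negative-binomial mean — the model's own data-generating
  process — and placed uniformly inside their quadrat.  A dispersal
  kernel is deliberately *not* used: truth must stay inside the fitted
  model family for recovery tests to be interpretable.  Adults get DBH
  uniform on [15, 60] cm and saplings on [5, 10) cm (GBH = π · DBH), so
  the adaptive staging thresholds reproduce the generated stages
  exactly.
* Expected richness is
  $45\exp(-0.12\,z_{alt} + 0.18\,z_{str} - 0.18\,z_{alt} z_{str})$ with
  $z_{str}$ the standardized true CNDD strength: richer plots where
  density dependence is strong, and a CNDD effect on richness that
  fades as altitude (environmental limitation) increases.

### Calibration of the study conditions

The generator's defaults are the package's fixed study conditions, and
the effect sizes were set analytically, not by trial: with ~1200 adults
over ~15–20 retained species per plot, per-species CNDD estimation noise
(SD ≈ 0.3–0.5) averages to plot-mean noise of ≈ 0.07–0.1, so a truth
gradient of SD 0.12 yields an estimate–truth correlation near 0.7–0.8
and essentially full power for the plot-level Spearman tests at
$n = 32$.  The same reliability (≈ 0.65–0.7) attenuates the richness
interaction; the interaction coefficient $-0.18$ was chosen so that the
attenuated noncentrality ($\approx 0.18^2 \cdot 32 \cdot 45 \cdot 0.8
\cdot 0.65^2 \approx 16$) leaves the likelihood-ratio test near-certain
to detect it.  Two consequences of these choices are documented rather
than hidden: plots carry about twice the stem density of the census the
generator emulates (an identifiability choice), and recovery statements
are conditional on aggregation-driven adult-count variation.

### What passing tests do and do not show

The generator emulates the *statistical* structure the estimator
assumes — it does not simulate dispersal, habitat heterogeneity,
topography, typhoon disturbance, browsing, or measurement error, and the
recruitment truth lives exactly in the fitted family.  Parameter
recovery under these conditions validates the implementation (the
estimator, filters, tests and plumbing), not the biological adequacy of
quadrat-based CNDD estimation on real forests, which remains debated;
on real data the estimates inherit that debate's caveats (static census,
possible aggregation confounding — which the spatial stage is there to
diagnose).

## Numerical choices and degenerate inputs

* Quadrat binning is half-open with the upper plot boundary clamped into
  the last quadrat; residual strips of non-divisible plots are dropped
  (with their stems, logged) so all quadrats keep equal area.
* Likelihood failures (all starts diverge), singular curvature, and
  empty scope units are flagged and excluded downstream, never silently
  imputed.
* Monte-Carlo p-values are exchangeable-rank based; with 199 simulations
  the attainable p-values are exactly $k/200$.
* All randomness flows from one master seed through counter-based
  sub-seeds (`derive_seed()`), so stages are reproducible independently
  of execution order; every table write keeps ≥ 15 significant digits so
  round-trips are lossless at test tolerance.

## Problem sizes used in the shipped checks

The standing verification sizes (chosen as the package's own trade-off
between Monte-Carlo resolution and a laptop-scale run): 200 replicates
for estimator bias/coverage (400 quadrats each), 1000 null replicates
for the interaction test's type-I error and 400 for its power, 200 CSR
and 100 Thomas replicates (199 null simulations each) for the spatial
layer, and 30 end-to-end 32-plot recovery replicates.  The acceptance
script runs the full pipeline on one default archipelago, with the
spatial stage on a six-plot subset at the full 199 simulations.

## Known limitations

* The analysis is single-census; CNDD here is a static, size-structured
  signal, not a demographic rate.
* HNDD truth with a non-zero heterospecific *sapling* coefficient is
  only approximate in the generator (saplings are generated in one
  pass); it is exact for the default 0 and for the adult coefficient.
* The spatial stage treats plots independently; no replicated-pattern
  pooling or cross-type statistics.
* Reading the real archipelago deposit is supported through the column
  mapping adapter, but its numbers are not bundled or asserted here.
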