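# forestcndd

Quadrat-based estimation of **conspecific negative density dependence
(CNDD)** from single-census forest stem maps, for forest ecologists
working with stem-mapped plot networks (one row per tree: plot, species,
coordinates, girth).

The Janzen–Connell hypothesis holds that enemies accumulating near
conspecific adults suppress conspecific recruitment, maintaining
diversity. From a static census this leaves a measurable trace: quadrats
rich in conspecific adults hold fewer conspecific saplings than adult
density alone predicts. For each species, after splitting stems into
adults and saplings (adaptive DBH threshold 15 → 10 → 5 cm at a 20%
adult rule) and binning into 10 m and 20 m quadrats, the package fits
the Ricker recruitment model with negative-binomial error by maximum
likelihood:

    mu_i = A_i * exp(r + CNDD * A_i + HNDD_adult * a_i + HNDD_sap * s_i)
    S_i ~ NegBin(mu_i, gamma),   Var = mu + mu^2 / gamma

where `S_i`/`A_i` are focal saplings/adults and `a_i`/`s_i`
heterospecific adults/saplings in quadrat `i`. More negative CNDD =
stronger density dependence. Species-level estimates (filtered by
quadrat occupancy ≥ 10 and CNDD SE ≤ 4) are averaged per plot and
related to diversity (S, Shannon H, Pielou evenness) and environmental
gradients (altitude, temperature, precipitation, ln-transformed snow
depth) via Spearman correlations and Poisson GLMs with
likelihood-ratio interaction tests. An inhomogeneous
pair-correlation-function stage (Gaussian 30 m intensity surface, Ripley
isotropic edge correction, DCLF test against 199 null simulations)
classifies each species' spatial pattern and summarizes per-plot
aggregation.

A synthetic multi-plot generator with known species-level truth
(`generate_multiplot_dataset()`) backs the whole pipeline with
parameter-recovery tests — no external data needed.

## Worked example

Simulate the default 32-plot archipelago (true plot-mean CNDD linear in
altitude, richness linked to CNDD strength) and run everything but the
spatial stage:

```r
library(forestcndd)
cfg <- simulation_config(seed = 42)
res <- run_pipeline(pipeline_config(simulation = cfg,
                                    spatial = FALSE, seed = 42))

co <- res$correlations
co[co$subset == "all" & co$var1 == "cndd_strength" &
     co$var2 %in% c("altitude", "S") & co$scale == 10, ]
#>           var1     var2  n    rho        p linear_r2 star
#>  cndd_strength altitude 32 -0.831 3.80e-09     0.688    *
#>  cndd_strength        S 32  0.715 4.19e-06     0.417    *

g <- res$glm_tables[["altitude_10"]]
round(g$pseudo_r2, 3)
#>         env    additive interaction
#>       0.817       0.823       0.889
g$lr_test
#> chisq = 24.48, df = 1, p = 7.51e-07
```

Read: CNDD strength (the negative of the mean Ricker coefficient, so
higher = stronger density dependence) falls with altitude
(Spearman ρ = −0.83, P ≤ 0.05) and rises with species number
(ρ = 0.72); adding the CNDD × altitude interaction to the Poisson GLM of
species number raises the deviance pseudo-R² from 0.823 to 0.889 and is
strongly supported by the likelihood-ratio test — the effect of CNDD on
richness changes along the gradient. Against the generator truth, the
recovered plot means correlate at 0.83 here.

Real data go through the same path: `read_stem_table()` /
`read_plot_metadata()` accept CSV/TSV with a YAML column mapping for
external deposits (see `inst/extdata/example_*`), and
`pipeline_config(stems = ..., plots = ...)` replaces the simulation.
A thin CLI (`exec/forestcndd`) exposes `simulate`, `run-all` and
`calibrate` subcommands.

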