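# autoflux

Kinetic modelling and statistical analysis of autophagic flux assays on
vesicle count data.

## The problem

Autophagy is routinely monitored by counting fluorescent Atg8/LGG-1
punctae: autophagosomes (APs, mCherry+GFP in the tandem reporter) and
autolysosomes (ALs, mCherry-only, because GFP is quenched at lysosomal
pH). But a steady-state pool size is a ratio of rates, not a rate: more
vesicles can mean more autophagy or a downstream block. `autoflux` makes
the kinetic reasoning behind this caveat executable for researchers who
quantify autophagy with tandem reporters and Bafilomycin A (BafA) flux
assays — in *C. elegans* ageing studies and beyond.

The core model is the three-step chain IM → AP → AL → degradation:

    dAP/dt = J − β·AP        dAL/dt = β·AP − γ·AL

with influx *J* (vesicles/h), conversion rate constant β (1/h) and
degradation rate constant γ (1/h). At steady state

    [AP] = J/β,   [AL] = J/γ,   FLUX = J = [AP]·β = [AL]·γ,

so the pool ratio [AP]/[AL] = γ/β, and for a treatment that leaves *J*
unchanged, the fold-change of each rate constant is *inverse* to the
fold-change of its pool: β_BafA/β_control = [AP]_control/[AP]_BafA.

On top of this the package provides:

* **Flux-assay inference and classification** — per-vesicle Poisson
  rate-ratio tests on paired control/BafA counts, inferred (f_β, f_γ)
  fold-changes, and the decision logic *no change in both pools ⇒
  blocked; change in either ⇒ active* (with complete/partial/other
  inhibition patterns).
* **Non-identifiability made concrete** — scenario tables showing that
  fixed pools are consistent with any flux, and flat profile likelihoods
  on steady-state-only data; plus maximum-likelihood time-course fitting
  (`fit_timecourse()`, with broom-style `tidy()`/`glance()`) showing that
  relaxation data *do* identify (J, β, γ).
* **Poisson-regression count statistics** — two-group rate ratios and
  day-versus-Day-1 age trends via `stats::glm`.
* **A synthetic puncta-count generator** emulating a multi-tissue,
  multi-genotype ageing design (days 1–10, ≥30 animals per cell, paired
  BafA arms, colocalization draws), so every stage is testable without
  experimental data.
* **A reproducible pipeline** (`run_flux_assay_pipeline()`,
  `run_identifiability_demo()`) writing CSV bundles with a manifest, and
  a thin CLI wrapper in `inst/scripts/run_pipeline.R`.

## Worked example

```r
library(autoflux)

p <- kinetic_params(influx = 12, beta = 4, gamma = 2)
steady_state_pools(p)
#> <pool_state>  AP = 3, AL = 6
pool_ratio(p)   # gamma/beta: fewer APs than ALs <=> gamma < beta
#> [1] 0.5

# a synthetic paired control/BafA experiment, then the full assay
cfg <- generator_config(n_animals_per_cell = 30)
assay <- generate_flux_assay(cfg, genotype = "WT", tissue = "intestine",
                             day = 1, seed = 42)
flux_assay(assay, alpha = 0.01)
#> # A tibble: 1 × 15
#>   genotype tissue      day ap_rate_ratio  ap_p_value al_rate_ratio al_p_value
#>   <chr>    <chr>     <dbl>         <dbl>       <dbl>         <dbl>      <dbl>
#> 1 WT       intestine     1          2.08 0.000000158          2.05   1.51e-15
#> # ap_direction "increase", al_direction "increase", f_beta 0.481,
#> # f_gamma 0.488, status "active", inhibition_pattern "partial", n 30/30
```

Both pools roughly doubled under BafA, so both rate constants roughly
halved (f_β ≈ f_γ ≈ 0.5), and the cell classifies as *active* autophagy
with a *partial*-inhibition pattern.

Why steady-state pools alone cannot measure flux — three parameter sets,
one observation:

```r
scenario_table(pool_state(3, 6), c(12, 24, 6))
#> # A tibble: 3 × 5
#>   assumed_flux  beta gamma    ap    al
#> 1           12     4     2     3     6
#> 2           24     8     4     3     6
#> 3            6     2     1     3     6
```

Relaxation time courses, in contrast, identify all three parameters:

```r
rec <- simulate_relaxation_counts(p, n_animals = 30,
                                  times = c(0.25, 0.5, 1, 2, 4, 8), seed = 42)
fit <- fit_timecourse(rec, init_guess = kinetic_params(5, 1, 1))
tidy(fit)
#> # A tibble: 3 × 3
#>   term   estimate std.error
#> 1 influx    13.1      0.941
#> 2 beta       4.33     0.352
#> 3 gamma     2.39      0.227
```

The truth (12, 4, 2) is recovered within about one standard error from a
single simulated experiment.

See `vignette("flux-kinetics")` (source in `vignettes/`) for the model,
its assumptions, the generator's scope and the numerical choices.

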