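---
title: "Kinetics and statistics of autophagic flux assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics and statistics of autophagic flux assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoflux)
library(dplyr)
```

## The model

Autophagy is a conveyor: an isolation membrane (IM) matures into an
autophagosome (AP), the AP fuses with a lysosome to form an autolysosome
(AL), and the AL degrades its cargo. `autoflux` models this as a linear
chain with first-order steps,

$$\frac{dAP}{dt} = J - \beta\,AP, \qquad
  \frac{dAL}{dt} = \beta\,AP - \gamma\,AL,$$

where $J$ (vesicles/h) is the influx of newly formed APs, $\beta$ (1/h) the
AP$\to$AL conversion rate constant, and $\gamma$ (1/h) the AL degradation
rate constant. The IM pool and its maturation rate constant are not
separately identifiable from vesicle counts — only their product ever
appears — so they are lumped into the single influx parameter $J$. The
lysosome pool is not modelled: lysosomes are not counted by the tandem
reporter and enter no balance equation. Amphisomes are not distinguished
from ALs, matching what the red-only reporter channel can resolve.

At steady state the pools are $[AP] = J/\beta$ and $[AL] = J/\gamma$, and
the flux through every step is equal:

$$\mathrm{FLUX} = J = [AP]\,\beta = [AL]\,\gamma .$$

Two corollaries drive everything else in the package:

* **Pool ratio.** $[AP]/[AL] = \gamma/\beta$ exactly. Observing more ALs
  than APs — the typical situation in adult *C. elegans* tissues — implies
  $\gamma < \beta$: AL turnover is the slow, rate-limiting step.
* **Fold-change inversion.** If a treatment leaves $J$ unchanged and both
  conditions are observed at steady state, then
  $\beta_{treated}/\beta_{control} = [AP]_{control}/[AP]_{treated}$ (and
  likewise for $\gamma$ with ALs). A threefold AP increase and twofold AL
  increase under Bafilomycin A therefore imply exactly threefold and
  twofold decreases of $\beta$ and $\gamma$:

```{r}
infer_rate_fold_changes(control = pool_state(1, 1), treated = pool_state(3, 2))
```

Time units are hours throughout, because the flux assay this package
models reads out two hours after BafA injection and rate constants are most
naturally quoted on that scale.

## The BafA flux assay and its classifier

Bafilomycin A blocks lysosomal acidification, which in the model reduces
both $\beta$ (fusion/maturation) and $\gamma$ (degradation)
multiplicatively. The assay logic is a pure function of two directional
calls: if neither the AP nor the AL pool changes after BafA, autophagy is
blocked; a change in either pool indicates active flux. Active responses
are sub-labelled: AP up with AL down is the signature of complete
inhibition of acidification (GFP is no longer quenched, former ALs score
as APs); AP up together with AL up is consistent with partial inhibition
(hydrolase efficiency drops, ALs accumulate); everything else is `"other"`.
`classify_flux()` is total over the nine direction combinations and the
truth table is asserted in the tests.

"No change" is operationalized as a two-group Poisson rate-ratio test with
a default significance threshold of $\alpha = 0.01$ — the weakest
significance tier the assay's conventions report — and is configurable in
every user-facing function. A blocked call requires *both* tests to be
non-significant, so under a true block the expected blocked-call rate is
$(1-\alpha)^2 \approx 1 - 2\alpha$, slightly below $1 - \alpha$; the tests
bracket it accordingly.

The 2-hour equilibration assumption is checkable rather than assumed:
`equilibration_fraction()` reports how far each pool has relaxed towards
its post-treatment steady state at the readout time, and flags regimes
(small $\beta f_\beta$ or $\gamma f_\gamma$) where the assay would be read
mid-transient. Steady-state conditions can plausibly differ between
genotypes, tissues and ages; the diagnostic makes that concern concrete.

## Why steady-state pools cannot measure flux

For any assumed flux $J$ and observed pools, $\beta = J/[AP]$ and
$\gamma = J/[AL]$ reproduce the pools exactly. The canonical demonstration
fixes the pools at $(3, 6)$ and tabulates unchanged ($J = 12$), doubled
($J = 24$) and halved ($J = 6$) flux:

```{r}
scenario_table(pool_state(3, 6), c(12, 24, 6))
```

Three different parameter triples, one observation. The likelihood face of
the same fact: on steady-state-only count data the profile log-likelihood
over $J$ (maximizing over $\beta, \gamma$ at each $J$) is exactly flat,
because any $J$ is matched by co-scaling the rate constants. The package
computes this profile by honest numerical optimization and the tests
assert flatness to within optimizer error.

What *does* determine flux is dynamics. `fit_timecourse()` fits
$(J, \beta, \gamma)$ by maximum likelihood to counts observed during a
relaxation (for example from a vesicle-free initial state, or a washout),
with a Poisson observation model around the deterministic closed-form
trajectory — counts are small integers, so a Gaussian least-squares model
would mis-weight them (least squares is retained as a cross-check via
`method = "ls"`). Optimization runs on the log-parameter scale
(positivity for free) with Nelder–Mead from the supplied guess plus
jittered restarts; the best objective wins and ties within $10^{-8}$ go to
the smallest parameter norm. Standard errors come from the inverse of the
observed information, delta-mapped to the natural scale; a nearly singular
information matrix (the steady-state-only case) produces an
ill-conditioning warning, never a silent answer.

## The synthetic-data generator

No public dataset of per-animal puncta counts exists for this design, so
the generator is the package's testbed. It emulates the study layout the
statistics are meant for: genotypes WT, *daf-2* and *glp-1* (plus *cst-1*
as a genetically blocked control and an `atg-mutant` slot), tissues
intestine, body-wall muscle, pharynx and nerve-ring neurons (plus Day-1
hypodermal seam cells — seam cells fuse shortly after Day 1 and are not
countable later), adult days 1, 3, 5, 7 and 10 with Day 7 dropped for
neurons, 30 animals per design cell, and paired control/BafA arms.

Counts are independent Poisson draws around per-cell means. The default
mean trajectories rise with age in all wild-type tissues (muscle most
steeply, roughly 15-fold), keep ALs more abundant than APs, plateau ALs
after early adulthood, and let neuronal ALs decline; long-lived mutants
start from elevated AP pools. These shapes are configuration data — inputs
that give the tests realistic scales — not assertions about any real
measurement. Treated arms are *derived*, not configured: per-cell rate
constants are backed out of the control means under a nominal flux
(default 12; the treated pools do not depend on this choice at steady
state), the configured perturbation is applied, and the treated means are
the new steady-state pools. BafA defaults to $(f_\beta, f_\gamma) =
(1/3, 1/2)$, the worked fold-change example run backwards.

Two deliberate wrinkles:

* **rab-7 RNAi.** A fusion block ($\beta \to 0.2\beta$, $\gamma$
  unchanged) leaves the *steady-state* AL pool unchanged ($[AL] = J/\gamma$)
  — the linear chain must pass the same flux through once it re-equilibrates.
  The observed AP-up/AL-down pattern of a fusion block is the transient:
  AL production collapses before the growing AP pool restores it. The
  generator therefore takes an `observe_at` time; `Inf` (default) gives
  steady-state arms, while a finite time (e.g. 2 h) samples the closed-form
  transient and reproduces the AP-up/AL-down pattern. This is a real
  limitation of steady-state reasoning, surfaced rather than papered over.
* **Overdispersion.** Real animal-to-animal variability likely exceeds
  Poisson. A negative-binomial `dispersion` knob exists (off by default,
  matching the Poisson-regression analysis model) and the tests document
  that the Poisson Wald test becomes anti-conservative under
  negative-binomial truth.

Colocalization of mCherry-positive punctae with GFP, LysoTracker or
neither is a multinomial draw with default fractions $(0.10, 0.75, 0.15)$,
the validation numbers for intestinal Day-1 counts of the tandem reporter.

What passing tests on these synthetics do **not** show: correctness of the
mean trajectories for any real tissue, robustness to non-Poisson noise
(only the calibrated failure is documented), or anything about imaging,
injection variability or counting error — counts enter the package as
data.

## Statistical engine

All pool comparisons go through one engine: a Poisson GLM with log link
and a single group indicator (`stats::glm`), Wald test by default,
likelihood-ratio test behind a flag. The GLM point estimate equals the
closed-form two-group MLE $\bar{y}_b/\bar{y}_a$ (asserted to $10^{-10}$;
the IRLS tolerance is tightened accordingly). Age trends are day-versus-
Day-1 contrasts of the same engine. No multiple-testing correction is
applied by default — comparisons are reported per-contrast with tiered
thresholds, and a correction can be layered on by the caller. All-zero
groups yield a flagged undefined ratio rather than an exception; an
optional 0.5 continuity adjustment exists but is off by default because
silent pseudocounts distort small-count data.

## Numerical choices

* Steady-state residual tolerances: $10^{-9}$ (relative) for analytic
  consistency checks, $10^{-4}$ for declaring an integrated trajectory at
  steady state.
* The closed form handles the repeated-eigenvalue case $\beta = \gamma$
  explicitly via its $t\,e^{-\beta t}$ limit.
* `deSolve::lsoda` with `rtol = atol = 10^{-10}` backs the numerical
  route; closed-form and integrated trajectories agree below $10^{-6}$
  absolutely on a 0–48 h grid across 1000 random parameter sets.
* Likelihood means are floored at $10^{-12}$ so zero-mean/zero-count cells
  contribute correctly without `log(0)`.

## Problem sizes used by the checks

The heavier simulation checks use: 200 replicates of 30 animals at six
relaxation time points (0.25, 0.5, 1, 2, 4, 8 h — spanning the AP
timescale $1/\beta = 0.25$ h and the AL timescale $1/\gamma = 0.5$ h of
the reference truth $J = 12$, $\beta = 4$, $\gamma = 2$) for parameter
recovery; 2000 null replicates for type-I calibration; 400 replicates for
the blocked-call rate; $10^6$ punctae for colocalization convergence.
These sizes give Monte-Carlo error comfortably below the margins being
tested.

## Known limitations

The chain is linear and memoryless: no saturation of lysosomal capacity,
no feedback from degradation products onto induction, no vesicle size or
cargo heterogeneity. Influx $J$ is assumed treatment-invariant when
fold-changes are inferred; a treatment that alters AP formation would be
mis-attributed to $\beta$. Observation units differ between tissues (a
cell, a bulb, a fixed-area patch) and are treated as exchangeable counting
windows without area normalization. The classifier inherits the power of
its underlying tests: with few animals, truly active cells can classify as
blocked; the blocked call is a statement about evidence, not biology.
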