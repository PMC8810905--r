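---
title: "Fitting prey-depletion functional responses with rogersfr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting prey-depletion functional responses with rogersfr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rogersfr)
```

## The model

A functional response describes how a consumer's per-capita feeding rate
changes with resource density. In a Type II (hyperbolic) response,
consumption rises with prey density and saturates because each captured
prey costs a handling time `h` during which the predator cannot search.
When trials run long enough that eaten prey measurably deplete the arena
and are not replaced, the classic Holling disc equation overestimates
consumption; the appropriate depletion-corrected model is Rogers' random
predator equation, the implicit relation

$$N_e = N_0\left(1 - e^{a (N_e h - T)}\right),$$

where $N_e$ is the number of prey eaten, $N_0$ the initial prey density,
$a$ the attack rate (search efficiency), $h$ the handling time per prey
and $T$ the trial duration. The equation defines $N_e$ only implicitly;
its unique root in $[0, N_0]$ has a closed form on the principal branch
of the Lambert W function:

$$N_e = N_0 - \frac{W_0\!\left(a h N_0\, e^{-a (T - h N_0)}\right)}{a h}.$$

`lambert_w0()` implements $W_0$ with a Halley iteration started from a
branch-point series (near $x = -1/e$) or a log-based asymptote (large
$x$), converging to the defining identity within 1e-12 relative error.
`predict_consumed()` wraps the closed form, with three numerical
safeguards:

* the degenerate limits $a = 0$ (no attacks, $N_e = 0$) and $h = 0$
  (pure exponential depletion, $N_e = N_0(1 - e^{-aT})$) are returned
  analytically rather than pushed through a form that divides by $a h$;
* for strongly saturated trials the Lambert argument overflows
  `exp()`, so it is evaluated in log space ($W_0(e^y)$ solved via
  Newton on $w + \log w = y$);
* the argument is mathematically positive here, but is clamped at
  $-1/e + 10^{-15}$ against floating-point undershoot.

### Units

Time is trial-normalised: one unit is one trial period (a 4-hour trial
in the motivating experiment). `h` is therefore in trial periods per
prey and the derived maximum feeding rate $1/h$ is "prey per trial
period" — e.g. $h = 0.063$ gives $1/h = 15.873$ prey per 4 h. This
convention is the only one consistent with reporting $1/h$ per trial
period, and it makes $a$ dimensionally a per-trial-period search rate.

## Classifying the response type

Following standard practice, the shape of the response is diagnosed
before fitting: `classify_fr_type()` regresses the grouped binomial
counts (eaten, surviving) on initial density with a logit link. A
significantly negative linear ("first-order") coefficient indicates
Type II (proportion consumed declines monotonically with density); a
significantly positive first-order coefficient, followed in a quadratic
model by a significantly negative second-order coefficient, indicates
Type III. The two models are fitted *sequentially* — the quadratic model
only when the linear term is significantly positive. Fitting them
jointly is an equally defensible convention; the sequential form was
chosen because the sign rule itself is sequential, and the choice is
documented rather than silent. The default `alpha = 0.05` is the
conventional level; it is a function argument (and CLI flag), not a
constant.

Degenerate inputs (a single density, zero consumption everywhere,
complete consumption everywhere) and complete separation are reported
as errors rather than returned as unstable coefficients.

## Maximum-likelihood fitting

`fit_rogers()` estimates $(a, h)$ by maximising a grouped binomial
likelihood: each trial's eaten count is
$\mathrm{Binomial}(N_0,\; N_e(a, h, N_0, T) / N_0)$. A binomial
objective was chosen over least squares because eaten counts at low
densities are small integers (0 or 1 at $N_0 = 1$), where Gaussian
assumptions are worst. The optimiser works on $(\log a, \log h)$,
which enforces positivity without constraints, and runs Nelder-Mead
from a fixed 3 × 3 grid of data-driven starts: $h_0$ from the
high-density consumption plateau (max mean eaten ≈ $T/h$) and $a_0$
from the proportion consumed at the lowest density
($\approx 1 - e^{-aT}$), each scaled by {0.3, 1, 3}. The grid is
deterministic, so refitting the same data is bit-identical.

Standard errors come from the inverse observed information on the log
scale, mapped to the natural scale by the delta method; p-values are
Wald tests ($z = \hat\theta / \mathrm{SE}$) and are approximate —
for small designs (18 trials) they should be read as rough evidence
strength, which is also why the bootstrap is the primary uncertainty
summary.

### Weak identifiability of the attack rate

At the reference design (six densities 1–32, three replicates each)
the attack rate is well identified only when it is moderate. When the
true $a$ is large (roughly $a \gtrsim 15$ per trial period), prey at
low densities are virtually always fully consumed, and the likelihood
becomes monotone in $a$ above some value: any sufficiently large attack
rate explains the data equally well, the MLE lies at the boundary
$a \to \infty$, and the observed information is singular (the fit then
carries `NA` standard errors with a warning). This is a property of the
design, not of the optimiser: saturated trials bound $a$ from below but
not above. Handling time remains well identified throughout, because
high-density trials pin down the consumption plateau. Comparisons
between groups with very large fitted attack rates should therefore
lean on $h$, $1/h$ and the bootstrap bands rather than on point
estimates of $a$.

## Bootstrap uncertainty

`bootstrap_fr()` resamples trials (rows) with replacement to the
original sample size, refits each resample (single-start, from the
original optimum), and returns 95% percentile intervals for $a$ and $h$
plus per-density 2.5%/97.5% quantiles of the predicted consumption
curve — the confidence "cloud" conventionally drawn around a
functional-response curve. Choices worth knowing:

* **Unstratified** row resampling is the default, matching common
  practice for this method family; stratified-by-density resampling is
  available (`stratified = TRUE`).
* **Percentile** intervals are the default; bias-corrected and
  accelerated intervals (`bca = TRUE`) use a jackknife for the
  acceleration constant.
* Resamples lacking two distinct densities or any consumption are
  unidentifiable and are redrawn (counted in `n_redrawn`); replicates
  whose refit fails are discarded (counted in `n_failed`), and more
  than 20% failures is an error, signalling data too unstable to
  summarise.
* The band is per-density quantiles of predicted curves, not an
  envelope of whole curves; with 2000 replicates the two differ little,
  and the per-density form is the documented default.
* Resampling operates on a canonically sorted copy of the trials, so a
  seed-fixed summary is invariant to input row order.

The default `n_boot = 2000` follows the convention for this analysis;
examples and tests use smaller counts purely to run quickly.

## The simulator

`simulate_trials()` generates feeding-trial datasets with the
statistical structure the analysis assumes, so the whole pipeline is
testable without any field data. `trout_fry_design()` is the preset
used throughout: three predator groups (diploid rainbow trout, diploid
brown trout, triploid brown trout fry) crossed with two prey-novelty
treatments, densities {1, 2, 4, 8, 16, 32} with 3 replicates per
density per group (108 predator trials), 4-h trials (1 time unit), a
predator-free control arm (3 per density, 18 controls), and true
$(a, h)$ per group equal to the reference fitted estimates (e.g. brown
diploid / novel: $a = 4.72$, $h = 0.063$).

Two mechanisms are available:

* **binomial** (default): eaten ~ $\mathrm{Binomial}(N_0, N_e/N_0)$
  around the Rogers expectation. This matches the fitting likelihood
  exactly, so parameter-recovery tests are clean tests of the
  estimator.
* **event_driven**: a continuous-time search/handle process (capture
  rate $a \times$ remaining prey while searching; handling blocks of
  length $h$), mechanistically closer to live predation and used to
  probe robustness to mechanism misspecification.

Controls have zero background mortality by default, emulating arenas
where control prey survival is 100% and deaths in predator trials are
attributable to predation; a `background_mortality` rate exists for
robustness tests. Prey are discrete and consumption is whole-prey.

What the simulator does *not* emulate: among-individual variation in
predator behaviour (each group has one fixed $(a, h)$), satiation or
learning across the trial, within-individual reuse across densities
(all trials are independent), and non-binomial overdispersion. Passing
tests on simulated data therefore demonstrate the estimator and
pipeline are correct under the stated model, not that real trials meet
those assumptions.

## The pipeline

`run_fr_pipeline()` chains validation, control checks, type
classification, fitting and bootstrap per (fish type, novelty) group
and emits a report table (TSV + JSON) plus tidy bootstrap bands (CSV).
Per-group bootstrap seeds are derived from the run seed and the group
*labels* (not positions), so adding or removing a group never changes
another group's numbers, and the whole run is byte-identical under a
fixed seed. Row-level input violations are reported with row numbers;
group-level failures carry the group name.

## Worked example

```{r example, eval = FALSE}
trials <- simulate_trials(trout_fry_design(seed = 1))
check_controls(trials)
report <- run_fr_pipeline(trials, n_boot = 500, seed = 1)
report$table[, c("fish_type", "novelty", "type_label", "first_order",
                 "handling_time", "max_feeding_rate")]
```

## Problem sizes used in the test suite

The statistical property tests simulate at the reference design
(6 densities × 3 replicates per group). Parameter recovery uses 200
simulated experiments per parameter row; type classification uses 200
experiments at 20 replicates/density plus 20 full-design runs;
bootstrap coverage uses 100 experiments at 500 bootstrap replicates;
the determinism check runs the full pipeline twice at 500 replicates.
These sizes are the package's chosen compromise between Monte Carlo
error and suite runtime.

## Known limitations

* The attack rate is unbounded above on saturated designs (see
  "Weak identifiability"); reports can legitimately contain very large
  $a$ with `NA` standard errors.
* Wald p-values at $n = 18$ are approximate; no profile-likelihood
  intervals are provided.
* Only the Type II (Rogers) model is fitted; Type I / Type III closed
  forms, generalised (flexible-exponent) responses and multi-predator
  interference are out of scope.
* The type test and the fit are not unified in one information
  criterion; the package follows the two-stage convention (classify,
  then fit).
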