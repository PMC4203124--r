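---
title: "Modelling and gene-based prediction of wheat heading date"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and gene-based prediction of wheat heading date}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headcast)
```

## The phenology model

`headcast` simulates wheat development from sowing to heading on a daily
time step. The model is deliberately empirical: development is an
accumulation of thermal time, and vernalization and photoperiod act as
multiplicative brakes on that accumulation. The daily mean temperature
`TM = (Tmin + Tmax)/2` drives three response functions:

* **FT**, a bilinear thermal response rising from 0 at `t_base` (1&nbsp;°C)
  to 1 at `t_opt` (26&nbsp;°C) and falling back to 0 at `t_card_max`
  (37&nbsp;°C). Daily thermal time is `Tt = FT × t_opt`, so a day at the
  optimum contributes 26&nbsp;°C·d.
* **Veff**, a trapezoidal vernalizing efficiency: 0 outside
  [−4,&nbsp;17]&nbsp;°C, 1 on the [3,&nbsp;10]&nbsp;°C plateau, linear on
  the flanks. The running sum of Veff is the vernalizing-day count VDD.
* **FP**, a linear photoperiod response between `p_base` (genotype
  specific) and `p_opt` (20&nbsp;h), computed from the astronomical day
  length with a 6° twilight extension.

Development has two phases. From sowing to emergence, plain thermal time
accumulates to 148&nbsp;°C·d; vernalization and photoperiod do not limit
pre-emergence development. From emergence to heading, the accumulated
quantity is the modified thermal time `PVTt = Tt × FV × FP`, with
`FV = min(1, VDD / v_sat)` continuing to modify development until heading
(there is no intermediate double-ridge phase in this formulation). The
genotype is described by three parameters: `v_sat` (days of vernalization
needed for FV&nbsp;=&nbsp;1), `p_base` (hours; photoperiod threshold
below which development stops), and `tt_emhe` (°C·d; the
emergence-to-heading duration, an earliness-per-se proxy, 500 by
default).

### Numerical conventions

Several small decisions are needed to make the day-step model exact and
reproducible; the package settles them as follows.

* **Stage-day convention.** A stage is assigned to the first day on which
  its accumulator *meets or exceeds* the phase duration. A strict
  inequality would never trigger on exact hits.
* **Accumulator reset.** The phase accumulator resets at emergence and
  surplus beyond the threshold is discarded. Carrying the surplus over
  would shift heading by at most a day at optimal temperatures and the
  simpler convention makes the phase arithmetic transparent (a constant
  26&nbsp;°C day with no other limitation gives emergence after
  ⌈148/26⌉ = 6 days and heading ⌈500/26⌉ = 20 days later).
* **VDD origin.** Vernalizing days accumulate from the day after sowing.
  Germination, the biologically correct origin, is not modelled; sowing
  is its closest observable proxy.
* **Fully spring genotypes.** `v_sat = 0` with `v_base = 0` makes FV a
  0/0; the package defines FV&nbsp;=&nbsp;1 in that case, the limiting
  behaviour of a genotype with no vernalization requirement.
* **Day length.** The daylength model uses the Forsythe et al. (1995)
  revolution-angle declination (accurate to about 0.2°) and a
  sun-angle-parameterized hour-angle formula, so the 6° convention is a
  default rather than a hard-wired constant. Twilight day lengths from
  different astronomical approximations differ by a few minutes; the test
  suite pins the implementation to an independent minute-stepped solar
  integration within 0.1 h.
* **Weather gaps are errors.** Interpolating missing days silently would
  bias thermal-time sums; the readers refuse gapped records and name the
  offending date.

## Brute-force calibration

For each genotype the package evaluates *every* vector of the parameter
grid — `p_base` 0–10 h in 0.1 h steps, `v_sat` 0–130 d in 1 d steps and,
in the 3p strategy, `tt_emhe` 400–800 °C·d in 10 °C·d steps — against the
heading dates observed in the genotype's environments, minimizing the
root mean square error of prediction (RMSEP, days). Because the simulated
heading date depends only on the environment and the parameter vector,
the per-environment grid predictions are computed once and shared across
genotypes; a full 2p calibration over several environments takes seconds.
The grid evaluation is bit-identical to simulating each vector
separately, which the tests verify on a small grid.

* **Not-reached predictions.** When a vector predicts that heading is not
  reached before the weather record ends but the genotype did head, the
  prediction is scored as the day after the record ends. Any finite
  monotone penalty preserves the ranking of realistic vectors; this one
  keeps the objective in calendar units.
* **Ties.** All vectors within 10⁻⁹ days of the smallest RMSEP count as
  minimizing. The representative vector is the tie member closest (in
  grid-step-scaled Euclidean distance) to the component-wise median of
  the ties, with exact-distance ties broken deterministically (lowest
  `v_sat`, then `p_base`, then `tt_emhe`). The median is applied jointly
  over the tied set rather than per parameter; for the small, compact tie
  sets seen in practice the two readings select the same member, and the
  joint form guarantees the representative is itself a tied vector.
* **Winter genotypes.** A genotype observed in at least one spring-sown
  experiment that headed in none of them is classified winter and
  calibrated on autumn sowings only. Its tied vectors are then filtered:
  any vector predicting heading in a spring experiment earlier than the
  last heading date recorded there plus 10 days contradicts the
  observation and is removed ("earlier than" is strict, so a prediction
  exactly at the cutoff survives); vectors predicting no heading always
  pass. If every vector fails the filter the genotype is reported as
  unfilterable rather than silently kept.
* **Robustness resampling.** Calibration stability is probed by
  re-optimizing on random subsets (one fewer autumn and one fewer spring
  experiment per draw, 10 draws by default, mirroring the usual
  leave-one-environment-out design) and reporting the SD of the selected
  parameters.

## Sensitivity analysis

Per environment, heading date is simulated for a 3p grid and regressed
(ordinary least squares, with intercept) on the three parameters.
Standardized regression coefficients `SRC_i = β_i² V(X_i) / V(Y)` with
`V(Y) = Σ β_i² V(X_i)` attribute the simulated variance to the
parameters and sum to 1 by construction. Vectors that never head are
excluded from the regression — scoring them with a penalty date would
manufacture linear signal — and the excluded fraction is reported.
Because SRC is a variance ratio it is stable under grid thinning; tests
use a 14 × 11 × 5 thinned grid rather than the full 542,471 vectors. The
characteristic seasonal pattern (sensitivity almost entirely to `v_sat`
in spring sowings, to `tt_emhe` and `p_base` in autumn sowings) is
asserted by the test suite on synthetic weather.

## From parameters to markers

The marker half of the pipeline turns calibrated parameters into
predictive allelic models.

1. **Rare-class masking.** Allele classes under 5% frequency per marker
   become missing: their effects cannot be estimated usefully.
2. **Imputation.** Missing calls are filled by iterative random-forest
   classification (each incomplete marker regressed on all others,
   repeated until the change between iterations stops decreasing, at
   most 10 iterations, 100 trees). The forest's out-of-bag
   misclassification rate per marker is its PFC (proportion of falsely
   classified entries); markers with PFC&nbsp;&gt;&nbsp;0.2 are discarded
   as unreliably imputable. The forests come from the `randomForest`
   package; the iteration scheme follows the standard missForest
   procedure.
3. **Association.** Each marker is tested by a partial F-test of trait on
   allele class given population structure. The four ancestral-group
   contributions sum to one, so the design uses an intercept plus three
   of them — the same fit without the singularity. Adjusted p-values come
   from permuting trait values across genotypes (covariates fixed,
   `perm_scheme = trait_shuffle`, 1000 permutations by default), with the
   standard `(1 + #{p_perm ≤ p_obs}) / (B + 1)` estimator, so adjusted
   p-values live in [1/(B+1), 1] and are reproducible from the seed.
4. **LD blocks.** Markers with pairwise `r_LD ≥ 0.8` are collapsed to one
   representative (fewest pre-imputation missing calls, ties by marker
   id). For multi-allelic markers `r_LD` is the maximum absolute
   correlation over allele-indicator pairs — a conservative multi-allelic
   generalization recorded in the output metadata.
5. **Backward elimination.** Starting from all surviving associated
   markers, the whole marker term with the largest partial-F p-value
   above 0.05 is removed, one at a time with refitting, until every term
   is significant. The final model is intercept + per-allele effects
   relative to each marker's reference class. A variant restricted to
   known major-gene markers quantifies how much the minor loci add.

The bundled reference models (11 markers for `v_sat`, 12 for `p_base`)
ship in the same JSON format the fitting code writes, and
`predict_parameter()` refuses missing or unknown alleles rather than
treating them as silent zeros; pipeline-level prediction reports such
genotypes in an exclusions table.

## The synthetic study

All tests run against a seeded generator that emulates the structure of a
multi-environment phenology panel at desk scale: 60 genotypes × 300
markers by default (a tenth of a realistic panel), two temperate sites at
French latitudes (45.8° and 48.7° N), three autumn and two spring
sowings, observation noise of 1.5 days SD (the scale of good optimized
fits on real data), 25% obligate-winter genotypes, and planted additive
effects on `v_sat` (one major winter allele of 100 d plus minors) and
`p_base` (a 3 h major plus a minor) at disjoint markers. Weather is a
latitude-dependent sinusoidal annual cycle with AR(1) noise; winters
sustain vernalizing plateau temperatures.

Two design choices deserve emphasis:

* **Spring sowings sit late (early May).** Model sensitivity to `v_sat`
  is concentrated in spring sowings, but an early-spring sowing in a
  temperate climate vernalizes quickly (April mean temperatures sit on
  the trapezoid's flank near efficiency 0.8), so the VDD trajectory
  crosses the whole spring range of `v_sat` within days and
  day-resolution heading dates cannot separate neighbouring `v_sat`
  values. Sown in early May, post-emergence vernalization is marginal:
  VDD rises slowly and plateaus inside or below the spring `v_sat` range,
  heading shifts by 1–3 days per day of `v_sat`, winter genotypes never
  head before the season ends, and the noiseless calibration becomes
  identifiable. This is a deliberate idealization: it gives the spring
  environment the full discriminating power that real designs only
  approximate.
* **Missing calls are confined to a twentieth of the null markers.**
  Typical panels have missing data at a small fraction of markers
  (single-digit percent rates). The generator does not model linkage
  disequilibrium (out of scope), and an LD-free marker is unimputable in
  principle — its out-of-bag PFC equals its minority-class frequency, and
  the PFC filter would rightly discard it. Injecting missingness into
  effect markers would therefore measure the generator's lack of LD, not
  the pipeline; missingness is restricted to null markers and documented
  as such.

What passing tests do **not** show about real data: the generator has no
LD, no kinship beyond the four-group structure, no genotype × environment
interaction beyond the model's own, and noise that is exactly Gaussian.
Real marker models inherit none of those conveniences, and real
validation errors (several days RMSEP) are correspondingly larger than
the synthetic round trip's.

## Known limitations

* **Winter `v_sat` is only bounded below.** Autumn sowings carry almost
  no `v_sat` information, and a non-heading spring observation is a
  censoring event: it gives a lower bound. The median-of-survivors
  representative therefore sits below the true `v_sat` of strongly
  winter genotypes. Predictions of heading date are almost unaffected
  (the parameter is insensitive exactly where the data are silent), but
  marker-model coefficients for winter alleles are attenuated relative
  to the truth.
* **`p_base` resolution.** An 0.1 h `p_base` step moves autumn heading
  by roughly a third of a day, so day-resolution observations tie
  neighbouring `p_base` values; exact recovery of `p_base` at grid
  resolution is not generally possible and errors of one or two steps
  are expected even without noise.
* **The winter filter induces a `v_sat`–`p_base` correlation.** Vectors
  surviving the spring filter trade high `v_sat` against high `p_base`,
  biasing calibrated `p_base` of winter genotypes upward and letting
  winter-allele markers enter the `p_base` model. The same positive
  correlation between the two calibrated parameters is a recognized
  feature of this two-parameter formulation, not an implementation
  artifact.
* **3p compensation.** With `tt_emhe` free, `p_base` and `tt_emhe`
  compensate (late heading can be bought by either a longer phase or a
  stricter photoperiod threshold), so 3p parameter vectors are less
  identifiable than 2p ones; the 2p strategy is the default throughout.

## Problem sizes in the tests

The suite calibrates full 13,231-vector grids (a few seconds per
environment set), runs SRC on a 770-vector thinned 3p grid, fits marker
models on 60 × 300 panels with 200–1000 permutations, and closes the loop
on a 90-genotype study with 30 held-out genotypes and two held-out
autumn environments. The acceptance script reruns only the deterministic
reference-model computations and finishes in seconds.
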