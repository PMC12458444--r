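---
title: "Models and methods behind invbehave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind invbehave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invbehave)
```

`invbehave` quantifies the behavior of individually tracked flies in 1-D
tubes and tests whether the In(2L)t inversion genotype shifts that
behavior across sexes and temperatures. This vignette explains the
models, the conventions and tunable parameters, the synthetic-data
generator and what it does and does not emulate, and the numerical and
design choices that were genuinely open.

## From positions to traits

The raw datum is one fly's position `x(t)` in mm along a tube of length
`L` (default 65 mm), food end at 0, sampled on a uniform grid `dt`
(default 1 s; trackers differ and the sampling rate is configuration,
not an assumption). Speed is the one-sided difference `|Δx|/dt` aligned
to the later sample, so each speed sample owns exactly one displacement
and summed speed times `dt` equals path length exactly — an identity the
tests rely on.

**Sleep.** Flies are scored on minute bins, the convention of
activity-monitor studies: a minute is *inactive* when its summed
displacement is at most `epsilon_mm` (default 1 mm, roughly the
positional jitter of a standing fly at our defaults). A *sleep bout* is
a maximal run of at least `min_bout_min = 5` consecutive inactive
minutes — the inclusive five-minute criterion that defines sleep in
Drosophila. The sleep trait is bout minutes per hour over the
pre-stimulus period (bouts truncated at the window edge contribute their
in-window minutes). Sub-minute inactivity is invisible to this scoring
by construction; the minute bin is a documented convention, not a claim
about the tracker.

**Baseline speed.** Mean speed over the hour before the first stimulus.
Because speeds are later-aligned, the scored samples lie in
`(t_stim − 3600, t_stim]`, which makes the value exactly path length
over the hour divided by 3600 s. Units are mm/s throughout; the trait is
reported on the same scale as the speed trace it derives from.

**Startle.** Each stimulus wakes the fly; the response is summarized by
*duration* — elapsed time until the 10-s right-aligned rolling mean of
speed first returns to (at or below) the fly's own baseline — and
*magnitude* — mean speed in the post-stimulus minute minus baseline.
The rolling mean (window `smooth_window_s`, default 10 s) exists to stop
a single quiet sample from ending the response spuriously; durations are
right-censored at the next stimulus (or recording end) and censored
values enter the per-fly mean at their cap, since dropping them would
bias durations downward. Per-fly values are means over stimuli.

**Foraging position.** The tube is cut into `n_zones = 8` equal
half-open bins `[iL/8, (i+1)L/8)`, with `x = L` assigned to the last
bin; the traits are the occupancy of the food-adjacent and far bins over
the baseline hour. Post-stimulus position is confounded by startle
locomotion, which is why the baseline window is the default (the full
recording is available by option). Proportions are
arcsine-square-root transformed (`asin(sqrt(p))`) before modeling; the
transform is applied to both the near-food and far-food traits.

## The inference ladder

For each trait the package fits four nested linear mixed models with a
random intercept for experiment block and compares them with
likelihood-ratio tests: null → genotype → genotype + covariate →
genotype × covariate. The covariate is sex (2-level factor) in the
25 °C analysis, or temperature in the females-across-temperatures
analysis. Choices that matter:

* **Maximum likelihood, not REML.** The ladder varies fixed effects, and
  LRTs on fixed effects are only valid under ML; AIC and logLik are
  reported from the same ML fits. This also matches how `anova()` on
  `lme4` fits behaves (it refits with ML).
* **Structural parameter counts.** `npar` is counted from the model
  specification — fixed effects plus one block variance plus one
  residual variance — giving the sequence 3, 5, 6, 8 and LRT df 2, 1, 2.
  It is never read off optimizer internals, so a parameter rendered
  inestimable by the data (a covariate observed at a single level) keeps
  its structural count; the term is dropped from the fitted formula and
  the LRT against the reduced model is exactly χ² = 0, p = 1.
* **Temperature is numeric (°C).** A single slope parameter, which is
  what the df = 1 of the temperature ladder requires; three-point
  temperature designs cannot distinguish linear from monotone-saturating
  responses anyway.
* **Treatment coding with STD reference.** Contrast choice does not
  affect LRTs, only the reported coefficients.
* **Numerics.** LRT statistics in `(-1e-6, 0)` are clamped to 0
  (optimizer noise at the boundary); anything more negative aborts as a
  convergence failure rather than being silently accepted. A constant
  trait puts the residual variance on its boundary; the fit survives and
  the warning is recorded. A single block makes the random intercept
  inestimable and is rejected with guidance.
* **Post-hoc tests.** Gated at α = 0.05 on the genotype and interaction
  LRT rows — the conventional reading of "a significant effect". Within
  each stratum, all three genotype pairs are compared with Welch t-tests
  by default; a pooled-variance option exists because both variants
  appear in published analyses of this design, and no correction for
  multiple testing is applied by default (a deliberate mirror of common
  practice in this literature; adjust `res$posthoc$p` with `p.adjust`
  if desired). Tests run on the same (possibly transformed) scale as
  the mixed models. Two constant groups yield t = 0, p = 1 rather than
  an error.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised and
calibrated without raw tracking data. Its defaults define the study
conditions once: a full factorial of 3 genotypes × 2 sexes × 3
temperatures × 3 blocks at `n_per_cell = 11` (≈ 594 flies per block,
the order of magnitude of the real cohorts), stimuli at 3600 s then
every 1800 s (4 total — a placeholder schedule, since no inter-stimulus
interval is published), recordings of 10800 s.

**Trajectory level.** Sleep/wake alternates as a renewal process with
exponential sojourns (means `mu_sleep_s = 900`, `mu_wake_s = 600` for
the reference cell), sampled through its memoryless per-step transition
probabilities. Exponential bouts are chosen for analytic tractability —
the long-run asleep fraction is `μ_S/(μ_S+μ_W)`, a closed form the tests
check — not realism; real bout distributions are heavier-tailed. Asleep
flies are frozen. Awake flies take steps whose *direction* is the sign
of a mean-reverting increment `κ(p* − x)dt + σ_x√dt·Z` (preferred
position `p*` genotype-dependent: STD 8, HET 12, INV 20 mm — inverted
flies sit farther from food) and whose *magnitude* is the wake bout's
log-normal speed draw times `dt`, reflected into `[0, L]`. Splitting
direction from magnitude makes the derived speed exactly additive in the
startle excursion `A·e^{−t/τ}` (a literal additive position increment
would not be, since `|a+b| ≠ |a|+|b|`), which is what makes the
closed-form magnitude identity `A·τ(1−e^{−60/τ})/60` testable; the
excursion is evaluated at step midpoints (midpoint rule) and keeps the
fly awake until it decays below one step-noise unit. Genotype, sex and
temperature act as multipliers on cell parameters (inverted flies:
shorter sleep bouts, longer startle decay; males: more sleep, stronger
startle; warmth: less sleep, faster movement), and blocks shift the mean
sleep-bout duration additively (`N(0, σ_B²)`, default SD 60 s) — random
intercepts, the only block structure the analysis models. Each fly runs
on its own RNG substream derived from the master seed by a fixed
counter over (design cell, replicate), so enlarging a cohort never
reshuffles existing flies; all randomness is R's default Mersenne
Twister via `set.seed`.

**Phenotype-table level.** For simulation studies where trajectory
realism is irrelevant (type-I error, power, recovery), traits are drawn
directly from the additive model the analysis assumes — intercept +
genotype contrasts + sex effect + temperature slope + interactions +
block intercept + Gaussian residual, clamped to natural ranges. Default
effect directions encode the biology being emulated (INV sleeps ~5 min/h
less, startles ~20 s longer, sits more often far from food; males sleep
more and startle harder; warmth reduces sleep and increases speed);
magnitudes were fixed once at values plausible for this assay and are
not revisited.

**What passing tests do and do not show.** The generator reproduces the
factorial design, additive genotype/sex/temperature structure, block
heterogeneity, renewal sleep, and exponential startle kinetics. It does
not attempt circadian rhythmicity (the assay runs in constant darkness,
but real flies still carry free-running rhythms), heavy-tailed bout
distributions, positional drift of trackers, social interaction, or
far-tube excursions — under the mean-reverting walk the far-food zone is
rarely visited at trajectory level, so far-food effects are exercised
through the phenotype-table generator. Green tests therefore validate
the machinery under the stated generative model, not the biology of any
particular dataset.

## Validation design and problem sizes

The test suite checks each primitive against an independent oracle
(brute-force run-length scanning for bouts, path-length sums for speed,
half-open binning for zones, textbook Welch formulas for post-hoc t),
and the statistical machinery against theory: the mixed-model logLik
must coincide with OLS when the between-block variance is exactly zero
in-sample (blocks constructed identical, which pins the variance
estimate to the boundary — data merely *simulated* with σ_B = 0 leave a
positive estimate about half the time, so that version of the check
would be flaky by construction); the inversion LRT must reject at ≈ 5%
with uniform p-values under a genotype null (500 cohorts of 10
flies/cell); configured effects must be recovered in sign and within
Monte-Carlo error of their magnitude (200 replicates at 20 flies/cell);
and the simulator must match its closed forms over ≥ 100 flies. The
renewal identity is checked on the undisturbed pre-stimulus window
(stimuli force wakefulness, so the stationary identity does not apply
across them) and, for the phenotyped version, in a long-bout regime
(μ_S = 3600 s, μ_W = 2400 s, 4-h window) where minute-binning and the
five-minute threshold are second-order; at the defaults those
discretization losses are first-order (roughly 10–15% of measured
sleep), which is a real property of threshold-based sleep scoring, not
a bug. These problem sizes keep the whole suite under a couple of
minutes while leaving Monte-Carlo error well below the tested margins.

## Known limitations

* Sleep scoring is minute-binned; trackers that define inactivity on
  sub-minute windows will measure systematically more or less sleep.
* The startle-duration cap (next stimulus) right-censors long responses;
  the per-fly mean treats censored values as exact at the cap and so
  understates extreme durations.
* Temperature enters linearly in °C; curvature across 20/25/30 °C loads
  onto the interaction and residual.
* The two post-hoc variants (Welch vs pooled) can disagree near
  α = 0.05; both are exposed because published analyses of this design
  mix them, and no recommendation between them is implied.
* With only three blocks, the block variance is estimated from three
  effective observations; its point estimate is noisy even though the
  fixed-effect LRTs remain calibrated (verified by simulation).
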