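---
title: "Methods: decomposing explicit and implicit learning in visuomotor rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing explicit and implicit learning in visuomotor rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmradapt)
```

## The task and its measures

`vmradapt` analyzes center-out reaching experiments in which cursor feedback
is rotated 45° clockwise relative to the hand and subjects verbally report,
before each reach, which of 63 numbered landmarks (spaced 5.625° on the 7 cm
target ring) they are aiming at. The design has seven blocks
(16/48/24/24/160/40/40 trials): familiarization, three baseline blocks (the
last two with aim reports; anodal tDCS — or sham — starts in the fourth), a
160-trial rotation block, a no-feedback block, and a washout block. Targets
appear at eight locations 45° apart, pseudorandomized so that every 8-trial
epoch contains each target once; epoch means therefore average out
target-specific biases.

From the 100 Hz tablet trajectories the pipeline computes, per trial:

* **hand angle** — the direction of the chord between the points where the
  trajectory first crosses 1 cm and 7 cm of radial distance, expressed with
  the target at 0° and counterclockwise positive (crossings linearly
  interpolated between samples);
* **reaction time** — target onset to the 1 cm crossing; **movement time** —
  1 cm to 7 cm; movements longer than 400 ms (strict inequality) are flagged
  *too slow* but kept in averages by default, with a filter flag exposed,
  since the original handling is not documented.

Per subject, the scalar measures are:

* **baseline bias** — mean hand angle over the final 8 trials of the last
  baseline block; subtracted from everything downstream;
* **rotation hand angle** — bias-corrected mean hand angle over the rotation
  block (trial means; epoch means are identical when all trials are valid
  and are available separately);
* **target error** — rotation hand angle − 45, so 0 is full compensation of
  the rotation and negative values are clockwise undershoot. The published
  tables never write this formula, but it is the only definition consistent
  with the printed signs and with explicit + implicit ≈ 45 + target error;
* **explicit component** — mean reported aim converted to degrees via
  `angle = −n × 5.625`. The sign is forced by two facts: counterclockwise is
  positive, and aiming at number −8 is the strategy that lands the cursor on
  the target under the −45° rotation, i.e. −8 ↦ +45°;
* **implicit component** — hand angle minus aim angle, averaged over
  rotation-block trials that have both valid kinematics *and* a report, so
  that the additivity identity explicit + implicit = rotation hand angle
  holds exactly over that trial set;
* **aftereffect** — mean hand angle over the first 8 no-feedback trials,
  bias-corrected.

Outlier screening follows the published rule: within each group, any subject
whose target error, explicit, or implicit score falls outside the group mean
± 3 SD is excluded. The screen is single-pass (the published exclusion
counts are consistent with one pass), and values exactly on a bound are
kept. Note that with a single extreme subject the largest attainable
standardized deviation is (n−1)/√n, so in groups of ten the bound is
unreachable for a lone outlier unless other scores co-vary; the screen is
applied as stated regardless.

## Group statistics

All tests operate on `(n, mean, sd)` group summaries — the sufficient
statistics — with raw-data overloads that agree to 1e-10:

* one-way ANOVA with partial η² = SSB/(SSB+SSW) and Cohen's
  f = √(η²/(1−η²));
* Tukey–Kramer studentized-range post-hoc tests (base `ptukey`), with
  pairwise Cohen's d and Hedges' g computed from the two groups' pooled SD
  (this, not the MS-within-based d, reproduces the published pairwise
  effect sizes);
* pooled-variance Student t-tests (Welch optional) with
  d = |Δm|/s_pooled and g = d·(1 − 3/(4N−9)); the pooled form and this
  Hedges correction reproduce the published t, d and g exactly, which is
  why they are the defaults;
* a 2×3 CONTEXT × STIM between-subjects factorial with Type-III
  (unweighted-marginal-means) sums of squares computed from cell summaries
  via contrast quadratic forms, SS = (Lm)′(LDL′)⁻¹(Lm) with D = diag(1/n);
  this matches `car::Anova(type = 3)` under sum-to-zero coding and
  reproduces the published main-effect F values. (The published table
  labels the 2-level context main effect "F(2, 52)"; the recomputed value
  matches at df 1, 52, so the df label is treated as typographical and the
  emitted result reports df_effect = 1.);
* JZS default Bayes factors from sufficient statistics: for t-tests the
  Cauchy(0.707) effect-size prior integrated by adaptive quadrature over
  the equivalent inverse-gamma(1/2, r²/2) prior on g; for one-way ANOVAs
  the fixed-effects Cauchy(0.5) prior with the g-conditional closed form
  (1+N_e g)^((N−1−p)/2)/(1+N_e g(1−R²))^((N−1)/2), using the
  balanced-equivalent per-group size N_e = N/J. The balanced form is exact
  for equal groups; for the mildly unbalanced published designs
  (16/15/15, 10/10/9) it reproduces all six published ANOVA Bayes factors
  to within 2%, well inside the reporting precision. Every Bayes factor is
  returned with its quadrature error estimate;
* noncentral-t power analysis: the minimum per-group n such that a
  two-sided pooled t-test reaches the target power, with noncentrality
  d·√(n/2) and df 2n−2, found by exact integer search.

No multiplicity correction is applied to the a-priori t-tests, matching the
published analysis.

## The synthetic cohort generator

No subject-level data are deposited for this paradigm, so the package ships
a generator that produces trial logs in exactly the dialect the analysis
ingests. Each simulated subject is a *two-process learner* — the minimal
structure consistent with the additive explicit + implicit decomposition the
analysis assumes, and declared synthetic scaffolding rather than a model of
any particular dataset:

* aim_t = clamp(explicit_t, ±cap), snapped to the 5.625° report grid on
  report trials after adding report noise (subjects report, and act on,
  integers);
* hand_t = aim_t + implicit_t + N(0, σ_motor);
* with feedback: explicit_{t+1} = explicit_t − η·e_t (e_t = cursor error
  relative to the target), and implicit_{t+1} = A·implicit_t −
  B·(cursor_t − aim_t). The implicit error signal is the aim-to-cursor
  discrepancy, not target error, mirroring the distinction between strategy
  and error-based adaptation; the sign is such that the implicit process
  cancels the discrepancy (the reinforcing sign diverges for A + B > 1 and
  contradicts the fixed point 45·B/(1−A+B) that the stated dynamics
  converge to);
* no feedback: explicit frozen, implicit decays by A; washout: same updates
  with rotation 0;
* after the last report block the aiming ring disappears and subjects are
  instructed to aim straight at the target, so aim_t = 0 thereafter while
  the explicit state stays frozen. This is what makes the simulated
  aftereffect reflect the implicit state alone, as in the real task.

Default parameters were chosen once, by calibration to the published
first-experiment group means (explicit ≈ 29–33°, implicit ≈ 13–15°, target
error a few degrees below zero): horizontal context η = 0.15, B = 0.012;
vertical context η = 0.08, B = 0.022 (harder transformation, less strategy,
more implicit); A = 0.98; σ_motor = 3.5°; σ_report = 1 number unit;
between-subject CV 0.3 on η and B. Stimulation-arm effects are injected
purely through the parameter means (CB: ×1.35 on B in the vertical context,
×1.10 horizontal; dlPFC: ×1.20 on η horizontal, ×1.05 vertical), keeping the
generator orthogonal to the pipeline. Heavy-tailed inter-individual
variability — the few extreme performers per group visible in individual
data — is emulated by a mixture: with probability `outlier_fraction`
(default 0.1) a subject's η and B are drawn with 3× inflated SD.

Trajectories are rendered at 100 Hz as a minimum-jerk radial profile to 8 cm
with a smooth curvature perturbation bounded at 0.5° between the 1 cm and
7 cm reference points. Timing is parameterized so the analyzer's rt and mt
recover the drawn values within one sample period. Reports are treated as
pre-movement only (they are given before moving; nothing is modeled about
mid-movement interaction with online feedback, which the task description
does not address).

What the generator does *not* emulate: online feedback corrections within a
movement, verbal-report latencies, trial-to-trial target-location effects
beyond balance, fatigue or attention drift, and any tDCS physiology. Passing
tests therefore show that the pipeline computes its measures correctly and
that the statistics behave as designed under a realistic additive-learner
cohort — not that the learner is a validated model of human adaptation.

## Numerical choices and degenerate inputs

* Radius crossings use the first crossing with linear interpolation; noise
  re-entry cannot move it backwards. Trajectories that never reach 7 cm
  raise a classed incomplete-trial condition and are flagged, not dropped.
* Angles are wrapped to (−180°, 180°]; the wrap point maps to +180°.
* Epochs with no valid trials are flagged missing; baseline epochs with
  fewer than 8 valid trials degrade to the available trials with a warning.
* Zero pooled variance with unequal means yields an infinite-t sentinel;
  identical group summaries give t = 0, d = 0, Tukey p = 1, F = 0.
* Bayes-factor quadrature uses `integrate` at rel.tol 1e-10 over (0, ∞);
  the returned error estimate is propagated to the caller.
* Schedules, parameter draws and trial noise are pure functions of their
  seeds; the cohort manifest records every derived seed.

## Problem sizes used in the test suite

The suite exercises the full 352-trial design throughout. Replicated
studies use sizes chosen to keep Monte-Carlo error well below the asserted
tolerances on a single CPU: 10,000-replicate null calibration of the
one-way ANOVA at n = 10/group; 200 replicate end-to-end null pipelines
(3 × 8 subjects, commanded-kinematics mode) for the 5% type-I check; 100
replicate two-arm cohorts (25/group) for the implicit-sensitivity sign
check; and a 100-subject sweep of B for parameter recovery
(rank correlation > 0.5). Commanded-kinematics mode (`render = FALSE`)
skips trajectory rendering and feeds the analyzer the commanded hand angle
and drawn rt/mt — exactly what noise-free rendering reproduces to 1e-6°,
as the closure tests verify — so replicate studies measure statistical
behavior rather than re-measuring the geometry thousands of times.

## Known limitations

* The generator's learner is intentionally minimal: no fast/slow implicit
  states, no strategy discovery dynamics, no use-dependent effects.
* The ANOVA Bayes factor treats mildly unbalanced designs through the
  balanced-equivalent group size; for severely unbalanced designs compute
  it from raw data with a dedicated Bayesian package instead.
* The original three-group power calculation that motivated the published
  sample sizes (f = 0.7) depends on unstated software rounding conventions
  and is out of scope; only the noncentral-t two-group calculation is
  implemented.
* Subject-level results of the original study are not reproducible (no
  deposited data); the package reproduces every statistic computable from
  the printed group summaries and provides the simulator for everything
  upstream.
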