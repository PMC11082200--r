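---
title: "Methods: trial-level pattern similarity for episodic counterfactual simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-level pattern similarity for episodic counterfactual simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question and the measurement model

When a person recalls a negative autobiographical memory and then simulates
how the event could have gone better (upward counterfactual) or worse
(downward counterfactual), the multi-voxel activity pattern of the
simulation can either drift away from the pattern of the original memory or
recapitulate it. `cftnps` measures this at the single-trial level with two
indices defined on Fisher-z-transformed Pearson correlations between
multi-voxel patterns within an anatomical parcel:

* **Recall-CFT similarity shift**, per trial:
  `z(r(Recall[4-8s], CFT[4-8s])) - z(r(Recall[4-8s], CFT[0-4s]))`.
  Negative values mean the simulation's pattern diverges from the memory as
  it is elaborated; positive values mean the memory pattern is re-instated.
  Only the middle recall window represents the memory: the late recall
  window abuts the jittered 1-3 s gap and its similarity with the early
  simulation window is inflated by BOLD temporal autocorrelation, while the
  late simulation window (8-12 s) is separated from recall by almost twice
  the interval of the early one and is therefore not comparable.
* **CFT-CFT similarity**, per trial: the mean Fisher-z correlation between a
  simulation's 4-8 s pattern and every other same-condition simulation
  pattern *from a different run*. Same-run pairs are excluded outright:
  within-run autocorrelation and shared estimation error inflate them.
  High values indicate a generalized representation of "better" (or
  "worse") outcomes; low values indicate episode-specific content.

Patterns are t-statistic maps from a single-trial GLM: each focal trial's
recall and simulation epochs are modelled with a finite-impulse-response
basis of three 4-s windows (two TRs each at TR = 2 s), everything else in
the run is nuisance (Least-Squares-Separate): five pooled event categories
(other recalls, other upward simulations, other downward simulations, the
odd/even filler task, button presses) convolved with a double-gamma
response plus temporal derivatives, ten confound series, per-TR
motion-outlier indicators, a discrete-cosine 100-s high-pass basis, and an
intercept. Trials whose focal epoch has three or more of its six TRs
flagged as motion outliers are excluded.

Trial indices are then analysed per parcel with a linear mixed-effects
model: fixed effects are the full factorial of simulation direction
(downward reference) x standardized trait anxiety x standardized per-memory
arousal, with a random intercept per subject, REML estimation, Wald t-tests
on Satterthwaite degrees of freedom (Kenward-Roger optional), simple
anxiety slopes per condition from the fixed-effect covariance, and
Benjamini-Hochberg FDR applied per term across parcels (separately per
index). Before modelling, the raw shift index is residualized on the
jittered recall-to-simulation interval (1/2/3 s) and the previous trial's
condition (upward/downward/none/no-previous), with the grand mean added
back so the model intercept still estimates the mean shift; this two-step
route is equivalent to a one-step model that includes the nuisance factors
(the package's test suite verifies the equivalence to 1e-6 on a balanced
design).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tr_seconds` | 2 | s | acquisition TR; windows are 2 TRs |
| window length | 4 (3 per epoch) | s | FIR resolution over the 12-s epochs |
| `min_voxels` | 100 | voxels | floor below which a pattern correlation is too impoverished |
| `min_overlap` | 0.25 | fraction | parcel must overlap the omnibus F-mask this much; both bounds inclusive |
| motion threshold | 3 of 6 | TRs | epoch-level exclusion rule (FD > 0.5 mm or standardized DVARS > 1.5 flags supplied upstream) |
| `highpass_s` | 100 | s | drift basis cutoff, implemented as DCT columns in the GLM |
| `fdr_q` | 0.05 | — | FDR level per term family |
| `df_method` | satterthwaite | — | fractional denominator df for Wald t |
| correlation clip | 1 - 1e-7 | — | keeps `arctanh` finite at `|r| = 1` |

## What the synthetic generator emulates

`generate_study()` produces complete studies at the conditions the analysis
is built for: per subject, 45 memories split 15/15/15 across
upward/downward/no-simulation conditions over 3 runs; 12-s recall epochs; on
simulation trials a jittered 1-3 s gap then a 12-s simulation epoch; 1.5-s
fixations; odd/even numerical filler blocks (2-4 numbers x 1.5 s); button
presses; AR(1) voxel noise; motion-outlier TRs with signal artifacts and
consistent FD/DVARS flags; an atlas whose parcels are voxel blocks and an
omnibus mask covering a configurable fraction of each parcel; trait-anxiety
scores drawn uniformly on 20-70 (emulating recruitment across the anxiety
spectrum, scores >= 40 conventionally "high"); per-memory arousal ratings
1-7.

Ground-truth dynamics are injected on the Fisher-z scale through latent
pattern mixing. Each trial's recall epoch carries one sustained "memory"
pattern `m`. The simulation epoch mixes `m`, a subject-by-condition
template `g`, and a trial-specific component, with weights chosen so that
in expectation

* `z(r(recall, CFT_early)) = base + jitter_effect * (2 - jitter)`,
* `z(r(recall, CFT_late)) = base + drift + slope * anxiety_z * sign(condition)`,
* within-condition CFT-CFT similarity `= base_cc + slope * anxiety_z * sign(condition)`,

with `sign(upward) = +1`, `sign(downward) = -1`. Anxiety enters
sample-standardized, the same scale the mixed models estimate, so the
implied model coefficients are exactly `drift` (intercept) and `2 * slope`
(upward-vs-downward interaction contrast). Epoch signals are
FIR-consistent boxcars (window amplitudes are recoverable exactly by the
FIR basis); filler and button-press signals are injected already convolved
with the double-gamma response, matching how the design models them. The
early and late simulation patterns share their trial-specific component, so
with zero injected effects they are *identical* and the latent shift is
exactly zero.

What the generator does **not** emulate: anatomical geometry, hemodynamic
convolution of the focal epochs (a flag exists in the design's nuisance
model for convolved data, but the default regime is convolution-free so
that FIR estimation has an exact-recovery reference), physiological noise,
spatial autocorrelation, and behavioural response-time structure. Passing
tests therefore demonstrate the statistical machinery under a known
generative model, not performance on real BOLD data.

## Numerical choices

* Onsets are snapped to the TR grid: FIR windows start at the nearest TR
  boundary at or after the event onset (the 1 s and 3 s jitters misalign
  the simulation onset by half a TR; the interval residualization absorbs
  the induced interval effects).
* The double-gamma response uses the conventional shape (peak 6 s,
  undershoot 16 s, ratio 6, unit dispersions).
* Correlations are clipped at `|r| = 1 - 1e-7` before `arctanh`;
  zero-variance patterns yield undefined correlations and the record is
  dropped and counted, never imputed.
* Voxels with numerically zero residual variance (possible only for exact
  noise-free fits) have no defined t-statistic; the coefficient itself is
  used as the pattern value, with a warning.
* Temporal-derivative nuisance columns are orthogonalized against the
  focal FIR block. This is an attribution choice (the model span, fitted
  values and residuals are unchanged): a derivative column exists to absorb
  timing variation of its own pooled events, and its sharp transients
  otherwise leach window-specific focal signal. On synthetic calibration
  runs this removed a systematic window-asymmetric bias of the shift index
  (visible as a nonzero mean shift under a null configuration). Noise
  regressors are never orthogonalized: artifact variance inside a focal
  window must remain attributable to the artifact columns.
* A trial is also excluded when motion censoring swallows an entire focal
  window (the window amplitude would be unidentifiable).
* Nuisance factor levels with no observations are dropped from the
  residualization design with a message; the sweep records per-parcel model
  failures and continues.

## Design choices that were genuinely open

* **Residualization grouping.** The nuisance regression is fitted once per
  parcel, pooling all subjects' trials: pooling maximizes the counts in the
  12 nuisance cells, and the equivalence property guarantees the
  fixed-effect interpretation either way.
* **FDR family.** Adjustment is applied within one fixed-effect term across
  parcels, separately per index kind — the scheme under which each reported
  P pairs naturally with a P_FDR from its own term's sweep.
* **Condition coding.** Downward is the reference level; a relabelling test
  guards against coding artifacts, and simple slopes are reported per
  condition so the coding never reaches the reader.
* **Interaction scope.** "All associated interactions" is read literally as
  the full three-way factorial (condition x anxiety x arousal); a
  `three_way = FALSE` switch restricts to pairwise terms.
* **Focal trials.** Single-trial models are fitted for simulation trials
  only (recall epochs of those trials are focal alongside the simulation
  epochs); recall-only trials serve as nuisance events, which is sufficient
  for both indices.
* **Motion rule for two-epoch trials.** The 3-of-6 rule is applied per
  focal epoch; a trial is excluded if either epoch crosses the threshold.

## Calibration results and known limitations

The test suite and `scripts/acceptance.R` exercise the full pipeline on
synthetic studies at the default conditions (40 subjects; problem sizes in
the replicate runs are 6 full-size recovery studies and 6 null studies of
12 subjects, chosen to keep the suite within a desk-scale compute budget;
smaller configurations are used for unit tests).

A finding of this calibration work, documented here because it shapes what
the acceptance checks can and cannot show: single-trial FIR window
estimates from a Least-Squares-Separate model with pooled nuisance
categories are not unbiased carriers of latent pattern similarity at this
trial density. Each 2-TR focal indicator shares, by chance alone, an
appreciable fraction of its variance with the ~35 nuisance columns of a
~200-TR run (variance inflation around 1.4), so window estimates pick up a
mixture of the other trials' unmodelled pattern deviations. The effect on
the indices is an approximately multiplicative shrinkage of injected
effects (about 15% on the Recall-CFT shift in the package's calibration
runs — compare `shift_intercept_b` from `scripts/acceptance.R` with the
injected drift of -0.05) plus a small proximity offset at the null (order
+0.004 in Fisher-z units). Consequences, as the package's own null and
recovery replicates show:

* The shift index's *effect* terms (condition, anxiety, arousal and their
  interactions) are correctly calibrated at the null — FDR-positive
  fractions of essentially zero.
* The shift *intercept* inherits the small proximity offset, so its
  null-configuration false-positive rate exceeds the nominal level once
  the standard error shrinks below ~0.004.
* Signs and orderings of injected effects are preserved; the
  anxiety-by-condition moderation signature on CFT-CFT similarity (upward
  slopes above downward slopes) is recovered essentially always.
* Confidence intervals for *absolute* effect sizes undercover the latent
  truth whenever the standard error is smaller than the shrinkage bias —
  exactly the situation at 40 subjects x 1,200 trials. The acceptance
  suite states the strict coverage checks anyway and they fail honestly.
  The same attenuation necessarily affects analyses of real data with
  this design, which is worth remembering when comparing index magnitudes
  across studies with different trial densities.

A second, independent calibration finding concerns the CFT-CFT index
itself: its trial records share cross-run comparison pools (every pair
contributes to both of its members), so records are positively dependent
within a subject's condition. With the conventional participant-level
random intercept — the specification this literature reports, with
trial-level degrees of freedom around 1,000 for interaction terms — the
Wald tests for condition-involving terms are anticonservative at the null
(FDR-positive fractions up to ~0.3 in the package's null replicates).
Adding a nested subject-by-condition random intercept
(`fit_index_lmem(..., random_structure = "subject_by_condition")`)
largely restores calibration. The default remains the conventional
specification for comparability; analysts of this index should prefer the
nested structure.

Other limitations: the generator's uniform anxiety distribution is wider
than a typical recruited sample; arousal carries no injected effect, so its
terms only exercise calibration; and the pipeline holds all runs of a study
in memory (about 150 MB at the default size).
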