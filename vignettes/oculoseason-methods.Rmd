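---
title: "Methods: oculomotor prediction of ONSD and PC-ImPACT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oculomotor prediction of ONSD and PC-ImPACT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oculoseason` implements a longitudinal analysis chain for contact-sport
athletes monitored across a season: eye-tracking tasks yield an oculomotor
feature battery, and linear mixed-effects models predict two complementary
neurophysiological markers from those features — optic nerve sheath
diameter (ONSD, an ultrasound proxy for intracranial pressure) and
PC-ImPACT (a one-dimensional summary of the six ImPACT cognitive
composites). This vignette explains the models, the defaults and why they
were chosen, what the synthetic data generator does and does not emulate,
and the numerical decisions that matter.

## 1. Task schedules

Three 1 kHz tasks are modelled, viewed from 60 cm:

* **Smooth pursuit** — a target moves at constant speed around a circle,
  visible 1.5 s then blanked 0.5 s, for 35 cycles. The circle phase is
  frozen during gaps so the target reappears where it vanished. Circle
  radius and speed are open design parameters; we use an 8° radius and
  120°/s of phase (≈16.8°/s tangential), a standard pursuit speed — slow enough to track, fast enough that pursuit gain is
  measurable against sensor noise and that realistic gain deficits
  produce catch-up saccades.
* **Visually guided saccades** — the target jumps instantaneously among
  10 unique horizontal positions, 78 jumps per trial; peripheral targets
  dwell 1.5 s and the central (0°) target 2 s. The default position set is
  0°, ±2.5°, ±5°, ±7.5°, ±10° and +12.5° (ten unique values). The jump
  sequence is a seeded random walk whose first ten entries are a
  permutation of all positions, so every position occurs.
* **Anti-saccades** — 18 one-second peripheral cues at ±10°, nine per
  side, separated by central fixations of 1, 2, 3 or 4 s drawn uniformly
  under a seed. The correct response is a saccade to the mirror position;
  a saccade toward the cue is an error.

The printed trial totals in the source description ("155 s", "90 s",
"just over 2 min") are not arithmetically consistent with the printed
counts and dwell times; the counts and dwells are treated as primary and
total duration simply emerges (70 s, ≈120.5 s, ≈63 s for typical draws).

## 2. Trace simulation and ground truth

`simulate_trace()` renders a schedule into a gaze recording under a
`subject_params()` parameter set, and logs every injected event — the
oracle that the detector and feature tests are scored against.

* **Saccades** follow the main-sequence law
  `duration = intercept + slope × amplitude` (defaults 30 ms + 2.5 ms/°)
  with a unimodal velocity profile
  `v(t) ∝ (½(1 − cos 2πt/T))^s`. The shape `s` fixes the Q-ratio
  (peak velocity × duration / amplitude) at
  `√π Γ(s+1)/Γ(s+½)` — exactly 1 for the rectangular profile (s = 0),
  2 at s = 1, and ≈1.61 at the default s = 0.55, a physiological value.
* **Latency** is Gaussian (default 200 ± 30 ms, floored at 90 ms);
  saccade endpoints get Gaussian landing noise (default 0.3°).
* **Pursuit** tracks the target velocity at `pursuit_gain`; positional
  error accumulates and a catch-up saccade fires when it exceeds 1.5°
  (after a 125 ms trigger delay). Both constants are configurable; 1.5°
  is a conventional foveal-error criterion.
* **Anti-saccade trials** err toward the cue with probability
  `antisaccade_error_p`; premature fixation breaks are Poisson with mean
  `premature_rate` per fixation period (an out-and-back excursion past
  the 2° central window).
* **Blinks**: one 150 ms invalid-sample gap per ~30 s window, placed so
  it never overlaps a logged event — this exercises the preprocessing
  mask without corrupting the oracle.
* **Sensor noise**: additive Gaussian position noise, default 0.02° RMS,
  typical of a video eye tracker at 1 kHz.

## 3. Event detection

`preprocess_gaze()` masks invalid samples ±50 ms, smooths position with a
centred 20 ms moving average, and differentiates by centred difference.
`detect_saccades()` uses two-threshold velocity detection: runs above
30°/s lasting ≥4 ms seed an event, whose boundaries are then refined
outward while speed stays above 15°/s. The refinement matters: a single
30°/s crossing under-covers the velocity pulse by an amount that depends
on peak velocity, which biases the measured duration-vs-amplitude
(main-sequence) slope upward by ≈12%; with refinement the bias drops
below 7% and median onset error on clean simulated trials is ≈4 ms.
Events closer than 20 ms are merged; events smaller than 0.5° or touching
the blink mask are dropped (dropping, not truncating, avoids corrupt
kinematics). Unmasked inter-saccade spans ≥40 ms become fixations
(pursuit epochs in the pursuit task). No single detection algorithm or
threshold set is canonical for this kind of recording; these are declared
package defaults, all configurable.

## 4. Feature battery

Per visually-guided step: the first saccade ≥1° starting ≥80 ms after the
jump (the standard anticipatory cutoff) defines reaction time, landing
error (distance from endpoint to target — "accuracy of saccades"
implemented as an error in degrees), Q-ratio and peak/mean velocity
ratio; earlier saccades count as premature; time-to-fixate is the latency
until gaze stays within 2° of the target for ≥100 ms. Per pursuit cycle:
gain is the median ratio of eye to target speed over visible-target
samples, excluding detected saccades and each cycle's first 100 ms;
catch-up saccades are the detected saccades inside the cycle. Per
anti-saccade cue: an error flag when the first saccade moves toward the
cue, reaction time for correct responses, and premature fixation breaks
(saccades leaving the 2° central window). The main-sequence slope is the
least-squares slope of duration on amplitude — the duration-based form,
matching how the feature is described for this battery, not the classic
amplitude-vs-peak-velocity form.

`aggregate_feature_vector()` reduces each metric to a central channel
(median for continuous metrics, total count for event metrics) and a
dispersion channel (SD across trials) in the fixed order of
`feature_registry()` — 28 features. Missing metrics stay `NA` and are
imputed with training-fold means inside the modelling loop only, keeping
extraction pure and cross-validation leakage-free. The "number of
fixations prematurely broken" and "premature saccades" are implemented as
one premature-saccade family with per-task counts.

## 5. Outcomes

`impact_pc()` builds PC-ImPACT: reciprocals of reaction time, impulse
control and symptom score (which improve downward), columns z-scored
(the composites have incommensurate units — unit-variance scaling is
required for the PCA to be meaningful), eigen-decomposition, and a sign
convention making the verbal/visual/visual-motor loadings positive so
higher PC-ImPACT means better neurocognitive performance. The symptom
composite is carried through by default (it receives a small loading),
with `drop_symptom = TRUE` available. `subtractive_normalize()` subtracts
each subject's first-session value from every session, flags baseline
rows (identically zero), and downstream SN fitting uses exactly
`rows − subjects` records. For the SN PC-ImPACT outcome the composites
are reciprocal-transformed first, baseline-subtracted, and the component
is fitted on the non-baseline deltas (deltas can be negative, so the
reciprocal must precede subtraction).

## 6. The mixed model and nested cross-validation

The core model is `y = Xβ + Zu + ε` with a subject random intercept,
fitted by maximum likelihood (not REML — ML is the estimation method this
analysis specifies). For this family the likelihood profiles analytically
over `β` and `σ²_ε`, leaving a one-dimensional maximisation over
`λ = σ²_u/σ²_ε` which we solve by golden-section search on `log λ` over
[−12, 16], always compared against the λ = 0 boundary (the OLS limit).
Per-subject block inversion makes each profile evaluation O(m p²), and
the backend is C++ (RcppArmadillo) because the nested cross-validation
below performs ~10⁵ fits per run; leave-one-out refits reuse rank-one
downdates of the sufficient statistics and warm-start the λ search in a
±2.5 window (in log units) around the full-training-set optimum. The fit
is exact for this model family; `fit_lme()` agrees with an independent
mixed-model implementation to ~1e−5 and with a brute-force
profile-likelihood grid search in the tests.

`loso_predict()` holds out each subject-session once. Within every outer
training set: missing features are imputed with training means, features
standardized by training statistics, a PCA fitted on training rows only,
and an inner leave-one-session-out loop evaluates each candidate PC count
(default grid 1–10), keeping the count that maximises inner
predicted-vs-actual Pearson correlation (ties go to the smallest count —
parsimony, and deterministic). The model is refit on the full training
set with the chosen PCs — with an intercept for the raw variant, without
for the subtractive-normalized variant (SN data are already offset-free)
— and the held-out session is predicted as `xβ + u_subject`, the
subject's BLUP estimated from that subject's *other* sessions (folds are
sessions, not subjects; this is what "leave-one-session-out" buys and why
the random intercept helps so much). Standardization and PCA are refit
inside every outer fold: the only leakage-safe reading of an optimization
"applied to the current training set". One PCA per outer training set is
shared across the inner enumeration (the reduction precedes the inner
loop). Pooled held-out metrics are Pearson correlation with a two-sided
t-distribution p-value, RMSE, bias (mean predicted − mean actual) and R².
A fixed-effects-only baseline runs through the identical procedure.

`feature_importance()` implements the importance weighting rule: per fold,
the top 20 features by |loading| on each selected PC are weighted by
|loading| × |PC coefficient| and summed per feature; weights are averaged
across folds and normalized so the top feature is exactly 1, reported
split by central vs dispersion channel.

## 7. The synthetic cohort: what it emulates, and what it does not

No real recordings ship with the package, so `simulate_cohort()`
generates the cohort every analysis runs on: 30 subjects × up to 4 sessions (pre-,
early-, late-, post-season). A latent impairment per session (default
0, 0.25, 1, 0.5 — none at baseline, peak late season, partial recovery)
jointly shifts:

* **ONSD**: baseline mean 4.0 mm (healthy range ≈3.5–5 mm), +0.30 mm per
  unit impairment (a significant late-season increase at n = 30),
  between-subject intercept SD 0.35 mm (baseline ONSD varies widely
  between healthy people), residual SD 0.15 mm (repeat-measurement
  noise);
* **ImPACT composites**: typical raw-score scales, worsening with
  impairment, with a shared subject-level cognition factor producing the
  moderate inter-composite correlations (~0.3–0.5) that make the first
  principal component dominant (~40–50% of variance on this generator),
  with the impulse-control and symptom scores only weakly involved so
  their first-PC weights stay an order of magnitude below the cognitive
  ones;
* **oculomotor parameters**: latency +15 ms, pursuit gain −0.08,
  anti-saccade error probability +0.08, premature rate +0.05, landing
  noise +0.15°, main-sequence slope +0.2 ms/° per unit impairment, each
  with plausible between-subject SDs.

Crucially, the subject intercepts in the *outcomes* are independent of
the subject's oculomotor parameters: features cannot predict them, and
only the random-intercept model — which learns each subject's offset from
their other sessions — can. This is what produces the analysis's central
qualitative pattern, the large gap between mixed and fixed-only held-out
correlation.

Two output modes exist. `output = "features"` (default) maps parameters
to feature expectations analytically and adds sampling noise scaled to
the per-trial counts (counts drawn from their Binomial/Poisson laws); it
is fast and is the mode the cohort-level tests and acceptance analysis
run on. `output = "traces"` simulates all three tasks at 1 kHz per
subject-session and is exercised at small scale in tests. Randomness uses
one root seed with per-subject/per-session counter-derived substreams, so
the cohort is byte-identical across runs and invariant to evaluation
order.

What passing tests do **not** show about real data: the generator is
linear-Gaussian with a single latent impairment; it has no learning or
fatigue effects across sessions, no task non-compliance, no asymmetric or
skewed feature distributions, no missing sessions (real cohorts lose a
sizeable fraction of measurements to quality control), no drift in
tracker calibration, and its
feature-measurement noise in feature mode is stylised. Detector and
feature recovery results on it bound algorithmic, not physiological,
validity.

## 8. Numerical choices and degenerate inputs

* λ search: golden section, 44 iterations globally (26 in warm-started
  inner folds); the λ = 0 boundary is always evaluated so the OLS limit
  is exact. Perfect within-subject fits are capped at λ = e¹⁶.
* Zero-variance feature columns are dropped per training fold; an
  all-missing column imputes to the fold mean (0 after centring).
* A training fold with constant outcome leaves its fold flagged with no
  prediction rather than an undefined correlation.
* Ties in inner-loop PC selection go to the smallest count; `which.max`
  on an ascending grid makes this deterministic.
* The permutation null of the pooled held-out correlation is wide:
  predictions lean on subject BLUPs, so the effective sample size is
  closer to the number of subjects (30) than of sessions (120), giving a
  null SD ≈ 0.17. Tests therefore bound the *mean* absolute null
  correlation across permutations rather than every single permutation.
* Cook's distance is scale-invariant, so "no influential points" is only
  meaningful with non-degenerate residuals; the diagnostics flag D > 1.

## 9. Problem sizes

The test suite and acceptance analysis use the full cohort-scale design
throughout: 30 subjects × 4 sessions (120 outer folds, inner grids of up
to 10 PC counts — on the order of 1.4 million mixed-model fits per
cross-validated run, a few tens of seconds with the compiled backend).
Detection accuracy is scored on 20 clean simulated visually-guided trials
(~1600 saccades); the type-I-error check pools 420 session t-tests from
20 null cohorts.

## 10. Known limitations

Random intercepts only (no random slopes or crossed effects); prediction
for a wholly unseen subject falls back to the population fixed effects —
a baseline session per subject is required for the model to be useful. The feature set is the representative battery
named above, not an exhaustive inventory. ONSD enters as a number; image
acquisition and reading are out of scope, as is accelerometer (head
acceleration event) telemetry.
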