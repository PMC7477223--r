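---
title: "Neuroadaptive generative modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuroadaptive generative modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogen)
```

## The closed loop

`neurogen` implements a brain-computer interface paradigm in which a
generative model is steered towards an operator's *perceptual category*
(say, "young faces") using nothing but single-trial EEG. Three components
interact:

* **Generate.** A generative model `G: Z -> X` maps points `z` of a latent
  space `Z` (dimension `m`, 512 for a typical face GAN) to stimuli. The
  package ships a toy linear generator behind the same interface; an
  external image generator can be attached but is never required.
* **Perceive.** Stimuli are shown in a rapid serial visual presentation
  (RSVP) stream at 2 Hz while EEG is recorded. Task-relevant stimuli evoke
  a late parietal positivity (the P300), the single-trial signature of
  relevance.
* **Adapt.** A classifier `f: S -> {0, 1}` labels each stimulus epoch as
  relevant or not, and the intention model updates

  `h(Z_n, y_n) = (sum_i y_i z_i) / (sum_i y_i)`

  — the arithmetic mean of the latent vectors whose epochs were classified
  relevant, a special case of the Rocchio relevance-feedback update. The
  final estimate after `N` presentations feeds back into `G` to render the
  inferred mental target.

Because real EEG is noisy, slow to collect, and not redistributable, the
package pairs the method with a *synthetic testbed*: an RSVP session
designer, a parametric multichannel ERP simulator with known ground truth,
and an end-to-end study runner. Every stage of the method is therefore
verifiable without any human data.

## Session design

`build_trial()` reproduces the oddball structure of an RSVP trial: 20
relevant and 50 irrelevant stimuli, no relevant stimulus immediately after
another relevant one, and at least one relevant stimulus in any five
consecutive presentations. The sampler draws the irrelevant run lengths
between relevant stimuli (1-4 internally, 0-4 at the edges) and rejects
draws whose total does not match, retrying up to 1,000 times; infeasible
class ratios fail loudly. Stimulus ids are drawn without replacement within
a trial and with replacement across trials. `build_session()` randomises
task order over blocks (default: 8 tasks forming 4 complementary pairs,
4 trials each) and assigns onsets at a 500 ms pace; irrelevant stimuli are
always drawn from the complementary category of the block's task.

Category membership itself is programmatic: a task is a unit direction `d`
in latent space and a vector is relevant when `d . z > 0` (ties fall to
irrelevant; the reverse task is `-d`). This replaces human curation of
stimuli and makes "matches the task" machine-checkable.

## The ERP simulator

`simulate_recording()` produces continuous multichannel recordings:

* **Background noise** — spatially independent 1/f-shaped ("pink") noise
  plus broadband white noise per channel. Defaults: pink SD 6 uV, white SD
  3 uV. These two SDs are free parameters of the testbed (real EEG noise
  depends on hardware and participant); they were calibrated once so that
  the full acquisition-scale synthetic study (32 channels, 1,000 Hz, 8
  tasks, roughly 1,700 training epochs per classifier) puts the held-out
  classifier AUC in the upper 0.7s — the operating regime reported for the
  paradigm — and then frozen.
* **Common evoked response** — a 1.5 uV occipital Gaussian component at
  120 ms for *every* stimulus, so that relevance classification cannot
  succeed by merely detecting stimulus onsets.
* **Relevance component** — a Gaussian-windowed parietal positivity added
  only for relevant stimuli: peak 464 ms after onset, amplitude 2.36 uV at
  the topography maximum (Pz), FWHM 150 ms, Gaussian spatial fall-off over
  a built-in 32-electrode 10/20 layout. Only latency, amplitude and
  topography are contract-bearing; the Gaussian waveshape is a modelling
  convenience. Per-task latency shifts and additional components (e.g. an
  N170-like response) can be injected through the same interface but are
  off by default.
* **Blink artifacts** — frontal transients of 500 uV at 5 per minute
  (RSVP suppresses blinking; the rate is chosen so that roughly a tenth of
  epochs are contaminated, matching the rejection budget below).

The simulator is additive and seeded: a recording equals its noise-only
version plus the injected components, bit for bit, which the test suite
exploits.

What the simulator does **not** emulate: volume conduction and spatially
correlated background activity, non-stationarity, alpha rhythms, latency
jitter and amplitude variability of the single-trial response, muscle or
line noise, or any face-specific components. Passing tests therefore show
the method's machinery is correct and behaves as specified under realistic
signal-to-noise ratios — not that any particular real dataset would yield
the same numbers.

### A note on overlapping epochs

At a 2 Hz pace an 1,100 ms epoch overlaps its neighbours. A relevance
positivity peaking at 464 ms is still rising and falling when the next
stimulus appears, so irrelevant epochs that follow a relevant stimulus
carry part of that response in their *baseline* window. Baseline
correction then shifts those epochs downwards, and the measured
grand-average difference slightly exceeds the injected amplitude — an
inherent property of fast RSVP designs, not a bug; the recovery checks
allow for it within sampling error (3 standard errors at 500 relevant
epochs). Per-epoch artifact ground truth, in contrast, is only exact for
non-overlapping epochs, which is how the rejection tests construct their
fixtures.

## Preprocessing

The pipeline order is fixed: band-pass filter, epoch + baseline-correct,
reject, decimate.

* **Filter**: linear-phase windowed-sinc FIR band-pass, 0.2-35 Hz,
  designed with `signal::fir1` and applied via FFT convolution with exact
  group-delay compensation (zero phase distortion at single-pass gain).
  The tap count is capped at `3 * rate + 1`; at that order the 0.2 Hz low
  edge cannot be fully realised, so the DC coefficient sum is nulled
  exactly (constant offsets are always removed) while sub-hertz drift is
  attenuated as sharply as the bounded order allows. Zero-phase
  application is a recorded choice; pass `taps` to change the order.
* **Epoch**: half-open window [-200, 900) ms relative to onset — exactly
  `1.1 * rate` samples (1,100 at 1 kHz, 275 at 250 Hz) — with the mean of
  the [-200, 0) ms baseline subtracted per channel.
* **Reject**: the epochs with the highest absolute maximum voltage are
  flagged, by default the top `ceiling(0.11 * n)` per recording
  (fraction mode, the "approximately 11%" heuristic); an absolute
  threshold mode exists for real data where per-participant thresholds are
  known. Amplitude ties are broken by rejecting the earlier-onset epoch
  first, making the rule fully deterministic.
* **Decimate**: keep every 4th sample (the 35 Hz cut sits far below the
  resulting 125 Hz Nyquist, so no extra anti-alias filter is needed), then
  re-apply baseline correction on the decimated grid so that retained
  epochs are exactly zero-mean over the baseline at the final rate.

## Classification

Features are spatio-temporal window means: the 50-800 ms post-stimulus
interval is split into 7 equal half-open windows and the mean amplitude per
channel per window is taken, concatenated channel-major (32 x 7 = 224
features at full scale). The classifier is Fisher-style linear discriminant
analysis with the pooled within-class covariance replaced by the
Ledoit-Wolf shrinkage estimate

`Sigma = (1 - lambda) S + lambda nu I`, `nu = tr(S)/d`,

with the analytically optimal `lambda` clipped to [0, 1] (maximum-
likelihood `1/n` covariance convention). Shrinkage keeps the discriminant
well-defined when features outnumber epochs. The decision score is placed
on a log-posterior-odds scale using the empirical class priors and mapped
through the logistic function; the resulting confidence is a two-class
posterior probability for the relevant class. A prediction is positive only
when the confidence *strictly* exceeds 0.7 — a deliberately conservative
gate that trades recall for precision, because false positives drag the
intention estimate towards the irrelevant category. "Posterior probability"
is our reading of the confidence score; the gate value is configurable.

Training pools epochs across tasks: the classifier for a task is trained on
all the participant's other tasks *except the target task's complementary
(reverse) task* — whose stimuli are the target task's own test stimuli —
plus the first 80% of the target task's epochs in presentation order. The
remaining 20%, still in presentation order, simulate the online phase:
their predictions drive the intention update in the order the stimuli were
seen. Labels in the pool always follow the *source* task's own relevance
assignment.

## Feedback models and evaluation

Three feedback modes bound the method's performance: `positive` uses the
predictions as-is; `negative` complements them (only vectors classified
irrelevant); `random` permutes the positive-mode labels uniformly,
preserving their count, so exactly as much feedback is given but detached
from the stimuli. When a mode yields zero positive labels the update is
undefined; `neurogen` treats this as an explicit error/undefined marker
rather than silently averaging everything, and study reports carry `NA`
for such cells.

Classifier quality is measured by the Mann-Whitney AUC (ties count one
half) and a label-permutation test: `k` refits on shuffled training labels,
evaluated on the fixed ordered test split, with
`p = max(#{permuted AUC >= observed}, 1) / k` — so `k = 100` gives a
minimum attainable p of exactly 0.01. Permutations shuffle training labels
at the epoch level; the test split is held fixed across permutations.

`grand_average_difference()` provides the classical ERP check: the
pointwise relevant-minus-irrelevant mean at one channel with its standard
error and the positive peak inside a 250-600 ms search window.

## The scaled simulation study

`run_study()` chains everything per simulated participant and task and
reports AUC, permutation p (optional), positive-prediction counts, and the
cosine similarity of each mode's final intention estimate to the true
category direction. Its defaults define the desk-scale testbed used by the
package's own acceptance checks:

* latent dimension `m = 8` — in 512 dimensions the cosine of even a
  perfect mean of a handful of vectors to the target direction is diluted
  by the other 511 coordinates; a low-dimensional space preserves the
  phenomenon while keeping it measurable;
* 4 tasks in two reverse pairs, 6 trials of 70 stimuli each (420
  epochs/task), 16 channels at 250 Hz — chosen so the classifier's
  training pool (about 1,100 epochs after rejection) and its parietal
  coverage keep the held-out AUC in the mid-0.7s with typically 5-9
  confident positives per task, inside the 5-60 range the paradigm
  operates in; with substantially smaller pools the 0.7 confidence gate
  frequently passes nothing and the positive-mode estimate becomes
  undefined rather than merely noisy;
* one participant per run; the run-level summary compared across feedback
  modes is the mean similarity over the run's tasks, i.e. a
  participant-level comparison.

Under these conditions the expected ordering is `positive > random >
negative`: the positive mean leans towards the category direction; the
random mean drifts towards the average of the presented test stimuli (which
is *negative* along the direction, since 50 of every 70 stimuli come from
the complementary category); and the negative mean aligns firmly with the
complementary category. Mean similarity under positive feedback also grows
with the number of processed presentations, which the trajectory
checkpoints (`n = 5, 10, 25, 50, all`) make visible. Convergence across
checkpoints is assessed *paired*: only cells whose estimate is defined at
every checkpoint enter the per-checkpoint means, because conditioning on
definedness otherwise changes the cell composition with `n` (an early
confident positive is not a random sample of positives) and masks the
trend.

One full run takes about two seconds; 100 runs, the scale at which the
ordering is asserted, about three to four minutes on one CPU. The
acquisition-scale configuration (32 channels, 1,000 Hz, 8 tasks, `m` = 512,
`k` = 100 permutations) runs in a few minutes per participant and is
exercised through documentation examples rather than the test suite.

## Numerical and degenerate-input conventions

* Half-open intervals everywhere (epoch window, baseline, feature windows)
  so sample counts are exact at both 1,000 and 250 Hz.
* Rejection ties: earlier onset rejected first.
* `lambda` is clipped to [0, 1]; a zero-dispersion input gets `lambda = 0`
  and training on degenerate (constant) features fails with a clear error
  rather than a numerical surprise. With exactly two samples the centred
  deviations cancel and the estimated shrinkage is zero by construction,
  so the shrunk covariance is only guaranteed positive-definite from three
  samples up.
* AUC and the update equation require both classes / at least one positive
  label and raise typed errors otherwise (`no_positive_feedback` for the
  update, so callers can distinguish the degenerate case).
* Trajectory checkpoints whose prefix has no positive labels are emitted
  as undefined markers, not errors.
* All randomness flows through explicit seeds; a study report is
  reproducible byte for byte from its master seed.

## Known limitations

* The toy generator is linear; nothing nonlinear about a real GAN's
  geometry (curved category manifolds, entangled attributes) is captured.
* Independent-channel noise slightly understates what multichannel
  classifiers can achieve on real EEG, where spatially correlated noise
  can be projected out.
* The human validation of generated images (selection and rating tasks)
  has no synthetic analogue; cosine similarity in latent space is the
  machine-checkable surrogate used throughout.
* Absolute-threshold artifact rejection is provided but untuned; the
  fraction mode encodes the published ~11% outcome, not per-participant
  thresholds.
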