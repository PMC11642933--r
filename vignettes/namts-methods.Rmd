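---
title: "Interpretable prediction of neonatal apnea and hypopnea with additive convolutional models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable prediction of neonatal apnea and hypopnea with additive convolutional models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Apneas and hypopneas in neonates at risk of upper-airway obstruction are
short (a few seconds), frequent (tens per hour) adverse events. Predicting
an *individual* upcoming event some seconds ahead — rather than detecting
it, or forecasting whole symptomatic episodes — would open the door to
automatic, pre-emptive intervention. The time scale rules out classical
epoch-level features; the clinical setting rules out opaque classifiers.

`namts` implements an inherently interpretable classifier for this task: a
**neural additive model (NAM) over time series**, in which each
physiological modality is processed by its own small fully convolutional
network (FCN) and the classification logit is the *sum* of the per-modality
outputs plus a bias,

$$\hat p = \sigma\!\Big(\sum_i \alpha_i f_i(x_i) + \beta\Big).$$

Six modalities enter the model: nasal pressure (NP), the standardized sum
of thoracic and abdominal respiratory effort (TA), heart rate (HR), the
photoplethysmogram (PPG), SpO₂ and transcutaneous PCO₂. Because the logit
decomposes additively, every prediction carries an exact per-modality
**additive contribution** $\alpha_i f_i(x_i)$; and because each subnetwork
ends in a per-timepoint linear combination of channels followed by global
average pooling, each contribution is exactly the time-mean of a
per-timepoint **activation map** that localizes discriminative signal
segments. Both identities hold to machine precision by construction and
are enforced by tests.

## Classification setup

Recordings are segmented into 30-second windows. A window is a **target**
if its end precedes an adverse-event onset by the prediction horizon
(default 15 s, safely above the longest annotated event so that imprecise
onset stamps cannot leak label information); it is a **control** if every
point is at least 180 s from every adverse event's start and end. Segments
annotated as adverse events or movement are masked out entirely; isolated
intermittent-hypoxia annotations are neither adverse nor masked. The 30 s
length is tied to the definition of periodic breathing: shorter windows
would make runs of periodic breathing trivially distinguishable by their
inter-event spacing alone.

Two windowing details are genuinely underdetermined by the setup and were
fixed as follows. Targets are anchored *per event* at
$[t-45\,\mathrm{s}, t-15\,\mathrm{s})$ rather than on a fixed 30 s grid —
per-event anchoring is the reading consistent with windows abutting events,
and it makes the horizon sweep well defined. When clustered events produce
overlapping target candidates, the earlier event wins, deterministically.
Control tiling starts at each eligible region's left edge and discards
sub-window tails. Windows containing missing samples are dropped, never
imputed.

## Preprocessing

Per modality, per window: NP (200 Hz), the two effort belts (50 Hz) and
PPG (100 Hz) are decimated to 5 Hz; SpO₂ and PCO₂ from 2 to 1 Hz; derived
HR stays at 1 Hz untouched. Decimation uses an order-8 Chebyshev type-I
low-pass, applied zero-phase (forward–backward) so pre-event signatures are
not shifted in time, factored into integer stages of at most 10. Filter
parameters the decimation reference leaves open were fixed at 0.01 dB
passband ripple and cutoff 0.8× the target Nyquist, and each stage is
normalized to exact unit DC gain. The rationale: zero-phase filtering
squares the magnitude response, so a conventional 0.05 dB ripple would cost
up to ~2.3% in-band amplitude error across two stages; 0.01 dB keeps
in-band sinusoid error below 1% (verified by test against directly
synthesized tones), and DC normalization makes constants pass through to
1e-6 rather than being attenuated by the ripple, which matters for
slowly-varying channels.

Oscillatory modalities (NP, TA, PPG) are standardized per window with the
population standard deviation; a signal with sd below 1e-12 maps to all
zeros instead of NaN (a raw channel that is exactly constant short-circuits
to that guard directly, so decimation roundoff is never amplified into
pseudo-signal). TA is formed by standardizing each belt, summing pointwise,
and standardizing again. HR, SpO₂ and PCO₂ are clamped to fixed physiologic
ranges (50–240 bpm, 60–100%, 30–70 mmHg) and mapped affinely to [-1, 1];
clamping treats out-of-range values as sensor artifacts.

## Architecture and training

Each subnetwork is `n_conv_layers = 3` blocks of (same-padded 1-D
convolution → batch normalization → ReLU) with 20 hidden channels, followed
by a per-timepoint linear collapse to one activation series and global
average pooling. Kernel sizes are odd, 5–17, selected by nested
cross-validation when a grid is supplied. The per-modality scales
$\alpha_i$ are not learned separately — they are absorbed into the collapse
layer, which is identical in expressive power; the reported contribution is
the whole additive term.

Training minimizes binary cross-entropy with Adam for 10 epochs at
learning rate 1e-4 and weight decay 0.01 (applied to convolution, collapse
and dense weights only — not biases, not batch-norm parameters, not β).
Controls are undersampled per patient to match the target count before
training; the rule is symmetric, so the rare patient whose targets
outnumber controls is balanced the other way, and single-class patients
drop out of training with a warning. Evaluation always scores *all*
windows of the held-out patient with batch normalization in evaluation
mode (running statistics), which makes predictions deterministic,
batch-independent, and input-wise additive.

Batch size is not pinned by the reference recipe and is config-exposed
(default 64). The desk-scale experiments in this package use batch size 16:
with cohorts of a few hundred balanced windows and the epoch count fixed at
10, batch 64 yields only a few dozen optimizer steps at a learning rate of
1e-4, which demonstrably underfits; batch 16 restores a step count at
which the same recipe converges. This is a property of the optimizer
budget, not of the model. Two experiments halve it further to batch 8,
where convergence of *every* subnetwork matters rather than overall
discrimination: the modality-importance readout (an untrained subnetwork
retains its initialization-scale contribution variance, which would mask
the planted modality's spread) and the small single-modality localization
experiment. Model *comparisons* (NAM vs blackbox) additionally average
three training runs per fold before the signed-rank test, the protocol's
guard against run-to-run noise masquerading as a systematic difference.

The blackbox counterpart shares the convolutional stacks but skips the
collapse: channel-wise global average pooling gives 20 features per
modality, concatenated (120 for six modalities) into a two-hidden-layer
MLP (width 64 — a default we fixed, as the reference leaves the head
unspecified). The feature baselines are an L2-regularized logistic
regression (ridge, glmnet) and a one-hidden-layer MLP (width 64, nnet) on
24 engineered features: per oscillatory modality, time-domain skewness and
excess kurtosis plus the spectral centroid, spread, skewness and raw
(non-excess) kurtosis of the DC-excluded normalized periodogram; per slow
modality, mean and range. Moments are computed on the *preprocessed* model
inputs so that both model families see the same information; the
time/spectral kurtosis conventions (excess vs raw) are declared here and
pinned by tests.

## The neural-network engine

No deep-learning framework is available in this package's dependency
stack, and the additive architecture *is* the methodological core, so the
engine (1-D same-padded convolution, batch normalization, ReLU, dense
layers, Adam, binary cross-entropy) is implemented in the package.
Activations for a batch live in flat `(T·B) × C` matrices; the hot kernels
(convolution and batch-norm passes) are RcppArmadillo code in `src/`, with
a convolution computed as one wide BLAS product against all kernel taps
followed by row-shifted accumulation; orchestration, Adam and the additive
bookkeeping stay in R. Analytic gradients for every layer are verified
against central finite differences in the test suite. Training is
bit-reproducible given the data and seed. Initialization is uniform with
bound $1/\sqrt{\text{fan-in}}$ per layer.

## Evaluation protocol

Patient-based leave-one-out cross-validation: all windows of one patient
form the test set; training and any hyperparameter selection see only the
other patients. Inner selection is grouped k-fold by patient (k = 5,
falling back toward leave-one-patient-out for small cohorts); ties prefer
the smaller kernel, then fewer channels. Per-patient AuROC uses midranks
(ties count ½). Operating points report TPR and precision at the smallest
threshold whose empirical FPR does not exceed 10/20/30%. Averaged ROC
curves are vertically averaged on a fixed 101-point FPR grid. The training
procedure can be repeated `n_runs` times with derived seeds and averaged
per patient (default 1 at desk scale; the repetition count is
config-exposed).

Significance: per-patient permutation tests of AuROC permute labels within
that patient's test set, with the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$, which
never returns zero and is calibrated (uniform under the null; verified by
a KS test across simulated null cohorts). Model comparisons use two-sided
Wilcoxon signed-rank tests over per-patient AuROCs: exact by dynamic
programming over midranks for up to 25 pairs (exact under ties as well),
normal approximation with tie and continuity correction beyond.

## The synthetic cohort generator

The clinical dataset is not bundled; a generator stands in for it so that
every stage is testable. It is phenomenological, not biophysical: it
guarantees the statistical contrasts a window classifier should exploit,
nothing more. Per patient it synthesizes the seven raw channels at native
rates: NP and the two effort belts share a wandering-frequency
(0.6–1.2 Hz), wandering-amplitude breathing oscillation with white noise;
PPG is a cardiac-band oscillation driven by the HR trace with baseline
wander; HR wanders around 140 bpm; SpO₂ around 97% with desaturation
carry-over for 30 s after every event (this is what makes clusters
informative); PCO₂ drifts around 41 mmHg.

Adverse events arrive through an episode-modulated Poisson process:
active episodes (mean 600 s) alternate with quiet stretches (mean 900 s),
the in-episode intensity is calibrated to the realized active time and
compensated for a 25 s minimum onset gap and for cluster follow-ups (with
probability `cluster_prob`, a follow-up lands 60–180 s later). The episode
structure is what produces the empirically reported regime of desk-scale
cohorts — control windows outnumbering targets despite tens of events per
hour — which a homogeneous stream cannot reproduce (the 3-minute control
buffer would erase virtually all controls). Movements are a homogeneous
Poisson overlay; roughly half the events get a trailing hypoxia
annotation.

The planted pre-event signature ramps linearly over
`[onset - signature_span_s, onset)` (default span 45 s, covering the
default target window) and scales with `signature_strength`: breathing
amplitude irregularity plus brief near-pause dips in NP (full strength) and
the effort belts (40%), an SpO₂ dip of up to 4% · strength, and a small HR
oscillation. Strength 0 disables everything, making pre-event windows
statistically indistinguishable from controls — the null cohorts used for
calibration checks. Everything is a deterministic, bit-reproducible
function of the config seed.

What the generator does *not* emulate: real waveform morphology, sleep
staging, artifacts beyond white noise, treatment effects, inter-patient
pathology differences. Passing the recovery experiments therefore shows
that the pipeline detects the kinds of contrasts it was built for — not
that it attains any particular performance on clinical data.

## Desk-scale experiment sizes

The package's experiments are sized for a single CPU: the main
experiment, the single-informative-modality recovery, the horizon sweep
and the blackbox comparison use cohorts of 8 patients × 2 h at 30 adverse
events/h (roughly a thousand windows); the null-calibration and
activation-map localization cohorts use 4–6 patients × 1 h. One training
repetition and a single-point default hyperparameter grid (kernel 9, 20
channels) are used at this scale; both are config-exposed. At these sizes the full-cohort leave-one-out
experiment trains in minutes; the reported behaviors (chance-level nulls,
modality recovery, horizon decay to chance by 150 s, blackbox parity,
localization) are qualitative properties with margins, not point
reproductions.

## Known limitations

* EDF support is read-only and covers plain 16-bit EDF; annotations embedded
  as EDF+ text streams are not parsed (annotation tracks arrive as
  CSV/JSON).
* `decimate()` accepts integer overall factors only — every rate pair in
  this pipeline is integer — and the fixture dialect, not EDF, is the
  bit-exact reference format.
* The Wilcoxon exact mode switches to a corrected normal approximation
  above 25 pairs; p-values there are approximate, as is conventional.
* Nested hyperparameter selection multiplies runtime by the grid size and
  the inner fold count; the desk-scale defaults use a single-point grid.
* The generator's defaults match printed descriptive ranges of the regime
  it emulates, not distributions; absolute AuROC values on synthetic
  cohorts are properties of the generator, not clinical estimates.
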