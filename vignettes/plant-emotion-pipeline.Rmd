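---
title: "Classifying human emotions from plant electrical signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying human emotions from plant electrical signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantsense)
```

## The problem

A plant sitting next to a person behaves as a crude electrophysiological
sensor: the voltage between its tissue and the soil responds to
environmental changes — light, pressure, electrostatic fields — at
bioelectric propagation speeds. `plantsense` implements a complete analysis
pipeline for the question of whether such a signal, recorded at audio-like
rates (10 kHz) while the person watches emotionally charged videos, carries
enough information to classify the person's emotion among the seven facial
classes *Anger, Disgust, Fear, Happiness, Neutral, Sadness, Surprise* (the
six Ekman basic emotions plus Neutral), using per-second facial-emotion
labels as ground truth.

Because no public recording of this kind is deposited, the package is built
around a seeded synthetic-session generator that emulates the study
conditions, so every stage — preparation, training, selection, evaluation —
is testable end to end.

## The synthetic-session generator

A session is defined by the stimulus schedule: 15 videos with expected
emotions and durations summing to 560 s. The full session is stated to be
690 s, so the generator inserts uniform inter-video gaps to pad to a
configurable total (130 gap seconds by default, assigned to the earliest
gaps when the division is uneven). This padding is an assumption of ours —
the discrepancy between the printed durations and the stated total is not
explained at the source — and gap seconds elicit Neutral.

Three seeded draws produce a session:

1. **Latent emotions.** Each video second is the video's expected emotion
   with probability $1-\texttt{neutral\_rate}$, else Neutral;
   mixed-emotion ("Multiple") videos draw a uniform non-Neutral emotion per
   second. `neutral_rate` defaults to 0.1 — occasional affective lapses.
2. **Plant signal.** The voltage trace is
   $x(t) = b(t) + d(t) + a_{e(t)}\sin(2\pi f_{e(t)} t)$: an AR(1) baseline
   with coefficient 0.999 and unit marginal variance (slow, correlated
   fluctuations of the kind plant voltage traces show), a low-amplitude
   sinusoidal drift (electrode/environment conditions), and an
   emotion-dependent sinusoid. Each non-Neutral emotion $e$ has a distinct
   integer carrier frequency $f_e$ (37–127 Hz) and amplitude
   $a_e = \texttt{effect\_amplitude} \times w_e$, where the arousal weights
   $w_e$ are 1.0 for Fear/Anger/Surprise, 0.7 for Disgust, 0.5 for
   Happiness/Sadness and 0 for Neutral. The carrier phase is locked to
   global session time and the frequencies are integers, so each 1-s
   segment of an emotion is a deterministic template plus noise.
3. **Face labels.** The latent sequence is copied with each second
   independently replaced by a uniformly random *other* emotion with
   probability `label_noise_rate`; the default 0.14 emulates the ~86%
   accuracy regime reported for the facial-emotion recognizer used for
   ground truth.

With probability `dropout_prob` a session records nothing and is flagged as
a malfunction, emulating the sensor failures that removed sessions from the
real study; the session loader excludes flagged sessions by default.

**Why this generative model.** The physical mechanism linking emotions to
plant voltage is unknown — the study measured real plants and fitted
black-box classifiers. The carrier-plus-arousal-weight model was chosen
because (a) distinct carriers make the classes separable by spectral
features (MFCCs) as well as by waveform shape, and (b) the arousal weights
make high-arousal emotions easiest to detect, mirroring the hypothesis that
emotional arousal drives detectability. What passing tests on this data
show is that the *pipeline* recovers planted class structure and is honest
under a null; they say nothing about whether real plants carry such
structure.

Features of real data the generator does **not** emulate: action-potential
spikes, non-stationary electrode drift, inter-participant gain variation
beyond what z-normalization removes, and any temporal autocorrelation of
the label errors.

## The two preparation tracks

**Windowed track.** Each recording is z-normalized once per file
(population convention, $\sigma = \sqrt{\frac1N\sum(x-\bar x)^2}$;
a constant signal is a hard error rather than a silent zero). Sliding
windows of `window` seconds advance by `hop` seconds; only complete windows
are kept, so a $T$-second recording yields
$\lfloor (T-\mathrm{window})/\mathrm{hop}\rfloor + 1$ windows (68 for
690 s at the selected window 20 s / hop 10 s). A window takes the label of
the last second it fully covers (the end-of-window rule); seconds are
0-based, half-open. Windows are downsampled with anti-aliased polyphase FIR
resampling (`signal::resample`); a naive stride decimator is kept behind
`method = "stride"` for ablation only. MFCC matrices are computed per
window: 25 ms frames with 10 ms hops (speech-processing defaults; the
source states neither frame parameters nor whether MFCCs were taken before
or after downsampling — we compute them at the native rate), Hamming
window, FFT power spectrum, 64 triangular mel filters, log, orthonormal
DCT-II, keeping `n_mfcc` coefficients (20/40/60 in the searched grid).

**Raw track.** Consecutive 1-s segments at the native rate, each
z-normalized independently, no downsampling — 690 segments of 10,000
samples per full-scale session.

**Expected-emotion filter.** Items whose label contradicts the emotion the
active video was designed to elicit are dropped (never relabeled). The
filter retains Neutral-labeled items by default: a strictly literal filter
would delete every Neutral item, yet the study reports a large Neutral
class surviving it, so retention is the only reading consistent with the
reported counts. `policy = "strict"` implements the literal reading.
Mixed-emotion videos match any label; gap seconds match Neutral only.
Filtering is applied after labeling, at window/segment granularity. The
windowed track keeps all 7 classes; the raw track excludes Neutral and
works with 6 (the class imbalance otherwise swamps the no-windowing
models).

## Models and training

Seven classifier families are built from declarative specs. No
deep-learning framework is available to this package's dependency
footprint, so the package carries its own small neural engine — dense,
1-D/2-D convolution (stride 1, im2col), max pooling, global average
pooling, residual 2-D blocks and bidirectional LSTM layers, trained with
Adam under (optionally class-weighted) categorical cross-entropy in
minibatches of 64, with early stopping (default patience 10 epochs, a
value the source never prints) that restores the best-validation-loss
weights. Every layer's backward pass is verified against central finite
differences in the test suite.

* **MLP** — ReLU dense blocks with dropout (selected: 2 × 4096, dropout 0.2).
* **BiLSTM** — stacked bidirectional LSTMs, then ReLU dense 1024 and 512
  with dropout (selected: 2 × 1024 units).
* **MFCC-CNN** — 2-D conv blocks with 2×2 max pooling, dense head
  (selected: 96 filters, 2 layers, kernel 7 — note 96 is the tuned value
  even though the printed search axis is {64, 128}).
* **MFCC-ResNet** — a compact residual backbone (stem conv, two stages of
  two residual blocks at 16 and 32 filters, global average pooling) with
  the classification head replaced by dense 1024 + dropout. The
  `pretrained` axis requires a user-supplied weights file
  (`pretrained_weights`); no published backbone weights are bundled. The
  selected configuration is `pretrained = No`, so the default path is
  unaffected.
* **RF** — a probability forest via `ranger` (selected: 300 trees, depth
  20); vote fractions are the probability vector.
* **1D CNN** — swish conv/pool blocks, swish dense 100 (selected: 96
  filters, 2 layers, kernel 7; the prose description of 64 filters/kernel 3
  conflicts with the tuned table, which wins as the default).
* **BiLSTM (raw)** — stacked bidirectional LSTMs on the 1-s waveform,
  swish dense 100.

All models end in a softmax dense layer of `nbemotion` units and classify
by argmax, ties breaking toward the lowest class index.

**Balancing.** `balance` resamples every class in the *training folds only*
to the mean per-class count (oversampling rare classes with replacement,
undersampling majority classes without; the target count is not stated at
the source — the mean achieves both directions and is configurable to the
median). `weights` leaves data untouched and weights the loss by
$w_c = N/(\mathrm{nbclass}\cdot n_c)$, so $\sum_c n_c w_c = N$. Classes are
counted over those present in the training fold. Balancing validation or
test data would corrupt the metrics and is never done.

## Grid search, folds, selection

The printed search grids are enumerated exactly — 288 (MLP), 648 (BiLSTM),
864 (MFCC-CNN), 432 (MFCC-ResNet), 60 (RF), 144 (1D CNN), 108 (raw
BiLSTM) configurations — as a deterministic lexicographic Cartesian
product. Five folds give the 60/20/20 train/validation/test split; each
rotation tests one fold, validates the next, trains on the rest, so every
item is tested exactly once across rotations. Whether the original folds
were split by window or by participant is not stated; the default here is
participant grouping, which prevents overlapping windows of one session
from straddling train and test (window-level grouping remains available
for a literal reading). Configuration performance is the fold-average of
overall accuracy and macro recall; the selection score is accuracy
(configurable to recall), ties breaking toward the earliest configuration.
Final training reuses the winning spec verbatim with a 1000-epoch cap.

## Evaluation

Overall accuracy is `trace/total` — the one-vs-rest TP/TN form collapses to
correct-over-total when aggregated, the only reading consistent with a
single accuracy per model. Macro (average) recall is
$\frac{1}{\mathrm{nbclass}}\sum_c \mathrm{TP}_c/(\mathrm{TP}_c+\mathrm{FN}_c)$;
a zero-support class is an error unless explicitly masked. Support-weighted
recall $\sum_c (n_c/N)\,\mathrm{recall}_c$ equals overall accuracy
algebraically — the identity is asserted over 1000 random matrices in the
tests. Precision and F1 use the zero-denominator convention (0 for a class
never predicted), reproducing all-zero rows for undetected classes.
Row-normalized confusion matrices carry per-class recall on the diagonal.

The valence–arousal layer groups emotions into quadrants — Q1
(positive/high): Surprise, Happiness; Q2 (negative/high): Fear, Anger,
Disgust; Q3 (negative/low): Sadness; Center: Neutral — and splits errors
into intra- vs inter-quadrant. Disgust sits in Q2 so that the
disgust-as-fear confusion counts as intra-quadrant, matching how that
confusion is discussed; the map is configurable since the underlying
placement is approximate.

## Numerical and design choices

* z-normalization uses the population (1/N) standard deviation; it is
  idempotent and invariant to positive affine rescaling of the raw signal,
  which the tests assert.
* Partial trailing windows/segments are discarded with a warning.
* Downsampling requires an integer rate ratio (all rates in the study are
  integer multiples).
* The MFCC log uses a $10^{-10}$ floor; empty mel filters therefore yield
  the floor rather than $-\infty$.
* The ResNet image adapter min-max scales an MFCC matrix to $[0,1]$,
  resizes bilinearly (two-pass linear interpolation) and replicates to 3
  channels; a constant matrix maps to zeros with a warning.
* RNG discipline: every stochastic step (simulation, fold shuffles,
  resampling, weight init, minibatch order, dropout) is an explicit
  function of caller-provided seeds; identical configurations are
  bit-reproducible, which the determinism tests assert.
* Training divergence (non-finite loss) marks a configuration as failed
  rather than aborting a search.

## Problem sizes in the shipped analyses

The numbered scripts under `analysis/` and the verification suite run at
desk scale, chosen once: cohorts of 6–12 participants, 1 kHz sampling, and
the stimulus schedule scaled to 25% duration (~172 s per session, all 15
videos and gaps retained). Structural checks (6,900,000 samples per
session, 690 × 10,000 segmentation, 68 windows at window 20/hop 10) run at
the native full scale. The parameter-recovery run uses
`effect_amplitude = 3` with noise-free labels — the planted structure is
then near-perfectly recoverable and the RF raw-track pipeline is expected
to exceed 0.90 held-out accuracy; the null run (`effect_amplitude = 0`)
uses a class-balanced subsample (drawn without replacement, so no
duplicated noise rows can leak across folds) because a chance-level test is
only meaningful when the class prior is uninformative; its accuracy is
expected within 3 standard errors of $1/6$.

## Known limitations

* The generator's class signal is stationary within a second and
  phase-locked; real plant responses, if any, would be none of these.
* The built-in neural engine is CPU-bound and desk-scale; the full neural
  grids (hundreds of configurations) are enumerable but not practically
  trainable with it at full input sizes.
* `pretrained = TRUE` for the ResNet family depends on externally supplied
  weights.
* Real-data headline numbers cannot be reproduced here: the study's
  recordings are available only on request, and no accession exists.
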