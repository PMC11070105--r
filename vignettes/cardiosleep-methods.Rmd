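---
title: "Methods: joint SDB-event detection and sleep-wake classification from cardiorespiratory signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint SDB-event detection and sleep-wake classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiosleep)
```

## The problem

Polysomnography (PSG) scores sleep-disordered breathing (SDB) with two
manual annotations: a hypnogram (sleep stage per 30-s epoch) and a list of
respiratory events (apneas and hypopneas). The clinical summary statistic,
the apnea–hypopnea index (AHI), divides the event count by total sleep
time (TST). Methods that detect events from surrogate signals but cannot
tell sleep from wake must fall back on the respiratory event index (REI),
which divides by time in bed (TIB) and systematically underestimates
severity in subjects with low sleep efficiency (TST/TIB).

`cardiosleep` implements a fully automatic alternative that uses only two
cardiorespiratory channels — the RR-interval tachogram from detected
heartbeats and a thoracic respiratory-effort (RE) belt — and learns both
tasks jointly: a per-second SDB-event probability and a per-epoch
sleep–wake probability, from which TST, AHI and an SDB severity class
follow without any human scoring.

## Signal conditioning

Heartbeat times arrive with a per-beat artifact/ectopic mask (beat
detection itself is out of scope; the pipeline ingests beat times). The
instantaneous RR value at each unmasked beat is the interval to the
previous unmasked beat; values outside a physiological gate of
[0.3, 3.0] s — including the long pseudo-intervals that bridge masked
stretches — are discarded, and the remaining (time, RR) samples are
linearly interpolated onto a uniform 4 Hz grid, with nearest-value
extension at the edges. The gate is a guard the package adds explicitly
because ectopic-beat classification is delegated upstream; windows in
which more than half of the beats are masked are flagged unusable.

The effort channel is low-pass filtered (Butterworth, order 4, 2 Hz) to
remove high-frequency noise, resampled to the same 4 Hz grid, and
high-pass filtered with an order-3 Butterworth at 0.05 Hz to remove
baseline drift. Both filters are applied forward–backward (zero phase):
the labels are time-locked to the signals, and a causal filter's group
delay would misalign events by several seconds. The zero-phase pass
squares the magnitude response, which only sharpens both band edges; the
0.25 Hz breathing band is preserved to well under 1%.

## Segmentation and labels

The two aligned channels are cut into 5-minute windows with a 180-s step
(2-minute overlap), anchored at lights-off so every window starts on a
30-s epoch boundary; a trailing partial window is dropped. Each window
yields a 1200 x 2 input (300 s at 4 Hz, RR and RE), a 300-sample binary
event target (1 Hz; a second is positive if it intersects any scored
event, of any type) and a 10-label binary sleep target (one per epoch;
wake = 0, any of N1/N2/N3/REM = 1).

Each window's channels are normalized independently by soft min–max: an
affine map sending the 5th percentile to 0 and the 95th to 1, without
clipping. Percentiles are computed per channel per segment — normalizing
per channel keeps the two channels' scales comparable across subjects and
sensors while staying robust to outliers a hard min–max would latch onto.
A window with degenerate spread (p95 = p5, e.g. a flat-lined channel)
normalizes to zeros and is flagged unusable rather than producing
non-finite values.

## The multi-task network

The model is a shared-trunk, two-head recurrent network:

* **Shared trunk** — two blocks, each of two bidirectional GRU layers
  followed by batch normalization, temporal max-pooling, ReLU and
  dropout. The two pool factors (2, 2) bring 1200 samples to 300, i.e.
  the trunk output lives at 1 Hz — exactly the event-label rate.
* **Event head** — two further bidirectional GRU layers with batch
  normalization, ReLU and dropout, then a dense ReLU layer and a dense
  sigmoid layer applied per time step: one event probability per second.
* **Sleep head** — three convolutional subblocks (temporal convolution
  with ReLU, batch normalization, max-pool, dropout) with pool factors
  (5, 3, 2), taking the 1 Hz trunk features to 1/30 Hz, then the same
  dense ReLU / dense sigmoid classifier: one sleep probability per epoch.

Only the pooling products are forced by the label geometry (4 overall for
the trunk, 30 for the sleep head); widths, kernel sizes and dropout are
free hyperparameters collected in `sdb_hyper()` (defaults: 64 GRU units
per direction, 32 convolution filters with time-axis kernels of length 5,
hidden dense width 64, dropout 0.2, kernel L2 1e-4). The sleep-head
convolution is implemented as a temporal convolution over the trunk's
feature channels — a kernel that spans the time axis only, with full
feature mixing; sharing one singleton-channel kernel across features
would leave the head too little capacity at the small widths this package
targets.

A single-task comparison model (`build_single_task_model()`) keeps the
identical trunk and event head but has no sleep head; its detected events
can only be normalized by TIB, yielding REI.

There is no deep-learning framework dependency: forward and backward
passes (including the GRU recurrence, batch-norm statistics, max-pool
argmax routing and the convolutions), Xavier-uniform initialization and
the Adam optimizer are implemented in the package, with the sequential
GRU recurrence in compiled code. Correctness is guarded by a
finite-difference gradient check in the test suite.

## Training

Adam (learning rate 0.001, weight decay 0.0001), batch size 128,
shuffling each epoch. The loss is the sum of two binary cross-entropies:
the event term weights event seconds 10:1 against normal breathing (event
seconds are rare), the sleep term is unweighted. Training stops when the
validation loss has not decreased for 10 consecutive epochs, and the
weights of the best validation epoch are restored; a configurable epoch
cap (default 200) is a safety net. Weight decay enters as an L2 term on
all parameters inside the optimizer; the kernel regularization penalty
additionally hits the weight matrices.

## Cross-validation and thresholds

Evaluation uses subject-exclusive, severity-stratified fourfold
cross-validation: subjects are classed normal/mild/moderate/severe by
reference AHI (boundaries 5/15/30 events/h, half-open intervals), each
stratum is split into four quarters, and one quarter per stratum forms
each fold. Per iteration the three non-test folds are re-pooled,
re-stratified, and split 75%/25% into training and validation subjects.
Early stopping and decision thresholds see validation subjects only.

Both decision thresholds are selected on the validation set by a grid
search over 0.01–0.99 in steps of 0.01 (the grid resolution is a package
choice), ties resolved toward the lower threshold. The sleep threshold
maximizes epoch-level F1 with sleep as the positive class, computed on
the center-covered epochs of the stitched validation nights — matching
how test performance is evaluated. The event threshold is chosen second,
because wake masking (below) feeds event formation: it maximizes
event-level F1 after masking with the already-chosen sleep threshold.

## Whole-night inference

Per-segment outputs are stitched with the center-3-minute rule: from each
5-minute window only the central 3 minutes are kept — the outer minute at
each end is half of the overlap shared with the neighbouring windows —
and the kept windows tile the night exactly. The first and last minute of
the night are covered by the outer minutes of the first and last segment,
an extension beyond the center rule so TST and AHI see the whole record;
agreement metrics, in contrast, use only center-covered epochs.

A 30-s epoch is sleep if its probability reaches the sleep threshold; a
second is an event sample if its probability reaches the event threshold
*and* its epoch was classified sleep (events during detected wake are
reassigned to normal breathing). Consecutive event seconds merge into
discrete events (half-open intervals). Detected events are matched to
reference events greedily in time order, one-to-one, counting a true
positive when they overlap by at least one second; this matching rule is
a committed interpretation (the exact rule of the antecedent study is not
public) and is isolated so alternatives can be swapped. No minimum
duration is imposed on detected events.

TST is 30 s times the number of detected sleep epochs; AHI divides the
detected event count by TST, REI by TIB. A subject with detected events
but zero detected TST has an undefined AHI and is excluded from AHI
agreement with a logged reason.

## Agreement statistics

Per subject and pooled: Cohen's kappa, F1, sensitivity and specificity
for sleep–wake (both classes as positive), pooled event
sensitivity/precision/F1 from summed TP/FP/FN, Bland–Altman bias with
95% limits of agreement (bias ± 1.96 x sample SD of differences),
Spearman correlation (average ranks on ties) and MAE for TST and AHI.
Severity classification is reported with and without near-boundary
double-labeling (NBL): a subject whose reference AHI lies within a zone
around a class boundary is accepted as correct in either flanking class.
The zone half-widths default to 10% of each boundary (0.5, 1.5, 3.0
events/h) — the published zones of the originating clinical study are
not printed anywhere accessible, so the package makes them explicit and
configurable. In the NBL confusion matrix a correct-by-zone pair is
tallied on the reference class's diagonal; kappa is computed on that
resolved matrix.

`efficiency_sweep()` reproduces the sleep-efficiency analysis: for each
cutoff it pools subjects with reference sleep efficiency at or below the
cutoff and reports Spearman R and MAE of AHI (multi-task) and REI
(single-task) against reference AHI; subsets smaller than three subjects
are reported missing.

## The synthetic cohort generator

Real scored PSG cohorts are access-restricted, so the package ships a
generator (`simulate_subject()`, `simulate_cohort()`) that emulates the
statistical structure the model must learn, with full ground truth:

* **Hypnogram** — a two-state (wake/sleep) per-epoch Markov alternation
  whose stationary sleep fraction equals the target sleep efficiency;
  the mean wake-bout length is fixed at 2 minutes. Sleep epochs receive a
  cosmetic uniform NREM/REM relabel, since every downstream consumer maps
  all sleep stages to one label.
* **Events** — a renewal process on the cumulative-sleep-time axis whose
  onset rate equals the target AHI per sleep hour; durations are uniform
  on a configurable range with a 10-s minimum (the standard scoring
  minimum). Onsets therefore always fall inside sleep epochs, and
  spacing by construction prevents overlap. The realized reference AHI
  is recomputed from the realized events and realized TST.
* **RR tachogram** — beats generated sequentially at a base heart rate
  with AR(1) variability, inflated during wake by a configurable factor;
  each event imprints a smooth RR lengthening (raised half-sine, peak
  +15% by default) followed by a ~10-s undershoot of −10% after the
  event ends — the cyclic variation pattern the event head must learn. A
  small fraction of beats is marked as artifacts with perturbed timing.
* **Effort** — a quasi-sinusoid at ~0.25 Hz whose envelope collapses to
  5% during apneas and to a configurable fraction (40% by default)
  during hypopneas, with raised-cosine transitions, additive noise, and
  extra movement noise during wake.

Defaults describe a plausible clinical night (8 h in bed, sleep
efficiency 0.85, heart rate 60 bpm, RR variability 50 ms, effort sampled
at 25 Hz); cohort generation assigns severity strata round-robin so all
four classes are populated, and draws per-subject sleep efficiency from
0.6–0.95. `sim_config_strong()` is a fixed variant with pronounced
signatures (RR excursion 0.25, wake HRV multiplier 3, hypopnea depth 0.3,
fewer artifacts) for desk-scale recovery experiments with small training
budgets.

What the generator does *not* emulate: realistic HRV spectra (only an
AR(1) process with an event-locked deterministic component), oxygen
saturation, arousals, paradoxical thoraco-abdominal phase (a single belt
cannot express it), position effects, or inter-scorer noise in the
labels. Tests that pass on synthetic cohorts therefore demonstrate that
the pipeline's machinery — preprocessing, learning, stitching,
estimation — recovers known structure; they are not evidence of clinical
performance on real PSG.

## Numerical and design choices

* Percentiles use linear interpolation (R's type-7 quantile); the test
  suite pins them to an independent sort-based oracle.
* Batch normalization uses biased batch variance with momentum 0.1 and
  eps 1e-5; validation and prediction run with running statistics.
* Max-pool backward routes gradients to the stored argmax (first maximum
  on exact ties).
* ReLU uses subgradient 0 at exactly 0.
* The gradient check avoids bias initializations that put pre-activations
  exactly on the ReLU kink (where one-sided derivatives differ).
* Thresholds grid 0.01; ties toward the lower threshold make selection
  deterministic.
* Sleep threshold before event threshold (masking feeds event F1); the
  order is a package decision where the antecedent text is silent.
* All randomness flows from explicit integer seeds; per-subject generator
  streams derive from (seed, subject index), so cohorts are reproducible
  and individual subjects are independent of cohort size.

## Desk-scale problem sizes

The package's recovery experiment (`sdb_recovery_experiment()`, also run
by `scripts/acceptance.R` and the test suite) uses a 40-subject synthetic
cohort with strong signatures, 4 h in bed per subject, a reduced model
(6 GRU units per direction, 6 convolution filters, dense width 16,
dropout 0.1), a 25-epoch training cap, and the first cross-validation
iteration's held-out fold for evaluation. These sizes are the package's
choice of a desk-scale experiment: large enough that the held-out fold
spans all four severity strata and sleep–wake agreement is measured over
thousands of epochs, small enough to run routinely. Running all four
iterations quadruples cost without changing what the experiment
demonstrates.

## Known limitations

* The synthetic signatures are placeholders with convenient statistics,
  not validated physiology; absolute performance numbers on synthetic
  cohorts do not transfer to real recordings.
* Layer widths of the published architecture are not legible from the
  source figure; defaults are package choices, exposed in `sdb_hyper()`.
* The event-matching rule and the NBL zone widths are committed
  interpretations of procedures whose exact parameters are not public;
  both are configurable.
* Training is CPU-bound R + compiled code; it is intended for desk-scale
  experiments, not full-cohort clinical training runs.
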