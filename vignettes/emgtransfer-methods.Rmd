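---
title: "Decoding hand-movement intention from sEMG: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hand-movement intention from sEMG: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emgtransfer)
```

## The problem

Myoelectric interfaces decode a user's intended hand movement from surface
electromyography (sEMG): multichannel recordings of muscle electrical
activity taken from skin electrodes on the forearm. Decoders are typically
trained per user, and collecting a large labeled dataset from every user for
every movement class is impractical. This package implements a complete
decoding stack for 10-channel forearm sEMG — preprocessing, handcrafted
feature baselines, two compact convolutional networks — together with two
transfer-learning strategies that reduce the per-user data burden:

* **Subject transfer (PFCnet).** Reuse feature extractors trained on *other*
  subjects. Two convolutional feature extractors — one trained on the target
  subject, one on the pooled source subjects — are frozen and applied in
  parallel; their flattened outputs are concatenated and a fresh classifier
  head is trained on the target subject's (possibly scarce) data.
* **Task transfer (Syn0net / Sia5net / FTnet).** Reuse a network trained on
  8 *basic* movements (wrist rotations: pronation, supination; hand
  functions: pinch, lateral pinch, grip; plus three further gestures) to
  classify 6 *combined* movements, each the simultaneous execution of one
  rotation and one function. The muscle-synergy premise is that a combined
  movement's activation pattern superposes its components' patterns, so a
  basic-movement decoder already carries usable information about combined
  movements.

## Preprocessing

Raw signals (microvolts, 2048 Hz for the 10-channel protocol emulated here)
pass through a 10–500 Hz Butterworth band-pass (4th order) and a 50 Hz
Butterworth notch (2nd order, ±2 Hz). Both are applied zero-phase
(forward–backward), which doubles the effective order; the package targets
offline analysis, where non-causal filtering is standard. The band-pass is
realized as a high-pass/low-pass cascade because a direct 8-pole band-pass
polynomial is numerically ill-conditioned at a 10/1024 normalized corner.

Cue schedules partition a recording into rest / preparation / movement
intervals. Each movement trial is trimmed to its *active* interval by a
threshold rule: the envelope (cross-channel mean of the moving-average
smoothed rectified signal, 100 ms window) must exceed
`mean + 3·SD` of the preceding rest interval's envelope for at least 50 ms.
The smoothing width, threshold multiplier and hold time are package
defaults — the procedure is standard but its constants are genuinely open,
so all three are configurable. The first and last 100 ms of the active
interval are then discarded (`floor` conversion from ms to samples, so never
more than 100 ms): classifiers target the steady-state signal, not the
electromechanical transient. The trim is applied to the onset-detected
interval, not the raw cue interval, which is the stricter of the two
readings. Finally a sliding window of 512 samples (250 ms) with a 128-sample
stride (62.5 ms; 384 samples overlap) yields the fixed-size inputs every
classifier consumes: `floor((L − 512)/128) + 1` windows per trial.

Train/test splits assign whole repetitions, never windows, so overlapping
windows cannot leak across the split. Two named policies are built in: per
(class, orientation) the first 3 of 5 repetitions to train (the remaining 2
test), and the 1/3/4/6-vs-2/5 split used with 6-repetition protocols. Which
3 of 5 repetitions go to train is not specified by the protocol; the package
deterministically takes the first three in acquisition order.

## Handcrafted features and classical baselines

Fifteen per-channel window features are implemented: MAV, IEMG, RMS,
waveform length; threshold-gated zero crossings and slope-sign changes
(threshold `0.01·SD` of the window by default — a conventional choice, the
protocol leaves it open); the three Hjorth parameters with derivatives taken
as first differences; bias-adjusted sample skewness; sample entropy (m = 2,
r = 0.2·SD — the conventional values); and cepstral coefficients CC1–CC4
derived recursively from an AR(4) fit (Levinson–Durbin on the biased
autocorrelation). Four feature sets are named: TD (4), ITD (9), CB (7,
exporting CC1 only from the order-4 fit) and Full (15). Tables are laid out
channel-major (`<feature>_<channel>`).

Outlier handling winsorizes training values at ±3 SD per column *before*
computing the scaling statistics, then z-scores everything with those
training statistics; winsorization (rather than row deletion) keeps rows
aligned with labels. Test tables only ever see training statistics.

Baselines: KNN (40 neighbors, Euclidean), linear SVM (C = 1), LDA, and an
MLP with one 300-unit tanh hidden layer trained by Adam at learning rate
1e-4. The MLP runs on the package's own dense-network engine because the
classical single-hidden-layer implementations available use a logistic
activation, and the tanh activation at that learning rate is part of the
baseline's definition.

## The convolutional networks

`Cnet1D` and `Cnet2D` share one skeleton: three convolution blocks
(convolution → batch normalization → RReLU → max-pool along time → dropout
p = 0.3) followed by a 300-unit and a 50-unit fully connected block and a
softmax output. Kernel time extents are 13, 9, 5 with 'same' padding along
time; max-pool width is 4 (or 3 for 2 kHz 6-repetition protocols). `Cnet2D`
kernels additionally span 3 adjacent channels with 'valid' boundaries, so
the channel extent shrinks 10 → 8 → 6 → 4 and electrode adjacency matters;
`Cnet1D` kernels never cross channels. RReLU multiplies negative inputs by a
slope drawn uniformly from [1/8, 1/3] during training and by the mean slope
at evaluation.

The number of filters per block is a free choice; the package defaults to
32/64/64 and exposes it. Every parameter-count invariant of the transfer
heads (301, 306, 15,456) concerns the classifier head only and is
independent of the filter counts.

Training uses Adam, batch 128, cross-entropy, a random 20% validation split
(seeded), checkpointing of the minimum-validation-loss epoch, and optional
early stopping (patience in epochs). Two named schedules exist: constant
learning rate 0.001 for 400 epochs with patience 100, and 0.001 decaying to
5e-7 over 600 epochs without early stopping. A decaying schedule is realized
as exponential per-epoch decay reaching the final value at the last epoch —
the natural reading of a rate "reduced from a to b" when no shape is
prescribed. Batch-norm momentum (0.1) and
epsilon (1e-5) are engine constants recorded here for reproducibility.
Argmax ties break to the lowest class index.

The engine itself is written in R over BLAS-backed matrix operations
(im2col + GEMM convolutions with cached gather indices). All randomness —
initialization, validation split, shuffling, dropout masks, RReLU slopes —
flows through R's RNG, so a seed pins a training run bit-exactly. Frozen
layers are skipped by the optimizer; frozen batch-norm layers also run with
their inference statistics during training, so a frozen stack is a
deterministic feature map. When everything below the earliest trainable
layer is frozen, those activations are computed once per dataset rather
than every epoch — this is what makes the staged fine-tuning schedules
(400 + 300 epochs on a 306- then 15,456-parameter set) cheap.

## Subject transfer: PFCnet

The feature layer is taken to be the flattened output of the last
convolution block — the classifier ("the dense blocks") is what the
construction discards. The target-trained and source-trained extractors are
frozen *except* batch normalization: BN scale/shift stay trainable and BN
inference statistics keep updating during the final stage, which is the
natural reading of "frozen except batch normalization". The new head
mirrors the base head dimensions (300/50), randomly initialized, and is
trained on the target subject's training windows; the validation split is
re-drawn (seeded) for this stage. Source-subject selection supports
all-others (10 sources from an 11-subject roster) and block grouping
(1–15 / 16–30 / 31–40). Data-budget experiments realize fractions by
removing whole repetitions per (class, orientation) cell, never windows.

## Task transfer

**Stage 1 — Syn0net.** A basic-movement network's output activations are
read twice: the more probable of {pronation, supination} fixes the rotation,
the most probable of {pinch, lateral pinch, grip} fixes the function; the
other three basic classes are ignored, and the composed combined class is
returned. The same rule applies to a sigmoid-head variant trained with
per-unit binary cross-entropy. Evaluation reports overall, rotation and
function accuracies against the decomposed true labels.

**Stage 2 — Sia5net.** Two weight-shared branches (the base network up to
its 300-unit representation; the 50-unit and output layers removed) feed an
element-wise L1 distance and a single sigmoid unit: 301 trainable
parameters, everything inherited frozen. Same-class pairs are labeled 0,
different-class pairs 1. Pair generation draws positives uniformly within
class (exact count) and negatives from three categories —
function–function, rotation–rotation, other — with weights 0.4/0.4/0.2 by
default. The emphasis operationalizes the design intent: hand functions
must be separated from each other, rotations from each other, while
rotation-vs-function separation is unimportant because every combined
movement contains one of each. The head trains 100 epochs, batch 32,
learning rate decaying 0.001 → 5e-5. At prediction time each sample is
scored against `q = 5` query windows per combined class; the default rule
averages the scores per class and takes the argmin (0 = same), with a
majority-vote alternative (one vote per query round to the class attaining
the round's minimum). The aggregation formula is a genuinely open design
point, so both modes are exposed as package decisions. Query banks take the
first q windows per class by default,
with a seeded random option.

**Stage 3 — FTnet.** The 8-unit output layer is replaced by a 6-unit
sigmoid layer (50·6 + 6 = 306 parameters), trained alone with per-unit
binary cross-entropy against one-hot targets (the loss pairing is a package
decision; prediction is the sigmoid argmax) for 400 epochs, learning rate
0.01 → 2e-6, batch 128. Stage 2 then additionally unlocks the 50-unit
block — its dense layer (15,050) *and* its batch-norm scale/shift (100),
bringing the trainable set to 15,456 — and fine-tunes 300 epochs at
1e-4.

## Statistical comparison

Accuracy matrices (subjects × methods) are compared with a Friedman rank
test followed by pairwise Wilcoxon signed-rank tests of a reference method
against every other. Wilcoxon uses the exact distribution up to 25 subjects
when ties and zeros permit, otherwise the normal approximation with
continuity correction; zero differences are dropped, and an all-zero
comparison degenerates to p = 1 with a warning. Holm's method is applied as
*threshold adjustment* — sorted ascending, the i-th p-value is tested
against α/(m−i+1) — matching how such tables are usually printed; Holm
adjusted p-values are emitted alongside. The Friedman test is always run
and reported, whether or not the pairwise family follows.

## The synthetic generator

The generator is the package's statistical stand-in for a multi-subject
acquisition, built on the synergy premise. A *synergy bank* assigns each
basic class a sparse non-negative channel-gain row (2–4 strongly activated
channels; banks are redrawn until basic rows correlate below 0.95).
Combined-class rows are derived, not free: the per-channel **maximum** of
the rotation and function rows — superposition without doubling
shared-channel power (an additive mode exists for sensitivity checks).

A recording is amplitude-modulated band-limited Gaussian noise: per channel,
baseline noise of RMS 5 µV (20–450 Hz) runs continuously; during a movement
a trapezoid envelope (250 ms rise/fall) scales a fresh unit-RMS noise
carrier by `subject_gain · orientation_gain · bank[class, channel] · 50 µV`.
Schedules follow the 3 s rest / 2 s preparation / 5 s movement pattern (7 s
for combined movements), with 5 repetitions × 3 hand orientations × 8 basic
classes per subject at the defaults and a 4-repetition sideway combined
protocol. Subjects share the bank but differ by multiplicative log-normal
channel-gain jitter (SD 0.15; orientation jitter SD 0.05) — chosen once so
that subjects are similar enough for transfer to help but not identical.

What this emulates: class structure shared across subjects, per-subject
gain variability, amplitude envelopes, EMG-band spectra, rest baselines,
mains hum (optional), and the superposition structure that makes zero-shot
combined decoding possible. What it does not: motor-unit action potential
trains, electrode-shift and impedance drift, fatigue, within-class
kinematic variability, or cross-talk structure beyond shared channel gains.
Tests passing on this generator therefore validate the *mechanics* of the
pipeline and the *direction* of transfer effects under the synergy model;
they do not certify accuracy levels on real recordings.

## Problem sizes of the bundled experiments

The packaged study harnesses (`subject_transfer_experiment()`,
`task_transfer_experiment()`, `syn0_experiment()`, `siamese_experiment()`)
keep the real channel count (10), sampling rate (2048 Hz) and window
geometry (512/128) but shorten schedules to 0.75 s rest / 0.25 s
preparation / 0.65 s movement (0.9 s combined), use compact convolution
stacks (4/6/6 filters) and 8-epoch base-network schedules. The
subject-transfer study uses 5 subjects (1 target, 4 pooled sources), 4
repetitions per class (2 train, 2 held out — two test repetitions keep the
per-seed accuracy estimate tight), and 10 independent seeds; the
task-transfer studies use 3 basic repetitions (2 train, 1 test), 3 combined
repetitions (1 train, 2 test), and 10 seeds. The staged FTnet schedules run
at their full 400/300 epochs since the frozen prefix makes them
inexpensive. These sizes are the package's choice of a desk-scale study:
small enough to re-run routinely, large enough for the directional effects
to be measured.

## Numerical choices and degenerate inputs

* Sample indices are 0-based with half-open intervals throughout the
  schedule/window arithmetic.
* ms → samples conversions use `floor`.
* Zero-variance windows return 0 for SampEn and Hjorth mobility/complexity,
  with a warning; zero-SD feature columns scale by 1, with a warning.
* Max-pool remainders (e.g. 512 with pool 3) drop the tail, as framework
  pooling does; pool argmax ties take the earliest sample.
* Softmax is computed with the max-subtraction guard; losses clamp
  probabilities at 1e-12.
* The Siamese identical-input score is exactly `sigmoid(bias)`; scores are
  symmetric under input swap by construction.

## Limitations

The CNN engine is plain R: adequate for the compact networks and desk-scale
studies it serves, not for GPU-scale replication of full 400/600-epoch runs
on real multi-subject datasets. Native readers for the public sEMG
databases' distribution formats are out of scope; recordings enter as
delimited text + JSON metadata (or from the simulator), and windows as a
binary array + JSON sidecar. Real-time (causal) filtering and
classification latency are likewise out of scope.
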