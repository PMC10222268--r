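---
title: "Multidomain scalogram fusion for ERP classification: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidomain scalogram fusion for ERP classification: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the method it implements: what
each stage computes, which constants matter and where their defaults come
from, which design points were genuinely open and how they were settled,
and what the synthetic test bed does and does not establish.

## The problem

Event-related potentials (ERPs) are stimulus-locked EEG epochs — here 1 s
epochs of 200 samples at 200 Hz, recorded simultaneously on up to 64
channels. Single trials have poor signal-to-noise ratio, and the
discriminative activity is spread over frequency (which rhythms respond),
time (when they respond) and space (which electrodes see them). The
pipeline classifies single trials and small averages by (1) transforming
each channel's epoch into a Morlet wavelet scalogram, (2) removing or
zeroing the coefficients contaminated by epoch-edge padding (the cone of
influence), (3) fusing channels into one array, and (4) training a small
convolutional network on the fused array.

## Morlet scalograms and the cone of influence

The analytic Morlet wavelet is a complex exponential of frequency
`f0` cycles/sample under a zero-mean Gaussian envelope,
`psi(t) = A exp(-t^2 / (2 sigma^2)) exp(i 2 pi f0 t)`, with `A` chosen so
each sampled daughter wavelet has unit L2 energy (this is enforced
numerically; the test suite checks it to 1e-6). The grid of analysis
bands is geometric: `voices_per_octave` bands per octave descending from
`fmax` (default Nyquist), with `scale = f0 * fs / frequency` samples per
envelope SD. `morlet_cwt()` computes zero-padded "same" convolutions at
every scale, so all bands share the epoch's time axis.

Two conventions deserve comment:

* **Per-band magnitude scaling.** Coefficients are computed against
  unit-energy daughters and then rescaled by `scale^(-1/2)` (the L1-style
  display convention). Under pure L2 normalization a unit sinusoid's
  response *grows* like `sqrt(scale)` toward lower bands, enough to shift
  the band of maximal response one band below the tone's own frequency at
  27 voices/octave; the L1 convention makes a tone's column argmax land on
  its own band, which is the behavior every downstream consumer of the
  scalogram (and every reader of one) expects.

* **The COI rule and its calibration.** A coefficient at time `t` in band
  `f` is treated as accurate when `t` lies at least
  `w(f) = ceiling(e_fold * scale(f))` samples from both epoch edges.
  The reference geometry for this method is a 108-band grid on a
  200-sample epoch whose in-COI coefficients number exactly NV = 17,056.
  Among all integer factorizations `voices x octaves = 108` with band
  ratio exactly `2^(-1/voices)` and `fmax` at (or one voice below)
  Nyquist, exactly one reproduces that count: **27 voices over 4 octaves
  from Nyquist**, with `e_fold` in the narrow interval around **2.0147**
  (about two envelope SDs). Those are the package defaults; they span
  6.4–100 Hz, every band keeps a nonzero in-COI run, and per-band
  durations fall from 192 samples (100 Hz) to 78 (6.4 Hz). The
  conventional `sqrt(2)` e-folding guard remains available through the
  `e_fold` argument; it keeps fewer coefficients. Both `F = 108` and
  `NV = 17,056` are recomputed end-to-end by `scripts/acceptance.R`.

From the masked scalogram the package derives the **Z-scalogram**
(outside-COI cells zeroed, rectangular, CNN-friendly) and the
**V-vector** (the in-COI cells only, concatenated band-major in time
order — the coefficients a "valid" convolution would have produced).

## Channel fusion and the four models

For D rank-ordered channels, `fuse_cuboid()` stacks Z-scalograms into an
F x T x D frequency-time-spatial cuboid and `fuse_matrix()` places
V-vectors as the columns of an NV x D matrix. Fusion is purely
structural — lossless, order-preserving, no rescaling.

All four classifiers share the backbone: two zero-padded "same"
convolution layers of 32 filters with ReLU, a 2 x 2 stride-2 max-pool,
and a three-layer fully connected head (tanh, tanh, softmax) with
dropout 0.15 on the two hidden layers. They differ in their first layers:

| model | input | conv-1 filters | conv-2 filters | head |
|---|---|---|---|---|
| `z_cuboid` | F x T x D | 3 x 3 x D (full depth) | 3 x 3 x 32 | 256, 128, classes |
| `z_matrix` | F x T | 3 x 3 | 3 x 3 x 32 | 128, 64, classes |
| `v_matrix` | NV x D | 3 x 3 over (ft, d) | 3 x 3 x 32 | 256, 128, classes |
| `v_vector` | NV | 9 x 1 column | 3 x 3 over the NV x 32 map | 128, 64, classes |

The cuboid filters intertwine frequency, time and space in one sum; the
`v_matrix` filter slides across both the concatenated frequency-time index
and the channel index; the `v_vector` model's second layer treats the
NV x 32 stack of column feature maps as a single-channel image. Each
convolution layer is verified in the tests against brute-force loop
implementations of its defining sum (tolerance 1e-10), and the backward
pass against central-difference gradients.

Training minimizes cross-entropy with Adam at learning rate 0.001 for a
fixed number of epochs (50 by default), deterministic given the model
seed. The convolution, pooling and optimizer inner loops are implemented
as C++ kernels (RcppArmadillo) behind the R layer graph; the im2col
patch gathers and their transposed scatters share one cached index map,
and BLAS does the filter products. Points the architecture description leaves open, settled here:

* **Batch size** — not specified; default 32, exposed. Mini-batches are
  reshuffled every epoch from the model seed.
* **Dropout placement** — applied to the two hidden fully connected
  layers only; convolution layers are never dropped.
* **Initialization** — fan-in-scaled uniform weights, zero biases,
  redrawn per run so repeated cross-validation runs start from different
  weights.
* **Input normalization** — not specified; default divides all inputs by
  the single scalar `max(abs(training ensemble))`, stored with the model,
  making the pipeline invariant to the recording's amplitude unit. A raw
  mode exists.
* **Odd pooling dimensions** — floor division (trailing row/column
  dropped).
* **Ties in the decision rule** — the maximum-response rule breaks exact
  posterior ties toward the lower class index, for determinism.

## m-subsample averaging

`generate_m_erps()` improves trial SNR by averaging m trials drawn
without replacement: within a round the class's trials are permuted and
partitioned into disjoint groups of m, each group is averaged, leftovers
are discarded, and rounds repeat (reshuffling between rounds) until the
requested count — by convention, as many m-ERPs as there were trials. The
source algorithm does not state whether draws reshuffle between rounds; a
round-based reading was adopted and every group is recorded in a
grouping log (exportable as JSON lines), so each emitted m-ERP can be
re-derived bit-exactly — the tests do exactly that. Averaging empirically
raises SNR like sqrt(m) on the synthetic generator, the premise the m
parameter rests on.

**Leakage.** Whether m-ERPs were generated before or after the
train/test split is not stated in the protocol this follows. The default
here generates m-ERPs separately inside each cross-validation partition,
so no single trial ever contributes to both a training and a test
average; the `leakage = "pool"` mode reproduces the average-then-split
alternative for comparison.

## Cross-validation protocols

*Customized* (BCI-style): stratified k-fold over one subject's m-ERPs,
k = 5 in the reference protocol (stratification is assumed; the protocol
does not state it). Every m-ERP is tested exactly once per run; with 195
m-ERPs per class, two classes and 50 runs this yields the reference
accounting of 19,500 tested per subject, which the accounting tests
reproduce against a trivial constant classifier.

*Group-based* (clinical-style): folds partition subjects (`k-subject-fold`);
training never sees any test subject's data, and k = B gives
leave-one-subject-out. Subject-to-fold assignment reshuffles between
runs when k < B. Each run reseeds weights and subsample groupings.

Accuracies are percentages: per subject, 100 x correct / tested pooled
over folds and runs; group figures are means over subjects.

## Channel ranking

Channels are scored per subject on their V-vector features — by default
the cross-validated accuracy of a nearest-class-centroid classifier on
the single channel (one shared fold split across channels, so a channel's
score depends only on its data), or a faster Fisher discriminant ratio.
Subject rankings (rank 1 = best, ties to the lower index) are aggregated
by **rank-of-rank-sum**: sum the per-subject ranks channel-wise and rank
the sums. The scoring criterion behind the reference rankings is defined
elsewhere and not restated; both scores here recover planted
discriminative channels on the simulator, which is what the package's
tests require of them.

## The synthetic test bed

`simulate_group()` emulates the structure the method assumes: each trial
is class-specific Gaussian-windowed sinusoidal bursts on designated
channels, plus 1/f background noise (spectrally shaped white noise,
exponent 1), plus a shared 10 Hz rhythm with random phase that correlates
channels within a trial. Subject-level effects — lognormal amplitude
jitter, Gaussian latency jitter, and a Gaussian burst-frequency offset
(the individual-rhythm-frequency analog) — make subjects genuinely
different, which is what gives the customized/group comparison content.
The default configuration mirrors the reference study's shape: 5
subjects, 64 channels, 195 trials per class, 2 classes, 200 samples at
200 Hz.

Three fixed-seed fixtures scale this down for testing (8 channels, 40
trials/class, 64 samples at 64 Hz). The `medium` fixture implements the
complementary-information regime deliberately: the class difference (a 6
vs 9 Hz burst) lives on channels 1–4, but each trial expresses it on a
random 2 of the 4. A single channel therefore sees the class difference
on only half the trials (unichannel Bayes ceiling ~75%), while the
4-channel ensemble sees it on every trial — so the advantage of fusion
over the best unichannel classifier is structural, not an artifact of one
training run. The `hard` fixture halves the burst amplitude; `easy`
plants strong bursts on channels 2 and 5 only.

What the simulator does **not** model: volume conduction and realistic
scalp topographies (channel correlation comes only from the shared
rhythm), artifacts (blinks, EMG), non-stationary noise, and overlapping
stimulus responses. Passing trends on this generator show the pipeline
orders conditions correctly when its assumptions hold; they do not
predict absolute accuracies on real EEG.

## The scaled-down trend experiment

`trend_experiment()` reruns the method's three headline comparisons on
the medium fixture at desk scale: 16-band grid (4 voices x 4 octaves),
3-fold single-run CV, 12 training epochs, cuboid/matrix models at D = 4
against the two best unichannel candidates (picked by the Fisher
criterion), m in {1, 2, 4}, and leave-one-subject-out against customized
training, averaged over 5 simulation seeds. These sizes are the package's
chosen compromise between statistical stability of the trend means and
keeping the whole experiment in the minutes range on one core; they are
asserted with a 2-point tolerance on seed means. Scaling any of them up
(more folds, more epochs, the 108-band grid) sharpens the same
comparisons.

## Known limitations

* The full-size `v_vector`/`v_matrix` models at NV = 17,056 imply a
  first dense layer of several hundred million parameters (inherent in
  the architecture's flatten-into-256/128 head at that input size);
  training them is memory- and compute-heavy in any framework and is not
  exercised by the test suite, which uses coarser grids.
* EDF/EEGLAB import is not provided; epochs enter through the RDS or
  plain-text container (`read_epochs()`).
* The CWT is not invertible here and no time-frequency statistics beyond
  the magnitude scalogram are computed.
* Morse and Bump wavelets, output-level (decision) fusion, and
  temporospatial PCA channel selection are out of scope.
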