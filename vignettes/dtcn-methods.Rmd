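---
title: "Deep temporal convolution networks: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep temporal convolution networks: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcn)
```

## The problem

Physiological signals — EEG, accelerometer and gyroscope traces — are
nonstationary, nonlinear and noisy, and their class structure (an eye
state, an activity) lives in temporal patterns spanning many samples.  A
static classifier sees such a signal through the time-delay
representation: overlapping windows of `w` lag observations per channel.
That gives the *input* layer temporal context, but in an ordinary deep
network the deeper layers never see any: each hidden representation
describes one window in isolation.  The DTCN's premise is that the
compositional locality of a time series should be exploited at *every*
level, so each deeper layer sees the joined representations of several
consecutive windows.

## Model

With hidden widths `n_1, …, n_L`, time steps `TS` and `K` classes, a
mini-batch of `B` time-ordered data vectors flows as follows.  The first
connection (`w·C × n_1`) consumes the raw windows — the time-delay
representation already encodes input-level context, so there is no
concatenation at the input.  After every hidden layer's sigmoid
activation, a concatenation sublayer joins each group of `TS` consecutive
rows into one row of width `TS·n_i`; the next connection attaches there.
Every concatenation removes `TS − 1` rows, so `B − L(TS − 1)` instances
survive to the row-wise softmax.  Each concatenation is placed after
*every* hidden layer, including the last: this is the only placement
consistent with near-equal complexity of the matched plain networks (6 160
weights for the `224-20-20-20-2` DTCN at `TS = 2` against 6 181 for the
plain `224-23-23-20-2`), and it gives the final classifier the widest
receptive field.

Concatenation is weight sharing: all rows entering a sublayer were
produced by the same connection.  It is also not differentiable, which
shapes the training algorithm below.

### Label-count pooling

Each data vector carries the per-class count of the sample labels inside
its window (summing to `w`), never a voted label.  Each concatenation
pools counts by the same sliding sum, so a surviving terminal row carries
the full class composition of its receptive field and the majority vote
happens exactly once, at the final classifier.  Voting early would
repeatedly summarize away minority classes and distort the class
distribution the deeper layers see.  Ties are broken uniformly at random
by a dedicated seeded generator.

## Data preparation

Two sliding windows are involved.  The first creates data vectors
(defaults `w = 16`, `s = 8`, i.e. 50 % overlap; vectors are flattened
channel-major, all `w` lags of channel 1 first — the layout is arbitrary
because the first connection is dense, but it is fixed for
reproducibility).  The second slides over the data-vector sequence to make
mini-batches of `B = 18` vectors with stride `B/2` (again 50 % overlap;
the batch-level stride is a package choice mirroring the window-level
overlap).  Windows and batches use 0-based, half-open coordinates, and
tails that do not fill a window or batch are dropped rather than padded.

Mini-batches preserve natural time order internally — concatenation is
meaningless otherwise — while whole batches are shuffled (deterministically
from the seed, and afresh every epoch) so the network cannot exploit the
long-range order of the label sequence.  Within one batch the overlap
makes individual vectors contribute unequally (up to `ceil(B/stride)`
repetitions); over the whole batch sequence the contributions even out.

Standardization is per feature, with statistics estimated from training
batches only and re-estimated inside every cross-validation fold;
zero-variance features pass through unchanged.

## Training

**Pretraining.**  The connections are trained greedily, bottom-up, as a
stack of RBMs by CD-k (default CD-1): connection 1 as a gaussian-visible
RBM on the standardized input (gaussian visibles assume unit-variance
inputs, which standardization provides), each deeper connection as a
bernoulli-visible RBM whose visible layer is the previous concatenation
sublayer.  Propagation between stages uses mean-field probabilities, not
samples, the common DBN practice.  Labels and the softmax connection are
never involved.  Defaults (10 epochs, learning rate 0.05) were fixed on
synthetic data by watching reconstruction error trends.

**Fine-tuning.**  Plain mini-batch gradient descent with classical
momentum on the softmax cross-entropy; targets are hard one-hot majority
votes of the terminal pooled counts (count-proportional soft targets are
available behind `soft_targets = TRUE`).  The backward pass alternates
three steps: multiply the delta by the upper connection's weights; route
the result across the concatenation sublayer by split-slide-add (split the
error table into `TS` column blocks of width `n_i`, slide block `j` down
by `j` rows, add overlaps); multiply elementwise by the sigmoid
derivative.  Routing is the exact linear adjoint of concatenation — the
package asserts the inner-product identity
`⟨concat(A), G⟩ = ⟨A, route(G)⟩` and full-network agreement with central
finite differences to relative error below `1e-5` — and it conserves the
total delta, so the non-differentiable sublayer adds no parameters and no
gradient mass is lost.

### Numerical choices

Softmax rows are computed with max-subtraction; cross-entropy probabilities
are clipped at `1e-12`; a non-finite loss raises an error naming the
learning rate as the usual culprit.  Weights initialise as
`N(0, 1/fan_in)`; biases start at zero.  The defaults `lr = 0.05`,
`momentum = 0.9`, 60 epochs were chosen for robustness: with sigmoid
hidden layers and momentum this close to 1, effective step sizes a few
times larger can drive individual runs into saturated configurations from
which gradient descent does not recover, and the failure is triggered by
the (seeded) batch order, so a schedule that is stable across shuffle
orders was preferred over the fastest one.

## The synthetic generator

`generate_series()` emulates the structure the DTCN targets: a `K`-state
latent Markov chain with geometric dwell times (memoryless switching,
mean `mean_dwell` samples — the default 300 makes regimes span many
windows) drives, per class and channel, an AR(2) regime with a distinct
dominant frequency in 0.10–0.35 cycles/sample (periods of 3–10 samples,
visible inside short windows), a distinct channel gain in `[0.6, 1.4]`
and a small baseline offset in `[-0.4, 0.4]` — spectral, amplitude and DC
signatures all accompany regime changes in real physiological recordings.
Regime coefficients blend linearly over 5 samples after each switch to
avoid discontinuities.  Channels are scaled to unit power and white
gaussian noise of power `1/snr` is added (default `snr = 4`).

What the generator does *not* emulate: volume conduction and channel
correlation, artifacts (blinks, motion), 1/f background spectra,
non-geometric dwell distributions, and label noise.  Tests passing on
this generator therefore demonstrate that the machinery works and that
temporal context is exploitable when it exists; they do not certify
performance on any particular recording system.

## Experiments at desk scale

`crossval()` forms contiguous blocks of the mini-batch sequence as folds
(fixed before shuffling, so no batch spans the train/test boundary) and
refits the entire pipeline per fold.  Accuracy is the fraction of
surviving terminal rows whose arg-max prediction equals their voted
target — the denominator choice is the package's own, made explicit
because surviving rows differ across `TS`.  `ts_sweep()` repeats the run
over `TS` values and adds complexity-matched plain baselines constructed
by `equivalent_dbn_config()`, which widens all hidden layers but the last
until the weights-only count is closest to the DTCN's (ties to the
smaller network).  Bias parameters exist but are excluded from the
complexity metric; that convention is what reproduces the matched totals
of 6 181 and 8 565 exactly.

The package's standing generalization check runs 3-fold cross-validation
on ten 9 000-sample, 6-channel records (dwell 300, snr 4) and compares
`TS = 2` with `TS = 1` pairwise per seed; `TS = 2` wins in at least 8 of
10 seeds.  Problem sizes here — and in all tests — were chosen as the
smallest at which the compared quantities separate cleanly from their
seed-to-seed variability.

## Known limitations and open choices

* Hidden activations are sigmoid throughout, for compatibility with
  bernoulli RBM pretraining; ReLU would require a different pretraining
  story.
* The optimizer is deliberately plain (SGD + momentum); no adaptive
  methods.
* Pretraining at desk scale helps when fine-tuning is brief and capacity
  moderate, and is neutral to mildly unhelpful when fine-tuning runs long
  enough to fit the training batches fully — consistent with its
  historical role as an initialization aid.  It is kept on by default as
  part of the canonical pipeline.
* Whether the softmax connection should consume the concatenated or the
  plain last hidden layer is ambiguous from complexity figures alone; the
  implementation concatenates everywhere, the reading most consistent
  with "after each hidden layer" and with the matched totals.
* Outlier removal and resampling of non-uniform series are out of scope;
  inputs are assumed uniformly sampled and clean.
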