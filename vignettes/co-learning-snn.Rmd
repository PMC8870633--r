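---
title: "Cluster-grouped spiking networks with structural and synaptic co-learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-grouped spiking networks with structural and synaptic co-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnclust)
```

## The model

`snnclust` classifies 28×28 grayscale digits with an ensemble of
homogeneous spiking clusters. The pipeline has four stages, each exposed as
ordinary functions and wrapped by the fitting interface `snn_fit()`.

### Spiking encoding

An image is convolved (valid cross-correlation, stride 1) with four fixed
oriented kernels — transverse, longitudinal and the two diagonals — and each
raw map is max-pooled with non-overlapping windows, incomplete borders
dropped. With kernel side $k$ and pool side $p$ each map has side
$\lfloor (29-k)/p \rfloor$; the default $k=4$, $p=2$ gives four 12×12 maps,
i.e. 576 input channels per cluster.

The pooled values are jointly min–max rescaled to $[0,255]$ and converted to
spike *latencies*: stronger features fire earlier (rank-order coding). The
linear coder assigns the raw delay $T = 255 - V$; the exponential, inverse
and power coders ($255/2^{V/32}$, $255/\max(V,1)$, $255/\max(V,1)^2$) are
provided as drop-in alternatives, all non-increasing in $V$. Raw delays in
encoding units are rescaled linearly onto the simulation window
(`window_ms`, default 100 ms), and a channel of rescaled intensity 0 emits
no spike, so every channel carries at most one event.

Two encoder choices deserve comment:

- **Kernel weights.** Within each kernel the oriented band carries equal
  weights summing to 1. With unnormalised bands the horizontal/vertical
  kernels (a 2×4 band at size 4) respond twice as strongly as the diagonals
  (4 cells) to the same ink, and a *uniform* image would produce apparently
  oriented features after the joint rescale. Unit-sum bands make the four
  orientations commensurate; the overall scale is irrelevant because of the
  rescaling.
- **Contrast cut.** Rescaled intensities below `contrast_cut` (default 0.2)
  of the per-image maximum are silenced. Oriented-band convolution of
  stroke images is strongly bimodal — in-band ink versus background — and
  the weak tail is background texture. Without the cut, pixel noise makes
  essentially every channel fire on every image, which defeats the
  event-driven, sparse regime latency coding is designed for (a
  dark-background digit image has intensity exactly 0 over most of the
  field, and its encodings are naturally sparse). Set `contrast_cut = 0`
  to disable.

### LIF cluster dynamics

Each cluster connects its input channels fully to one decode neuron per
class. Decode neurons are leaky integrate-and-fire units integrated on a
fixed clock (exponential-Euler: exact leak toward `v_rest` with time
constant `tau_m`, input current held constant over a step of `dt`). An
input event injects the synaptic weight into an exponentially decaying
current (`psc_tau`). Threshold crossing records a spike, resets the
membrane to `v_reset` and opens an absolute refractory period `t_ref`
during which the potential is clamped and inputs are ignored.

Defaults (all in `snn_config()$lif`, standard cortical textbook values):
`tau_m` 10 ms, `v_rest` −65 mV, `v_thresh` −50 mV, `v_reset` −70 mV,
`t_ref` 2 ms, `psc_tau` 2 ms, `dt` 0.1 ms. The inner loop is compiled
(Rcpp); `step_lif()` is the reference R implementation of the same update,
and the tests check the two against each other and against the closed-form
subthreshold solution.

The input relay is pass-through: encoded events drive the decode synapses
directly, with no dynamics or learning of their own, since nothing in the
architecture calls for main-layer spiking state.

### Bipolar supervised learning

Training one cluster on a labelled spike train is an inner loop:

1. simulate teacher-free; collect the fired set $M$;
2. if $M = \{L\}$ (label neuron only) stop;
3. otherwise inject teachers — one *encouraging* pulse at 70 ms for $L$
   (always, even when $L$ is silent: the forced spike is the only mechanism
   that can potentiate a silent label neuron) and one *punishing* pulse at
   35 ms per wrongly fired neuron — re-simulate, and update weights.

Teacher pulses are current injections into a separate accumulator that is
cleared when the neuron spikes: the encouraging magnitude (3000 current
units) depolarises ~30 mV in a single step, forcing exactly one spike at
the injection time; the punishing pulse is the same magnitude
hyperpolarising, which silences the neuron from its injection time to
roughly the end of the window.

Weight updates are all-pairs additive STDP
($+a_+ e^{-\Delta t/\tau_+}$ causal, $-a_- e^{-\Delta t/\tau_-}$
anti-causal) with two deliberate credit-assignment rules:

- **Encouraged neuron:** the update is computed against the
  *teacher-forced* spike(s) only — post spikes at or after the encourage
  time. Using all of the neuron's spikes instead lets its own early firing
  dominate the pairing (Hebbian self-amplification plus anti-causal
  depression around the early spike); in development that variant made
  accuracy *fall* as training was prolonged, while the forced-spike rule
  improves monotonically with training scale.
- **Punished neuron:** the depression is
  $-\texttt{punish\_scale}\cdot|\Delta w|$ computed against the neuron's
  *natural* (teacher-free) spikes — the very firing that put it in $M$. The
  teacher-run record cannot be used here: the hyperpolarizing pulse
  silences the neuron during that run, so depression computed against it
  is identically zero and the loop deadlocks (wrong neuron silent under
  punishment, still firing without it, no weight ever changing).

Weights are clipped to $[w_\min, w_\max]$ and pruned synapses are never
updated. STDP constants (`a_plus` 0.5, `a_minus` 0.25,
`tau_plus = tau_minus` 20 ms, bounds $[0, 50]$, initial weights uniform on
$[0,5]$) are exposed in configuration; they are standard pair-based ranges,
chosen once — the upstream experiments they emulate do not publish theirs.
The loop is capped at `max_inner_iters` (50) rounds per sample;
non-convergence is recorded as an outcome, not an error.

### Structural learning and the ensemble

After a cluster finishes training, synapses with
$|W - W_{\text{init}}| < w_{\text{change}}$ (strict) are eliminated:
weights that never moved took no part in learning. `W_init` is the
construction-time snapshot and is never refreshed, pruning only clears the
alive mask (weights are untouched), so pruning is idempotent, monotone in
the threshold, and exactly equivalent to zeroing the weight as far as
simulation is concerned. Note the threshold is in *this package's* weight
units: with initial weights on $[0,5]$ and potentiation quanta of order
0.03–0.5, thresholds around 0.01–0.1 remove only inactive synapses, while
thresholds of order 1 (meaningful in other unit systems) would remove the
signal carriers themselves. `prune_sweep()` reports the
accuracy/sparsity trade-off over a threshold grid.

The ensemble trains `clusters` (default 15) structurally identical clusters,
each on its own bootstrap subset (`subset_size` draws with replacement,
default 1000) for `iterations` passes (default 3). Per-cluster RNG streams
are derived sub-seeds, so results are independent of the order in which
clusters are processed, and the seed list is prefix-stable (adding clusters
leaves existing ones unchanged). Decoding is teacher-free: output class $j$
accumulates the spike counts of every cluster's decode neuron $j$, and the
prediction is the argmax with ties broken by earliest first spike, then
lowest label; an all-silent network falls back to label 0 and is flagged
`no_spike`. The accumulator readout was chosen over a second LIF layer
because nothing constrains such a layer's dynamics or weights, while the
count accumulator is deterministic and exactly testable.

## The synthetic data generator

`synth_digits()` renders each class from a fixed stroke template — thick
horizontal, vertical and diagonal strokes at positions and slopes of its
own — then applies an integer translation jitter (±2 px) and clipped
Gaussian pixel noise (sd 8 intensity units), deterministically per seed.
It emulates what digit encoders actually rely on: bright oriented strokes
on a dark 28×28 field, ten discriminable classes.

Template design matters more than it looks: an early draft used
seven-segment glyphs, under which several classes were strict subsets of
others at the channel level (the "1" segments are contained in "0", and
everything is contained in "8"). A subset class is *undecodable* by any
monotone readout with non-negative weights — activating a superset's
channels can only add drive — so the generator guarantees by construction
that every ordered pair of classes keeps a private share of encoded
channels (≥5% is asserted in the tests; the shipped templates give ≥11%).

What the generator does not emulate: stroke curvature and width variation,
writer-style diversity, elastic distortion, and grey ink levels. Passing
the packaged tests therefore demonstrates that the co-learning mechanism
works on sparse latency-coded oriented features, not that it reaches any
particular accuracy on real handwriting; the CLI accepts user-supplied
IDX files for that purpose.

`separable_spike_set()` is the sharper instrument: classes occupy disjoint
channel blocks with spike times in the 40–65 ms band, where the 70 ms
encouraging teacher's causal window gives appreciable potentiation. On it,
a correct implementation must reach 100% teacher-free training accuracy —
and does, which the acceptance tests assert.

## Numerical choices and degenerate inputs

- `window_ms = 100` with delays rescaled from encoding units: the window
  must extend past the 70 ms teacher, and 100 ms keeps simulations short. A
  255 ms window (raw delays read as milliseconds) was evaluated and
  performed no better at 2.5× the cost.
- Events and teacher pulses are binned to the step containing their time;
  a teacher pulse therefore forces its spike within one `dt` of the nominal
  time. Spike times are reported at the step start and always lie in
  `[0, window_ms)`.
- Convolution is cross-correlation (no kernel flip); the oriented kernels
  are symmetric enough that this is bookkeeping, stated for
  reproducibility.
- Degenerate inputs: a constant image encodes to an empty train; an empty
  train with no teachers fires nothing; `stdp_delta` of empty spike lists
  is 0; simultaneous pre/post spikes count as anti-causal.
- Ties in decoding are broken deterministically (earliest first spike, then
  lowest label) so evaluation is reproducible bit-for-bit.

## Problem sizes used by the packaged checks

The test suite trains single clusters on constructed fixtures (tens of
samples, ≤576 channels) and one three-cluster ensemble on 1,000 synthetic
digits with the default subset size (1000) and passes (3), evaluated on 200
held-out digits — about 75% accuracy against a 10% chance level, in well
under a minute. These sizes exercise every code path at a scale a laptop
reproduces comfortably; ensembles of 15 clusters on larger sets are a
matter of the same functions and more minutes, not different code.

## Known limitations

- The punishing pulse suppresses firing only from its injection time
  (35 ms); a wrong neuron whose spikes all precede it is corrected by the
  anti-STDP depression alone.
- Pruning thresholds are not transferable across weight-unit conventions
  (see above); compare proportions of synapses removed, not raw thresholds.
- The main layer is a pass-through relay; architectures requiring hidden
  spiking dynamics are out of scope.
- Accuracy on real handwritten digits depends on neuron and plasticity
  constants that the package exposes but cannot tune automatically.
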