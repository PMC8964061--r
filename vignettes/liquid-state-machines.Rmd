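---
title: "Liquid State Machines: model, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liquid State Machines: model, training and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidstate)
```

## The model

A Liquid State Machine is a three-layer spiking network with Elman-style
connectivity: `N` input channels fully connected to a *liquid* of `M`
recurrently connected leaky integrate-and-fire (LIF) neurons, read out by
`C` output neurons (one per class) with the same dynamics but no lateral
connections and no feedback into the liquid. The liquid's weights are
random and frozen; only the hidden-to-readout matrix is trained. The
liquid acts as a fixed nonlinear temporal kernel: it mixes the input's
history into a high-dimensional spiking state in which a simple readout
can separate classes that are not separable from instantaneous (or
time-summed) input statistics.

### Membrane dynamics

Every neuron follows the same discrete-time update with the reset folded
into a multiplicative factor:

$$u_j[k] = u_j[k-1]\, d\, (1 - \theta_j[k]) + g\, I_j[k], \qquad
  \theta_j[k] = \mathbf{1}\{u_j[k-1] \ge u_\mathrm{th}\}, \qquad
  d = e^{-\Delta t/\tau_m}.$$

Conventions, fixed once and used everywhere:

* **Spike timing.** The spike recorded at step `k` announces a threshold
  crossing of the membrane at step `k-1`. Consequently a network started
  from rest is always silent at step 1, and spikes at step `k` depend only
  on inputs before `k` — the synaptic delay equals the simulation
  resolution. Zero-delay (within-step) propagation is deliberately not
  implemented.
* **Threshold comparison is inclusive** (`>=`).
* **Reset.** When `theta = 1` the decayed history term is zeroed, so the
  membrane restarts from the reset potential (0) plus the incoming
  current. This factored form is algebraically identical to the piecewise
  "reset to `u_reset`" formulation when `u_reset = u_rest = 0`.
* **Initial state** is the resting potential; no refractory period is
  modelled.
* **Gain.** The current enters through a dimensionless gain `g`
  (`neuron_params(gain = ...)`, default 1). In physical units this absorbs
  the `dt / c_m` factor of a capacitance-based formulation; in normalized
  units it is the one free knob that sets the liquid's operating point
  (below).

Defaults reproduce the standard parameterization for 1 ms resolution:
`u_rest = u_reset = 0`, `u_th = 0.3`, `tau_m = 9.4912` ms, hence a decay
of `d = 0.9` per step.

### Weights

`W_ih` (M×N) and `W_hh` (M×M, all-to-all including the diagonal — nothing
in the model requires excluding self-connections) are i.i.d. uniform on
`[-1/N, 1/N]` and never change after construction; tests assert bitwise
equality across training. The readout matrix is initialized uniform on
`[-1/M, 1/M]` by analogy with the reservoir rule; since it is trained, the
initialization only needs to give a live (neither silent nor saturated)
readout at the operating point. No layer has bias terms.

## The operating point: why `gain = 16` in the study

With weights bounded by `1/N`, the per-step current into a hidden neuron
has standard deviation about $g\sqrt{n_a}/(N\sqrt{3})$ when $n_a$ input
channels are active. For the study's `N = 512` and typical $n_a \approx
30$–50, a gain of 1 yields membrane fluctuations of a few thousandths of
the 0.3 threshold: the liquid would be silent and the readout would have
nothing to learn from. The packaged benchmark therefore drives the liquid
at `gain = 16`, chosen by calibrating the *liquid firing rate* (not
accuracy): it yields sparse activity (~7% of neuron-steps) and an
effective recurrent spectral radius $\rho(g\,W_{hh}) \approx 0.29$, well
inside the echo-state (fading-memory) regime. The gain is shared by hidden
and readout neurons; the trained readout weights absorb it.

## Training the readout (STBP)

The loss is the squared distance between a sample's one-hot label and its
readout firing-rate vector, averaged over samples
(`rate_loss()`): driving the correct readout neuron towards firing on
every step of the window and the others towards silence. Training unrolls
the readout membrane recursion over the `T`-step window and backpropagates
through time with two standard surrogate-gradient conventions:

* the spike nonlinearity's derivative is replaced by a rectangular window
  of unit area, $(1/a)\,\mathbf{1}\{|u - u_\mathrm{th}| < a/2\}$, default
  `a = 1` in threshold units;
* the reset factor `(1 - theta)` is treated as a constant during
  differentiation.

Because the liquid is frozen, hidden spike trains are constants of the
optimization: they are computed once per dataset and reused across all
epochs, no gradient or optimizer state ever exists for `W_ih`/`W_hh`, and
the per-epoch cost is only the (tiny) readout recursion. Readout membrane
state is reset at every sample boundary during training, matching the
independent-sample structure of the loss. The implementation is verified
against an independently written forward-mode unrolling of the chain rule
to below 1e-10 relative error (`test-train.R`, `test-acceptance.R`).

**Optimizer.** Plain minibatch SGD (batch 64, 20 epochs) with learning
rate `1e-3`; Adam is available. The rate was chosen for stability of the
spiking readout: much larger steps push readout membranes far outside the
surrogate window, where the gradient dies and training locks into
all-silent (loss 1) or all-firing fixed points. All of this is
configurable via `train_config()`.

## Event data and binning

Events follow the 5-byte N-MNIST AER dialect (x, y, polarity bit plus
23-bit microsecond timestamp); the codec is bit-exact under round-trip.
Binning divides `[0, window)` into `T` half-open bins; a raster cell is 1
iff at least one event of that (polarity, row, column) channel fell into
the bin — one spike per timestep per channel, matching a binary-input LIF
— with a count-preserving mode for diagnostics. Channels are flattened
polarity-major, then row-major, 0-based. Events at `t >= window` are
dropped and counted, never silently lost.

Recordings of a few hundred ms must be mapped onto a short simulation
window. Both options are provided (`rasters_from_streams(time_mode=)`):
**compress** (default) bins the full recording into `T` steps, using every
event at coarser effective time resolution; **truncate** keeps the first
`T * dt` ms at native resolution. The study compresses 300 ms recordings
into `T = 25` bins so each raster spans exactly the 25 ms stimulus window
of the streaming schedule.

## The synthetic benchmark

`synth_generate()` emulates the statistical shape of saccade-recorded
event data on a small grid: class `c` sweeps a one-pixel-wide front
across a 16×16 grid along direction $2\pi (c-1)/C$; a pixel emits ON
events (Poisson, 0.5 events/ms) while covered and OFF events for an equal
span after the front leaves, with 5 ms Gaussian timing jitter per pixel,
over uniform background noise (0.005 events/ms per pixel per polarity).
Each 300 ms recording carries ~5,000 events, comparable to real
event-camera digits. The defaults (4 classes, 100 samples per class,
seeded) are the package's reference conditions.

The task is deliberately *purely temporal*: every class activates every
pixel exactly once, so time-summed input statistics are identical across
classes (a multinomial probe on summed input counts performs at chance).
Class information exists only in the order in which pixels fire — exactly
what a liquid with ~10 ms membrane memory can convert into separable
instantaneous states. What the generator does **not** emulate: realistic
DVS noise correlations, per-pixel threshold mismatch, hot pixels,
polarity imbalance, or the visual structure of natural scenes. Passing
the benchmark therefore demonstrates that the pipeline trains and
classifies genuinely spatio-temporal spike patterns; it does not certify
accuracy figures on any real event-camera dataset.

Study problem sizes: liquids of 64, 128 and 256 neurons, 400 training and
200 test recordings, 25-step windows — small enough that the full
benchmark (data generation, three trainings, quantization and streaming
comparisons) completes in well under a minute on one CPU, while large
enough that test accuracy (97–100%) and its growth with liquid size are
stable across seeds.

## Quantization

Reservoir weights are quantized to a symmetric uniform lattice,
$w_q = \Delta \cdot \mathrm{round}(w/\Delta)$ with
$\Delta = s\,2^{1-b}$ and `s` fitted per matrix (default: max |w|;
percentile fitting available). This gives at most $2^b + 1$ levels
including zero across $[-s, s]$ and rounding error at most $\Delta/2$
there. Rounding is ties-to-even for bit-exact reproducibility; values
outside $[-s,s]$ are lattice-rounded, not clipped. A naive reading of the
"scale times round(w·2^b/s)" recipe would inflate magnitudes by $2^b$;
the implemented form preserves magnitudes, which is what lets the
quantized liquid keep functioning. At `b = 1` the lattice still contains
`{-s, 0, s}`; a strict two-level binarization (`mode = "sign"`,
$s\,\mathrm{sign}(w)$) is provided as the alternative reading of
"binarized" weights. The readout is never quantized, and because the
reservoir is frozen, quantize-before-training and quantize-after-training
are literally identical.

## Streaming inference

Batch inference zeroes all state between samples. Streaming inference
feeds samples back to back — membrane state persists — with each period
split into a 25 ms stimulus and a 25 ms relaxation. A recurrent liquid
keeps reverberating after its input stops, so the relaxation alone is not
enough; a rhythmic inhibitory pulse (default −10 membrane units, i.e.
~33 thresholds, injected into every hidden neuron on the first relaxation
step) quenches that activity. The pulse is implemented as a scheduled
current injection: a one-neuron inhibitory population firing at fixed
intervals is behaviourally identical and this form is exactly testable.
Three consequences worth knowing:

* Classification counts only readout spikes inside each sample's stimulus
  window, never the relaxation.
* The readout is not inhibited (the inhibitory population targets the
  liquid only); readout membranes decay by $0.9^{25} \approx 0.07$ across
  the relaxation.
* The pulse leaves a residual hyperpolarization of
  $|w_\mathrm{inh}|\,0.9^{25} \approx 0.7$ units at the next stimulus
  onset, which can suppress a handful of early spikes; agreement with
  batch predictions is ≥95% (typically 100%) on the benchmark, and
  with inhibition off but the same schedule, relaxation-window liquid
  activity is strictly higher. In the limit of overwhelming inhibition
  and long relaxation, streaming predictions equal batch predictions
  exactly (tested).

Degenerate predictions are flagged rather than hidden: ties break to the
lowest class index and an all-silent readout sets `silent = TRUE`.

## Numerical and degenerate-input choices

* All randomness (weights, generator, minibatch order) flows through
  locally scoped seeds; every fitted object is a pure function of its
  inputs and seeds, and rollouts are bitwise reproducible.
* `free_decay_trace()` iterates multiplication in the simulator's
  arithmetic order rather than using `d^k`, so closed-form and simulated
  traces agree bit for bit.
* An all-zero weight matrix quantizes to the zero map and is flagged
  degenerate instead of erroring.
* Empty training sets, shape mismatches and truncated AER records raise
  immediate errors naming the problem (the AER error reports the byte
  offset).

## Limitations

* The package targets method-scale experiments; it simulates dense
  liquids with BLAS matrix products and is not a sparse/neuromorphic
  runtime. Liquids beyond a few thousand neurons will be slow.
* Only the readout is trainable by design; there is no reservoir
  plasticity, architecture search, or online learning.
* Conductance synapses, refractory periods, axonal delay distributions
  and sub-millisecond integration are out of scope.
* The AER reader speaks one dialect (the 5-byte N-MNIST format); other
  event-file families are not parsed.
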