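---
title: "A polychronous spiking-network memory with programmable axonal delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A polychronous spiking-network memory with programmable axonal delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polychron)
```

## The model

`polychron` simulates a memory for spatio-temporal spike patterns built from
two populations that talk over an address-event bus:

* **Axon modules** are the storage elements.  Each module latches, once, one
  *input* neuron address, four *output* addresses, and four programmable
  conduction delays (one per output path).  When a post-synaptic spike with
  the module's input address appears on the bus, the module's ramp counter
  restarts from zero; each delay path emits a pre-synaptic spike in the tick
  in which the ramp reaches its programmed delay.  The ramp is a 9-bit
  counter: it saturates at 511 ticks and stops.
* **Neurons** are pure coincidence detectors with four synapse lines.  A
  pre-synaptic spike starts a 1 ms timer on its line (spikes on an
  already-running line, or during the refractory period, are ignored).  When
  three of the four timers are simultaneously active the neuron fires, then
  stays refractory for 1 ms.  There are no membrane potentials or weights.

One tick — the sole clock of the model — is the axon-array update period of
62 µs; the 1 ms window and refractory period are 16 ticks, and the 9-bit
delay ceiling is 511 ticks ≈ 32 ms.

A pattern is stored by writing its inter-spike structure into delays: the
module consumed by spike *k* connects the neuron of spike *k* to the neurons
of spikes *k*+1…*k*+4, with delays equal to the corresponding tick spans.
Cueing the first four spikes then regenerates the rest of the pattern: the
four paths converging on each later spike's neuron deliver simultaneous
arrivals at exactly its trained tick, three of which suffice to fire it.
This time-locked chain is the polychronous mechanism.

## Timing semantics

Two discrete-time choices matter, and both are forced by requiring that a
stored pattern recalls *time-locked*:

* **A delay path emits when the ramp reaches the latched delay.**  During
  training the latched value is the ramp count at the moment the output
  spike arrives, so emitting on reaching (not strictly exceeding) that count
  reproduces the trained arrival time exactly.  A one-tick-late convention
  compounds: every recall generation adds a tick, and the error grows
  without bound along the pattern.
* **A neuron fires in the tick its coincidence is detected.**  The
  biological integration latency that the hardware emulates — the sum of the
  synapse-timer values when the third spike arrives, exposed here as
  `integration_delay()` — is counted by a delay stage running at the system
  clock, orders of magnitude below the tick resolution, so at the 62 µs
  scale it rounds to zero whole ticks.  Treating it as whole ticks instead
  would *amplify* arrival dispersion (a neuron receiving arrivals at offsets
  $e_1 \le e_2 \le e_3$ would fire at $3e_3 - e_1 - e_2$), and recall would
  diverge whenever delays are not exact.

With these semantics a single stored pattern recalls every spike at exactly
its trained tick (the suite asserts bit-exact time-locking), and
perturbations from noise decay instead of compounding: a neuron that fires
late by $\delta$ feeds four downstream paths, but each downstream neuron
fires with its third-earliest arrival, so isolated late arrivals are simply
outvoted.

Within a tick the phase order is fixed: ramps advance and emit; pre-synaptic
spikes are delivered in ascending module index; coincidences fire; fired and
externally injected post-synaptic spikes restart matching ramps.  The engine
is fully deterministic — identical parameters and injected streams give
bit-identical event streams.

## The pattern generator

Patterns are pseudo-random spike sequences from two maximal-length LFSRs:
one register picks each successive neuron address, the other the inter-spike
interval.  Both registers run continuously across a whole training set (one
seed pair per run reproduces every pattern, for training and recall alike),
clocked one full register turnover per spike.

* **Interval mapping.**  Intervals are uniform on 16–160 ticks (≈1–10 ms,
  mean ≈5.5 ms, so a 50-interval pattern lasts ≈270 ms).  The upper bound is
  set by the storage geometry: a module stores spans of up to *four*
  consecutive intervals, and 4 × 160 = 640 ticks only rarely exceeds the
  511-tick ramp ceiling (≈3% of four-interval spans; such paths are clamped
  in programming mode and reported).  A mean interval of 10 ms — the naive
  reading of "about 100 spikes per second" — would put *most* three- and
  four-interval spans beyond the ceiling and make threshold-3 recall
  structurally impossible.
* **Address register width.**  The address register is 16 bits, reduced
  modulo the array size — deliberately wider than any array's address bus.
  Width-matched registers look natural but are statistically ruinous: all
  patterns then sample one short cyclic orbit (period 2^w − 1), so different
  patterns become shifted copies of the same address sequence and their
  stored delay paths interfere coherently ("ghost" chains).  Worse, if the
  register is clocked per tick rather than per sample, register-step
  distance becomes identical to tick delay and *every* stored delay in the
  network is consistent with a single travelling wave over the orbit — the
  network locks into a self-sustaining resonance.  With a 16-bit register
  the joint generator state has period lcm(65535, 511) ≈ 33M spikes, so no
  training stream ever revisits a state.
* The interval register (9 bits, fixed polynomial) depends only on its own
  seed, so runs with the same interval seed share interval sequences across
  network sizes — sizes are compared on identical temporal structure.

Noise is a network-wide Poisson stream: `rate_hz` counts *total* extra
spikes per second entering the bus, each aimed at a uniformly random neuron.

## Training

**Delay programming** is write-once: each spike of a pattern consumes the
next unconfigured module (the programming index advances once per spike),
and the delays latch the true spans directly.  A 4096-module array therefore
stores 82 patterns of 51 spikes only partially — 82 × 51 = 4182 > 4096 — and
the harness reproduces exactly this regime, counting the partially stored
trailing patterns in the denominator.

**Delay adaptation** initializes each configured path with a random 9-bit
delay and, on every training presentation (teacher forcing: the full pattern
is injected, so firing times are the trained times), moves each delay toward
the measured span: all the way (`one_step`), by one tick (`single_count`),
or by `coefficient` × the difference, rounded half away from zero
(`proportional`, the default with coefficient 0.5).  Updates apply once per
path per presentation, including the configuring presentation; paths whose
span exceeds the ramp ceiling cannot be measured and keep their random
delays.  With coefficient 0.5 the error halves each epoch: from a mean
initial mismatch of ≈150 ticks, five epochs leave ≈5 ticks, eight epochs
reach exactness.

### The adaptation accuracy boundary

Residual delay errors do not break the recall chain — three-of-four
coincidence tolerates ±16-tick dispersion — but they bias its *time base*:
each generation fires at the third-earliest of four error-shifted arrivals,
which drifts late by roughly the expected third order statistic of the path
errors (≈ +0.3 × mean |error| per generation).  After the default five
epochs (≈5-tick residuals) a 51-spike pattern ends ≈90 ticks late, beyond
the checker's acceptance pulse, and adaptation-mode scores collapse even
though every spike is regenerated.  One additional epoch (≈2.5-tick
residuals) brings the final-spike lag inside the pulse and restores scores
to programming-mode levels; at seven or more epochs the two modes are
indistinguishable.  The five-epoch protocol thus sits exactly on the
convergence boundary, and the package reports its five-epoch results as
measured rather than adjusting the protocol.  The suite's adaptation
experiments document this; the convergence itself (geometric error decay,
monotone per-epoch improvement, one-step/programming equivalence) is
asserted exactly.

## Recall and scoring

A recall trial injects the first four spikes of a pattern at their trained
relative ticks (plus optional Poisson noise), runs the network for the
pattern duration plus ten delay ceilings (ample for residual activity to die
out), and scores the emitted spikes like the hardware checker: each
reference spike after the cue opens a 64-tick (4 ms) acceptance pulse
starting a random 8–16 ticks (0.5–1 ms) early; a pulse accepts at most one
address-matched spike (earliest wins, no double counting), and a pattern
counts as successfully recalled when the accepted fraction *strictly*
exceeds 70%.  A trial whose emission count exceeds 50 × the pattern length
is aborted and scored as failure — this is the all-fire cross-talk state,
which the model reliably produces at 128 neurons under the 82-pattern load
(and intermittently at 256).

## Experiments

The harnesses mirror the headline measurements: `sweep_network_size()`
(success percentage vs array size, 82 patterns × 50 intervals, ten seeded
runs whose seeds are shared across sizes; standard deviation over runs),
`spike_recall_distribution()` (the per-pattern fraction of spikes recalled),
`sweep_noise()` (success vs Poisson noise rate at 4096 neurons; training is
always noise-free), and `full_capacity_test()` (every module consumed:
70 × 4096 modules at full scale, pattern lengths 21 and 51, both training
modes; the `scale` argument shrinks the module budget and pattern count
proportionally at fixed 4096 neurons).  Note the scaled-down capacity test
is *sparser* in connections per neuron (28 at scale 0.1 vs 280 at full
scale), i.e. an easier cross-talk regime; its success rates read as upper
bounds on the full-scale configuration, which the sparsity rule (mean
connections per neuron below a quarter of the array size) predicts to behave
similarly.

Because the bus is modeled as ideal and lossless (no address collisions, no
active-module ceiling), recall is somewhat more noise-robust and the
all-fire threshold sits at slightly smaller arrays than on real hardware,
where colliding spikes are dropped; collision modeling is a possible
extension.

Problem sizes in the test suite and acceptance script are the study
conditions themselves (82 × 50 × 10 runs per size; capacity runs at scale
0.1): a full suite run takes a few minutes on one core.

## What the generator does and does not emulate

Synthetic patterns are LFSR-uniform: addresses evenly distributed, intervals
independent and identically distributed, no refractory violations within a
pattern only by virtue of the 16-tick minimum interval.  Real spike trains
have bursts, rate structure and correlations that these patterns do not
model, so passing results here demonstrate the storage mechanism's capacity
and noise behavior under its design assumptions, not performance on
biological recordings.

## Worked example

```{r example, eval = FALSE}
net <- create_network(sim_params(n_neurons = 512, modules_per_array = 64))
pat <- generate_pattern(seed_neuron = 3, seed_interval = 5,
                        n_neurons = 512, n_intervals = 50)
tr  <- train_patterns(net, list(pat), mode = "programming")
run_recall_trial(tr$net, pat, seed = 7)
#> recall report: 47/47 spikes coincident (100.0%) -> success
```
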