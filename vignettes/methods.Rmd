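---
title: "Methods: emulating an accelerated analog neuromorphic core at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating an accelerated analog neuromorphic core at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
behind `analognet`. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## Units and the accelerated time domain

All internal computation uses SI units in the *hardware* time domain: the
emulated circuits run nominally 1000× faster than biology, so membrane
time constants are tens of microseconds and experiment durations hundreds
of microseconds. Biological parameter sets enter only through
`convert_biological_params()`, which divides the time constants
(`tau_w`, `t_r`) by the acceleration factor and rescales `C_m` so that
`tau_m = C_m / g_l` transforms identically, leaving voltages,
conductances and currents untouched. This makes the conversion an exact
involution (converting back with the inverse factor restores the set).

## Neuron model and integration

The core neuron is the adaptive exponential integrate-and-fire (AdEx)
model with a hard firing threshold, reset, refractory clamp and
spike-triggered adaptation. Four per-neuron switches mirror the digital
configuration of the circuits: disabling the exponential and adaptation
terms gives a leaky integrate-and-fire (LIF) neuron; disabling also leak
and threshold turns the membrane into a pure charge integrator — the
mode used for analog matrix multiplication.

Numerical choices:

* **Exponential Euler** on the leak term (exact for the linear part, hence
  unconditionally stable for the stiff leak), with the exponential
  current, adaptation current, stimulus and axial currents held at their
  start-of-step values. Default step `dt = 0.1 µs`, i.e. 1/200 of the
  default membrane time constant.
* **Threshold crossings are located by linear interpolation** inside the
  step, giving O(dt²) local error in spike times; the test suite verifies
  first-order convergence of spike times under step halving.
* The **exponential current is clamped** at `I_exp_max = 50 g_l Delta_T`
  by default, mimicking the finite current a real circuit can source and
  preventing floating-point overflow.
* During refractoriness the membrane is **clamped to `V_r`** (not frozen
  mid-flight), and the adaptation current keeps evolving against the
  clamped potential.
* Stimulus windows are tested against the **step midpoint**, which makes
  the integrated charge of a grid-aligned step current exact (the basis
  of the integrator-mode charge-conservation test).
* The hard threshold defaults to `V_th = V_T + 5 Delta_T`; the hardware
  distinguishes the soft AdEx threshold from the hard spike trigger but
  no fixed relation is published, so this is a package convention.

### Firing-regime defaults

The classical AdEx firing-pattern taxonomy (Naud et al. 2008,
*Biol. Cybern.*) provides the biological-domain parameter sets shipped in
`adex_pattern_sets()`. The regimes are characterized by: transient
spiking — large `b` *and* strong positive `a`; regular bursting and
initial burst — small `a`, large `b`, distinguished by `V_r` above
(bursting) versus at (initial burst) the soft threshold `V_T`; delayed
patterns — inverted subthreshold adaptation `a < 0`. Two step amplitudes
were chosen by the package (they are not published values): the
delayed-bursting drive (70 pA) sits low enough that the positive feedback
of `a < 0` needs >30 % of the stimulus window to charge the membrane, and
the regular-bursting drive (250 pA) sits far enough from the
burst-size bifurcation that the pattern is robust to the few-percent
parameter residuals left after calibration.

### Pattern classification

`classify_firing_pattern()` is a deterministic ISI-statistics rule:
transient = all spikes within the first 20 % of the stimulus window;
delayed = first spike later than 30 % of the window; bursting = the
sorted ISIs split (at the largest consecutive ratio gap) into short and
long groups with `max(short) < 0.25 min(long)`, recurring until stimulus
offset; one leading burst followed by tonic ISIs is an initial burst.
All three thresholds are configurable arguments; the defaults are package
choices since no published decision rule exists for these labels.

## Multi-compartment graphs

Compartments are full neuron circuits joined by axial conductances
`g_ic (V_j − V_i)`, added as explicit coupling terms inside the same
exponential-Euler step, so the per-compartment integrator is unchanged.
Passive chains are exactly linear, which the suite exploits: responses
superpose to <1e−6 relative error, amplitudes scale linearly in the
injected weight, and EPSPs attenuate and broaden monotonically along the
chain.

Plateau-type dendritic spikes are modelled as a clamp of the initiation
zone to `V_plateau` (default `V_th + 20 mV`) for `t_plateau` (default
10 µs), with no adaptation increment — deliberately distinct from the
sodium-like AdEx upswing, for which the hardware uses the exponential
term. Published figures for the plateau level and duration do not exist;
these defaults were chosen once so that the branched demonstration model
expresses location- and order-sensitive coincidence detection (proximal
pairs fire, distal pairs do not, and distal-before-proximal fires at
delays where the reverse order does not) at a single injection weight
(0.7 nA).

## Crossbar, graded spikes and MAC mode

Event delivery is address-matched: a row event with label ℓ increments
exactly the columns whose stored 6-bit address equals ℓ, by
`gamma * weight * payload / 31`. Payloads use 5 bits (0–31); the mapping
from payload to synaptic activation is assumed linear. Synaptic currents
decay analytically (`I <- I exp(-dt/tau)`), so the event-driven current
equals the closed-form kernel sum to machine precision — there is no
integration error in the synaptic path.

MAC mode encodes an input vector as graded payloads, pairs an excitatory
and an inhibitory row per signed weight, accumulates charge on
integrator-mode neurons and digitizes with the 8-bit columnar ADC.
Outputs are reported in product units (`W x`): the dynamic range is
`64 × 63` product units, i.e. a single full-weight, full-payload event
deflects the integrator by 1/64 of the range, which keeps 64-input sums
on scale. With quantization off the path is ideal and reproduces the
exact product; with it on, the readout error is bounded by half an LSB
*relative to the payload-encoded input* — the 5-bit input encoding is a
separate, earlier quantization. Arbitrary shapes are tiled into
≤128-input × ≤512-column blocks whose partial results accumulate
digitally at full precision.

## Correlation sensors and the plasticity engine

Each synapse carries two analog accumulators; pairing is
**nearest-preceding-spike**: a postsynaptic spike adds
`eta_+ exp(-(t_post - t_pre)/tau_+)` for the latest preceding
presynaptic spike (and symmetrically for the anti-causal bank). This
matches accumulate-per-event sensor semantics; an all-to-all variant
would require unbounded per-synapse state. The accumulation is exact
event arithmetic, checked against the closed-form pair sum at 1e−9.

The embedded plasticity processor is abstracted as a synchronous periodic
callback receiving row-parallel views (weights, addresses, quantized
correlation reads) and returning weight writes, which are rounded,
clipped to the 6-bit range (clips counted) and logged as
`(time, row, col, old, new)`; replaying the log reconstructs the final
weights exactly. Instruction-level timing is out of scope.

## Homeostatically regulated reservoirs and criticality

The reservoir is a desk-scale recurrent LIF network in normalized
membrane units (leak 0, threshold 1): `N = 32` neurons, 80 %/20 %
excitatory/inhibitory, all-to-all 6-bit recurrent weights, `n_sources =
32` external Poisson sources at 25 kHz (hardware domain) of which each
neuron receives `K_ext`. Defaults: `tau_m = 20 µs`, `tau_s = 5 µs`,
`t_ref = 2 µs`, drive per weight LSB `kappa = 0.02` thresholds, initial
excitatory weight 10, fixed inhibitory weight 30, external initial weight
32, target rate `nu_target = 20 kHz` (20 Hz biological), homeostatic
update every 250 µs with integer steps clipped to ±2.

The homeostatic rule is deliberately the simplest integer proportional
controller, `dw = clip(round(lambda_h (nu* − nu)/nu*), ±2)`. It is
applied to **all excitatory afferents of a neuron — external and
recurrent alike**. This choice is essential for the phenomenon the
module exists to reproduce: with plastic input weights only, the network
stays input-driven at every `K_ext`; with fixed input weights, a low
`K_ext` network can never bootstrap out of silence. With both plastic,
weak external drive saturates the input synapses and the remaining rate
deficit is built up by recurrence (long intrinsic time scales, near
criticality), while strong drive is trimmed at the inputs and recurrence
stays weak (fast, input-locked dynamics). During task streams the
homeostatic period is decoupled from the bit period (one update per
~250 µs of stimulus) so the controller does not track and cancel the
stimulus itself.

The autocorrelation time is estimated from the population activity binned
at 5 µs: a log-linear fit of the empirical autocorrelation function over
the initial lags with `r > e^-2`. Later lags are excluded because their
finite-sample errors are large, positively correlated, and bias the
fitted time constant upward; with this cutoff the estimator recovers the
AR(1) closed form `tau = -bin/log(phi)` within 10 % at 1e5 samples. A
non-decaying or immediately negative ACF is flagged unreliable.

The memory tasks (n-bit parity / n-bit sum of a random binary stream,
60 µs per bit, rate-modulated sources) are read out by ridge regression
(`MASS::lm.ridge`, one-vs-rest on indicator targets) on low-pass-filtered
spike counts (`tau = 30 µs`) sampled at mid-bit and bit end, with an
80/20 train/test split. An all-silent reservoir is flagged and scored at
chance.

## Fixed-pattern noise and calibration

The noise model distinguishes the physically analog from the digitally
configured parameters: `g_l`, `tau_w`, `a`, `b` and `Delta_T` receive
independent multiplicative log-normal distortions with CV 0.10 (unit
mean), while the potentials receive additive Gaussian offsets
(sd = CV × 50 mV, i.e. 5 mV at the default CV) — the threshold offset
shifts `V_T` and `V_th` together, as one threshold circuit would.
`C_m` and `t_r` are digitally configured on the hardware and therefore
carry no fixed-pattern noise; this also makes the effective `tau_m`
spread equal the `g_l` spread (≈10 %) rather than the ≈14 % a second
independent factor would add.

Each instance exposes 10-bit bias codes with monotone logistic-saturating
transfer curves (gain `2^±1` for magnitude parameters, ±40 mV for
potentials, neutral at code 512). Calibration is measurement-only — the
hidden distortion factors are never read; only simulated protocols
(charging-curve fits, resting potentials, spike-train statistics,
adaptation-trace jumps) are observable:

* Target values are the observables **measured on a distortion-free
  reference instance** rather than the nominal parameter values, so any
  systematic estimator bias (e.g. the adaptation coupling folded into the
  `tau_w` decay fit) cancels between reference and device.
* The threshold protocol probes with the reset bias forced low, so that
  no probe code can put `V_r` above `V_th` and degenerate the spike train
  (which would break the monotonicity the bisection relies on).
* The refractory estimate extrapolates over two drive strengths
  (`t_r ≈ 2 ISI(2I) − ISI(I)`), using only measured spike trains.
* Per target, a bisection on the controlling code runs until the
  measurement is within tolerance (2 % for `tau_m`, 1 % for `tau_w` and
  the adaptation parameters, 0.25 mV for potentials); the whole target
  list is swept **twice**, because the observables couple weakly through
  the calibrated operating point.
* A `rheobase` observable (bisected minimal spiking current) exists for
  the exponential slope but is not targeted by default: its value aliases
  sub-tolerance leak/threshold residuals into the `Delta_T` code and can
  worsen the calibration it is meant to refine.

Before/after comparisons use the uncalibrated common setting — every
code at the median of the calibrated codes — versus each instance's own
codes, mirroring how a common median configuration exposes fixed-pattern
spread on real arrays.

## Event-based adjoint gradients

The gradient module treats the network as a hybrid dynamical system:
smooth flow `x' = f(x, p, t)` punctuated by transitions `x+ = T(x-, p)`
fired when jump conditions `j(x, p, t) = 0` cross zero. The reference
instance is the LIF network (state `(V, I)` per neuron, threshold jump
per neuron, transition `I+ = I- + W e_i`, `V_i+ = V_reset`).

* **Exact flow.** The LIF flow is linear, so propagation between events
  uses the closed-form solution; event times are located by root finding
  (`uniroot` at ~1e−16 tolerance) on the closed-form membrane trajectory
  inside a grid step. There is no integration error in the forward pass;
  the dense grid only fixes the trajectory storage and quadrature
  resolution. Simultaneous crossings are processed in ascending neuron
  index (deterministic tie-break).
* **Event-time derivatives** follow the implicit function theorem:
  `dt*/dq = -(∂x j · ∂q x- + ∂p j)/(∂x j · f- + ∂t j)`. For threshold
  jumps `∂x j` has a single non-zero entry, so `dt*/dx-` is sparse. A
  vanishing denominator (grazing, tangential crossing) is detected
  (|f_V| < 1e−9 V/s) and flagged, never smoothed.
* **Adjoint event jump.** Writing `h = f+ − ∂x− T f−`, the pre-event
  adjoint is `λ−' = λ+' D` with `D = ∂x− T + h (∂x j)/(∂x j · f−)`.
  The sign of the correction term follows from differentiating the
  composed flow at the event (the scalar reset case, where
  `λ− = (f+/f−) λ+`, pins it down); it is validated coordinate-wise
  against central finite differences on every fixture.
* **Parameter gradients.** Transition parameters accumulate only at
  events (`dL/dW[j, i] += λ+_{I_j}` at each spike of neuron `i` — so a
  weight with no presynaptic spike in the horizon receives exactly zero);
  flow parameters accumulate continuously by Simpson quadrature of
  `λ' ∂p f` over each smooth segment, with endpoint and midpoint states
  and adjoints all evaluated exactly under the closed-form flow.
  Sparse-observation losses add Dirac terms `2 P'(P x − x̂)` to the
  adjoint at the (grid-snapped) observation times.
* **Forward and backward share the same grid and flow** (a
  discretize-then-optimize pairing at event boundaries), which is what
  lets the finite-difference oracle agree coordinate-wise at 1e−3 on the
  fixture family of 1–5-neuron systems with 0–10+ events.
* The **finite-difference oracle** perturbs each parameter by
  `1e−6 × max(|p|, 1e−3)` (so second-scale time constants get relative
  steps), re-runs the forward pass from a fixed initial state, and flags
  any coordinate whose perturbation changes the event count as
  non-differentiable at that point. External input spikes at fixed times
  propagate gradients both to their input weights and to the spike times
  themselves, which is what makes composed per-subsystem adjoint passes
  chain correctly through spike times.

## Surrogate gradients from sampled traces

The surrogate module mirrors trace-based in-the-loop training: the
substrate is modelled as a discrete-time LIF graph at the ADC sampling
period (1.7 µs) with decay factors `alpha = exp(-dt/tau_m)`,
`beta = exp(-dt/tau_s)`, multiplicative reset, a non-spiking
leaky-integrator readout, and softmax cross-entropy on the max-over-time
readout (gradient routed to the argmax step), plus an optional activity
penalty `rho · mean(S)`. The backward pass inserts the *measured*
(8-bit-quantized) membrane samples and spikes into the graph in place of
the model's own state, attaches a SuperSpike-style surrogate derivative
`1/(1 + beta_s |v - v_th|)²` (`beta_s = 10`, i.e. 10 per unit of the
normalized threshold range) at the hidden thresholds, and passes
gradients straight through the trace quantization. Insertion is per time
step. Readout-weight gradients are exact (they coincide with central
finite differences along the measured trajectory); hidden-weight
gradients are non-zero through the surrogate even though the true
discrete loss is piecewise constant — which is precisely the point of
the method. Training uses full-batch Adam (lr 5e−3).

## Synthetic data

The harness generates all inputs: homogeneous Poisson event streams
(reproducible under seed, KS-checked against exponential ISIs) and
16 × 16 latency-encoded image classes built from random Gaussian-blob
templates plus pixel noise, one spike per active pixel at
`t = t_max (1 − intensity)`. At `separation ≥ 1` the generator verifies
linear separability with a ridge probe. These stand-ins reproduce the
*structure* of latency-encoded vision benchmarks (sparse one-spike-per-
pixel codes, class-dependent spatial patterns) but not their difficulty:
passing the trainability checks shows the gradient machinery works, not
that the emulated substrate would reach any particular benchmark
accuracy.

## Problem sizes

The shipped tests and the acceptance script run: the six-member gradient
fixture family (1–5 neurons, ≤ 25 events); 4-compartment chains over
120 µs; 64 × 64 MAC products; cohorts of 128 calibrated instances;
reservoirs of 32 neurons with 4–32 external inputs, ~50–75 ms
(hardware-time) warm-up and 800-bit task streams over 5 seeds; and
surrogate training of a 256–32–2 network on 200 latency images for up to
200 epochs. These sizes were chosen as the smallest at which each
qualitative claim is stable across seeds.

## Known limitations

* Temporal (thermal) noise is not modelled beyond an optional additive
  readout term in MAC mode; fixed-pattern noise is static per instance.
* Short-term plasticity has a hook (presynaptic payload modulation) but
  no dynamics, as no quantitative model is specified for the substrate.
* The adjoint module's closed-form flow covers LIF-type linear modes;
  AdEx events are handled by the simulation core but not by the exact
  adjoint path.
* The event router (bandwidth, latency, spike loss beyond disabled-row
  drops) is not modelled.
* The reservoir reproduces the direction of the criticality phenomena
  (monotone `tau_ac` in `K_ext`, task-dependent optimal regime,
  reversibility under switching); absolute time scales depend on the
  package's normalized-unit defaults, not on published circuit values.
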