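# analognet

A desk-scale software twin of the analog core of an accelerated
mixed-signal neuromorphic chip, written for computational neuroscientists
and neuromorphic-hardware researchers who want to prototype experiments,
plasticity rules and gradient-based training schemes for such a substrate
without the hardware in the loop.

The emulated core consists of 512 neuron circuits fed by four synaptic
crossbar quadrants of 256 × 128 synapses (2¹⁷ in total, 6-bit weights and
6-bit source address labels), runs nominally 1000× faster than biological
time, and is observed through an 8-bit columnar ADC sampling at 1.7 µs.
The package models, in one coherent set of units (SI, hardware time
domain):

* **Neuron dynamics** — the adaptive exponential integrate-and-fire model

  $$C_m \dot V = -g_l (V - E_l) + g_l \Delta_T
    \exp\!\left(\tfrac{V - V_T}{\Delta_T}\right) - w + I, \qquad
    \tau_w \dot w = a (V - E_l) - w,$$

  with a hard threshold $V_{th}$, reset to $V_r$, refractory clamp $t_r$
  and spike-triggered increment $w \mathrel{+}= b$; per-neuron feature
  switches reduce it to LIF or to a pure charge integrator.
  Multi-compartment graphs couple neuron circuits through axial
  conductances and support plateau-type dendritic spikes.
* **The crossbar** — address-matched event delivery, exponentially
  decaying synaptic currents (evaluated analytically, event by event),
  graded-spike payloads, and a non-spiking matrix-multiply (MAC) mode with
  signed excitatory/inhibitory row pairs, tiling and 8-bit readout.
* **Hybrid plasticity** — per-synapse causal/anti-causal correlation
  sensors, row-parallel quantized readout, a programmable periodic rule
  engine with a full audit log, and homeostatically regulated recurrent
  reservoirs whose autocorrelation time is controlled by the input
  strength `K_ext`.
* **Calibration** — log-normal fixed-pattern noise on the analog
  parameters, measurement-only characterization protocols, and iterative
  bisection calibration of 10-bit bias codes that narrows the cohort
  spread and restores target firing patterns.
* **Gradients** — the hybrid-dynamical-system adjoint: exact closed-form
  flow between threshold events, implicit-function-theorem event-time
  derivatives $\mathrm{d}t^*/\mathrm{d}q = -\,\partial_x j \cdot
  \partial_q x^- / (\partial_x j \cdot f^-)$, reverse-time adjoint
  integration with event jumps, event-based weight-gradient accumulation,
  sparse-observation losses, and a central finite-difference oracle — plus
  surrogate-gradient backpropagation through a discrete LIF graph aligned
  with sampled (8-bit, 1.7 µs) membrane traces.

## Worked example

Replicating a classical firing pattern and checking the gradient machinery:

```r
library(analognet)

sets <- adex_pattern_sets()                      # biological-domain regimes
hw   <- convert_biological_params(sets$regular_bursting$params)  # 1000x
prot <- stim_protocol(sets$regular_bursting$I_0) # step on [50, 400] us
res  <- run_neuron(hw, prot)

length(res$spikes)                        # 7
classify_firing_pattern(res$spikes, prot) # "regular_bursting"
round(head(diff(as.numeric(res$spikes)), 6) * 1e6, 1)
# 3.8  5.0 97.3  6.2 112.3  6.1        <- bursts of short ISIs separated by
#                                         ~100 us inter-burst intervals

gradcheck_suite()
#       name n_events n_coords n_flagged  max_rel_err pass
# 1 smooth_1        0        8         0 1.478066e-08 TRUE
# 2 driven_1        6        8         0 9.741435e-07 TRUE
# 3     ff_2       10       14         0 7.617275e-07 TRUE
# 4  chain_3       12       18         0 4.631221e-06 TRUE
# 5    rec_2       19       12         0 8.351597e-06 TRUE
# 6   rand_5       13       36         0 1.650657e-05 TRUE
```

The table compares the adjoint gradient of every parameter (weights, time
constants, potentials, drives) with central finite differences on a family
of 1–5-neuron hybrid LIF systems; `max_rel_err` is the worst coordinate.

Experiment drivers (`firing-patterns`, `chain`, `coincidence`,
`criticality`, `mac`, `calibrate-cohort`, `train-surrogate`, `gradcheck`)
are available through `run_experiment()` or the thin CLI in
`exec/analognet`:

```sh
Rscript exec/analognet firing-patterns --seed 1 --out out/
```

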