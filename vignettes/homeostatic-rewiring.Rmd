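---
title: "Calcium-driven structural plasticity and synaptic scaling in spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium-driven structural plasticity and synaptic scaling in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hspnet)
```

## The model

`hspnet` simulates an inhibition-dominated network of current-based leaky
integrate-and-fire point neurons in which the excitatory-to-excitatory (E-E)
synapses are not fixed: they are created, pruned and re-wired by a
homeostatic structural plasticity (HSP) rule, and their weights can
additionally be regulated by a homeostatic synaptic scaling (HSS) rule. Both
rules are driven by the same per-neuron activity proxy, a low-pass-filtered
spike count interpreted as intracellular calcium.

### Neuron and network

Each neuron obeys

$$\tau_m \dot V = -(V - V_\mathrm{rest}) + R\,I(t), \qquad R = \tau_m / C_\mathrm{mem},$$

with delta-jump synapses: a presynaptic spike arriving after the
transmission delay adds its weight (in mV) to the membrane potential
instantaneously. Crossing the threshold emits a spike, resets the potential
and starts an absolute refractory period during which inputs are discarded.
Defaults: $\tau_m = 20$ ms, $t_\mathrm{ref} = 2$ ms, $V_\mathrm{rest} =
0$ mV, $V_\mathrm{reset} = 10$ mV, $V_\mathrm{th} = 20$ mV, $C_\mathrm{mem}
= 250$ pF.

The reference architecture has 10000 excitatory (E) and 2500 inhibitory (I)
neurons. The I-I, I-E and E-I blocks are hard-wired at build time: each
neuron receives synapses from 10% of the relevant presynaptic population
(fixed in-degree; a Bernoulli-per-pair variant is available). Every neuron
receives an independent 30 kHz external Poisson drive with 0.1 mV jumps.
Excitatory synapses jump $J_E = 0.1$ mV, inhibitory $J_I = -0.8$ mV. The
E-E block starts empty and is governed entirely by the plasticity rules.

Numerics: exact exponential-decay integration at $dt = 0.1$ ms (not Euler:
the relaxation between step boundaries is solved in closed form, so the
integrator is exact for piecewise-constant input), uniform 1 ms transmission
delay, spikes applied at step boundaries. The delay and step are not imposed
by the biology and are configurable; 1 ms / 0.1 ms are the conventional
choices for this network family.

### Calcium trace

Each excitatory neuron carries a calcium trace

$$\dot C = -C/\tau_\mathrm{Ca} + \beta_\mathrm{Ca} S(t),$$

updated per step as $C \leftarrow C e^{-dt/\tau_\mathrm{Ca}}$ plus
$\beta_\mathrm{Ca}$ per emitted spike (decay first, influx second — the
order is fixed for bit-reproducibility; it matters only at $O(dt)$). With
$\tau_\mathrm{Ca} = 10$ s and $\beta_\mathrm{Ca} = 10^{-4}$ the
steady-state mean is $C = r\,\beta_\mathrm{Ca}\tau_\mathrm{Ca} = r / 1000$,
so the setpoints $\epsilon = 0.0079$ and $\eta = 0.0007$ correspond to
7.9 Hz and 0.7 Hz.

### Growth rules

Each excitatory neuron owns continuous counts of axonal boutons ($z_A$) and
dendritic spines ($z_D$), the "synaptic elements". A growth rule maps the
calcium trace to their rate of change:

* linear: $\dot z = \nu (1 - C/\epsilon)$, one stable setpoint;
* Gaussian: $\dot z = \nu\,\bigl(2\exp[-((C-\xi)/\zeta)^2] - 1\bigr)$ with
  $\xi = (\eta+\epsilon)/2$ and $\zeta = (\epsilon-\eta)/(2\sqrt{\ln 2})$,
  which places the zeros exactly at $\eta$ and $\epsilon$, the maximum
  $+\nu$ at $\xi$, and the retraction limit $-\nu$ at high calcium.

A note on the Gaussian form: the curve is sometimes written with an
unsquared exponent and $\zeta = (\eta-\epsilon)/(2\sqrt{\ln(1/2)})$, which
is imaginary; the squared-exponent form above is the unique smooth curve
with the stated geometry (zeros at both setpoints, peak $+\nu$ midway,
$-\nu$ asymptote) and is what this package implements.

With $\eta = 0$ ("zero-Gaussian") silent neurons stop changing their
elements; with $\eta > 0$ ("biphasic") neurons firing below $\eta$ retract
elements — the regime that produces silencing-induced synapse loss.

### Structural updates

Every 100 ms (configurable) the engine performs one structural cycle:

1. Euler step of $z_A, z_D$ with the calcium sampled at the boundary,
   clamped at 0. The interval is long relative to $dt$ and short relative
   to growth timescales ($\nu \times$ interval $\ll$ 1 element).
2. Deletion: for each neuron and element type, if the number of elements
   bound in synapses exceeds $\lfloor z\rfloor$, surplus synapses are
   deleted uniformly at random (axonal pass, then dendritic). A deletion
   frees the partner's element without touching the partner's $z$ — the
   freed element returns to the pool and can re-bind, which is what makes
   *rewiring* (rather than mere loss) possible.
3. Formation: free elements ($\lfloor z\rfloor$ minus bound count) are
   pooled globally, both pools shuffled, and paired sequentially; autapse
   pairings are rejected and re-drawn once among themselves; leftovers
   stay free. New synapses start at $J_E$. Multapses are allowed (the
   connectivity matrix counts synapses per pair); autapses are not.

Floor-based free-element accounting and the survive-and-rebind convention
for the partner of a deleted synapse are deliberate choices where several
conventions are defensible; both are asserted by the test suite, and the
compiled engine is verified state-for-state against an independent plain-R
reference implementation on small fixtures.

### Synaptic scaling

The scaling rule multiplies every E-E synapse onto postsynaptic neuron $j$
by $1 + \rho\,\Delta t\,(\epsilon - C_j)$ at the structural cadence:
cell-autonomous (all inputs of a neuron share one factor, preserving their
ratios) and multiplicative, growing weights under deprivation and shrinking
them under over-excitation. The drive is written here as $(\epsilon - C)$:
with the opposite sign the rule would be anti-homeostatic (silenced neurons
would lose input weight and could never be rescued by upscaling); a `sign`
switch in `scaling_params()` exposes the reversed convention for
completeness. Weights are clamped at `w_min` (default 0, no upper cap);
newly formed synapses always start at $J_E$ regardless of scaling history.
Effective connectivity divides summed weights by the 0.1 mV unit weight, so
with scaling off, effective and structural connectivity are identical.

## Desk-scale preset

Full-size runs (12500 neurons, thousands of biological seconds) are not
desk-scale, so the protocols run on `scaled_preset()`:

* $N_E = 1000$ (E population divided by 10), excitatory weights multiplied
  by 10 ($J_{EE} = J_{EI} = 1.0$ mV) so every excitatory mean drive is
  unchanged;
* the **static inhibitory pool is kept at full size and weight**
  ($N_I = 2500$, $J_I = -0.8$ mV);
* external drive untouched (30 kHz, 0.1 mV).

The reason for the asymmetric treatment is that the equilibrium the growth
rules find is set by the *diffusion* statistics of the membrane, not only
the mean drives: the per-neuron homeostatic controller moves each neuron's
E-E in-degree until its rate sits at 7.9 Hz, and the in-degree at which
that happens depends on the input variance through the first-passage (
Siegert) rate function. Keeping the inhibitory pool intact preserves the
inhibitory input statistics exactly and leaves the total membrane variance
within ~15% of the full-size model; a self-consistent Siegert calculation
puts the preset's equilibrium E-E connection probability within 0.1
percentage points of the full-size prediction (~8.5% in the diffusion
approximation; simulated networks plateau near 10%). A fully proportional
scaling (N/10 with weights ×10 everywhere) triples the membrane noise and
shifts the 7.9 Hz operating point to ~3% connectivity — and with
Bernoulli-wired static blocks the quenched in-degree variance additionally
produces a ~16 Hz rate dispersion with pathological churn; this is why the
static blocks default to fixed in-degree wiring.

Plasticity acceleration: the growth phases run the printed rules with
`nu_growth = 150`, perturbation phases with `nu_perturb = 300`, and scaling
strengths are multiplied by `rho_mult = 100`. Protocols trade biological
duration against plasticity speed — the reference protocols themselves
switch between 100%/50%/10% growth rates for the same reason. The
multipliers were chosen so that (i) growth completes within a few hundred
simulated seconds while $\nu_\mathrm{eff}\tau_\mathrm{Ca}$ stays well below
the equilibrium in-degree (no control-loop overshoot), (ii) a silenced
subpopulation disconnects within a ~350 s phase, (iii) the weight-upscaling
race against structural loss discriminates weak ($\rho = 0.01$) from strong
($\rho = 0.02$) scaling within the same phase, and (iv) scaling remains
slow on the calcium timescale
($\rho_\mathrm{eff}\,\epsilon\,\tau_\mathrm{Ca} \lesssim 0.2$; much faster
scaling reacts to its own reactivation bursts within one calcium decay
time and turns the rescue into a burst–collapse oscillation). The rescue
race is intrinsically demanding: a silenced neuron keeps its full
inhibition while losing its entire external drive, so the surviving
excitatory weights must grow by an order of magnitude before structural
retraction removes them — which is also why the reactivated subpopulation
re-enters as synchronized bursts rather than smoothly. The facilitating
current for biphasic
growth decays over 300 s of the nominal 450 s growth span, mirroring the
4000 s / 6000 s full-scale protocol.

## Protocols

`grow_network()` grows a network from an empty E-E block until the
connectivity plateaus (the mean E-E connectivity of the two most recent
50 s half-windows differing by less than 0.1 percentage points for two
consecutive 100 s chunks, after any facilitating current has decayed); the
linear and zero-Gaussian rules grow unaided, the biphasic rule receives the
750 pA linearly decaying somatic current in all excitatory neurons (without
it, excitatory rates start below $\eta$ and the network fragments).

`apply_foi()` multiplies the external-drive rate of a 10% excitatory
subpopulation (chosen as the first $\lceil 0.1 N_E\rceil$ ids of a seeded
permutation) by a fold-of-original-intensity factor: stimulation (>1), mild
deprivation (<1) or silencing (0). `silencing_rescue()` chains silencing
with re-stimulation; `run_sweep()` repeats silencing over a
growth-rate × scaling-strength grid and scores each run by trapezoidal
deviation areas of the subpopulation's input connectivity (target: the 10%
equilibrium) and rate (target: 7.9 Hz).

The qualitative outcomes reproduced by the test suite: 110% stimulation
causes homeostatic disconnection with rate recovery; 95% deprivation causes
a homeostatic connectivity increase with rate recovery; silencing without
scaling disconnects the subpopulation; under silencing, strong scaling
($\rho = 0.02$) reactivates and re-wires the deprived neurons while weak
scaling ($\rho = 0.01$) fails to restore synapse numbers — the recovery is
ordered in $\rho$.

## What the synthetic protocols do and do not show

All inputs are generated internally (seeded wiring, Poisson drive, scripted
spike trains); there are no external data. The desk-scale runs reproduce
the *mechanisms* — setpoint-seeking growth, facilitated biphasic
development, perturbation-direction-dependent rewiring, and the
scaling/structural-plasticity interaction — at the full-scale operating
point. They do not reproduce full-scale synapse counts (in-degrees scale
with $N_E$), the slow biological timescales (plasticity is accelerated by
the stated multipliers), distance-dependent topology (none; the network is
deliberately topology-free), or any cellular detail beyond point neurons.
Conclusions about real tissue rest on the model's assumptions, not on these
simulations.

## Numerical and testing notes

* Exact per-step exponential decay for membrane and calcium; errors under
  time-varying current are first order in $dt$ and are verified to halve
  with $dt$.
* All randomness flows from R's RNG (`set.seed()`): wiring, Poisson drive
  (drawn by exact inversion of the Poisson CDF through an alias table, fed
  by an internal xorshift stream seeded from R's RNG), structural matching.
  Identical seed and configuration give bit-identical spike trains, traces
  and synapse stores.
* The compiled structural engine and an independent naive-R reference
  implementation follow a documented RNG-consumption contract
  (insertion-ordered per-neuron synapse lists, swap-with-last removal,
  top-down Fisher–Yates shuffles) and are asserted equal state-for-state
  over 100 cycles on 3-neuron fixtures.
* Degenerate inputs: empty element pools form nothing; `z` is clamped at 0;
  an all-autapse pairing round forms nothing; a non-finite membrane
  potential aborts with a diagnostic.
* Desk-scale problem sizes used by the tests and the acceptance script:
  1000 E + 2500 I neurons, growth to plateau (typically 350–550 s of
  biological time), 150–200 s perturbation phases.

## A worked micro-example

```{r example, eval = FALSE}
p <- scaled_preset()
net <- grow_network("linear", preset = p, seed = 1)
equilibrium_summary(net)
#> gamma_EE ~ 0.10, rate_E ~ 7.9 Hz, indegree ~ 0.1 * N_E

sil <- apply_foi(net, foi = 0, duration = 200, preset = p, rho = 0.02)
tail(gamma_sub_input(sil), 1)   # recovered input connectivity of S
```

## Known limitations

* The desk-scale inhibitory pool dominates runtime; very large sweeps
  should reduce phase durations or the grid rather than the network.
* The diffusion argument for the preset holds near the asynchronous
  operating point; protocols that drive the network far into synchrony
  (very strong stimulation with high growth rates) leave its validity.
* Element counts are unbounded above; pathological parameter choices
  (e.g. $\epsilon \le 0$) are rejected by the constructors rather than
  handled downstream.
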