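---
title: "A loop-plus-branch FitzHugh-Nagumo memory network: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A loop-plus-branch FitzHugh-Nagumo memory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhnmem)
```

## The scientific problem

Short-term memory (STM) and long-term memory (LTM) can both be pictured as
firing patterns in a neural network: STM as a pattern that dies out soon
after the sensory input stops, LTM as a pattern that sustains itself
indefinitely. `fhnmem` implements a minimal excitable-network model of this
transition: a small closed loop of `n` neurons carrying a linear branch of
`N - n` neurons that reconnects to the loop at a junction node `i0`, so
that the graph contains exactly two cycles. Node 1 (on the loop) is the
sensory neuron and receives a sinusoidal input; every other neuron is
driven only by its neighbours. Whether the stimulus-evoked waves survive
the switch-off — and with how many circulating wavefronts — depends on the
stimulus frequency, the stimulus duration, the junction position and, most
importantly, on a small heterogeneity in the baseline synaptic
conductance between the loop and the branch.

## The model

### Neurons

Each node is an excitable FitzHugh-Nagumo neuron,

$$\varepsilon\,\dot u_i = u_i - u_i^3/3 - v_i + I_{sum,i},\qquad
  \dot v_i = a u_i + b v_i + d,$$

with the recovery coefficients $a = 0.08$, $b = -0.064$, $d = 0.056$ —
i.e. the classic FitzHugh recovery law $\dot v = 0.08\,(u + 0.7 - 0.8 v)$
— so a resting neuron sits on the left stable branch of the cubic
nullcline and fires exactly once when pushed past the left knee.
$\varepsilon$ sets the fast time scale of the voltage-like variable $u$
relative to the recovery variable $v$ (whose intrinsic relaxation time is
$1/|b| \approx 15.6$ model time units).

### Synapses

Neighbouring neurons are coupled by chemical synapses. The conductance a
postsynaptic neuron sees from presynaptic neuron $j$ is

$$g_{syn,j}(t) = f_j + g_{max,j}\, s_j(t), \qquad
  s_j(t) = \kappa \sum_{k}\Big[e^{-(t - t_k - \tau)/\tau_d}
           - e^{-(t - t_k - \tau)/\tau_r}\Big]\,\Theta(t - t_k - \tau),$$

and the synaptic current is $I = g_{syn}\,(u_{syn} - u_{post})$ with
reversal potential $u_{syn} = 0$. Here $f_j$ is the baseline (steady-state
open-channel) conductance: even a silent neighbour leaks the depolarising
current $-f_j u_{post}$ into the cell. The transient rises with
$\tau_r = 1$, decays with $\tau_d = 10$, and starts one axonal delay
$\tau = 0.5$ after each presynaptic spike $t_k$ (all times in model time
units). $\kappa$ is a fixed normalisation constant discussed below.
Transients of successive spikes add; since delay and kinetics are uniform,
one gating variable per presynaptic neuron serves all its outgoing
synapses exactly.

### Stimulus

The sensory node receives $I_{ext}(t) = A\sin(\omega t) + B$ for
$0 \le t < T_0$ and nothing afterwards. With the standard $A = 1$,
$B = 1.2$ the drive sweeps through the firing window once per cycle: the
peak $2.2$ lies above the right knee current and the trough $0.2$ below
the left knee current, so firing of the sensory node is gated by the
stimulus phase.

### Closed-form excitability theory

The package computes the knee points of the nullclines exactly
(`knee_points()`): the cubic has folds at $u = \mp 1$, the recovery
nullcline $v = -(a u + d)/b$ gives $v_L = -0.375$ and $v_R = 2.125$ there,
and substituting back yields the firing window
$I_L = 0.2917 < I < I_R = 1.4583$ for a constant input. Three corollaries
are exposed as functions:

* `max_baseline_f()` — excitability requires the resting synaptic current
  of a degree-$k$ node, $\approx k f |u_{rest}|$, to stay below $I_L$;
  with the empirical rest magnitude $1.5$ and $k = 3$ this caps the mean
  baseline conductance at $f_{max} = (I_L/3)/1.5 \approx 0.065$. A
  self-consistent variant substitutes the computed fixed-point magnitude
  $|u^*| \approx 1.20$ instead of $1.5$; both are reported because the
  empirical rest value is read off simulated trajectories (which dip well
  below the fixed point after each spike) rather than off the fixed point
  itself.
* `stimulus_feasible()` — the drive can elicit firing iff
  $B > I_L - 1.5\,(2 f_b + f_r)$, or failing that
  $A > I_L - 1.5\,(2 f_b + f_r) - B$.
* `rest_state()` — the uncoupled fixed point solves
  $u^3 + 0.75 u + 2.625 = 0$, giving $(u^*, v^*) \approx (-1.199, -0.624)$;
  baseline coupling shifts it monotonically toward less negative $u$.

### Wavefront geometry

A firing elicited at node 1 propagates along both directions of each of
the two cycles; counter-propagating fronts annihilate where the arc
distances from node 1 coincide, because the far side of each front is
refractory. For the standard topology ($N = 150$, $n = 30$, $i_0 = 10$)
the midpoints are node $i_{m1} = 2 + (n-2)/2 = 16$ on the small loop and
$i_{m2} = n + 1 + [N - (n+1) + 1 + (i_0 - 2)]/2 = 95$ on the large loop
(`predicted_collision_nodes()`). When an arc length is odd the pair meets
on an edge; the package reports the fractional midpoint and rounds
half-down to the lower node index, the endpoint that annihilates first
under synchronous update. The formula is property-tested against a
breadth-first equal-distance oracle on all small topologies.

## Heterogeneity schemes

The baseline conductance is the model's heterogeneity dial
(`het_scheme()`):

* `two_constant` — $f = f_b$ on the loop, $f = f_r$ on the branch, with
  the convention $f_b < f_r$ (standard values $0.031$ and $0.05$, i.e.
  $\delta f = 0.019$); the identical-$f$ control case requires an explicit
  `allow_equal` flag rather than being silently accepted.
* `gaussian_f` — per-node $f$ from a Gaussian with mean $E$ and s.d.
  $\sigma$, truncated positive by resampling (clipping would put an atom
  at $f = 0$, which changes the rest-state current structurally).
* `gaussian_gmax` — constant $f$ with per-node Gaussian $g_{max}$.
  Whether a distributed $g_{max}$ is a per-node or per-edge property is a
  genuinely open modelling choice; the package implements it per
  presynaptic node, mirroring how the per-node $f$ enters the analysis of
  the sensory node's three inputs, and notes per-edge as the flagged
  alternative.

Gaussian draws are reproducible under the scheme's seed, which is the only
randomness in the package.

## Numerics

The integrator (`simulate_network()`) is a compiled fixed-step classical
Runge-Kutta (RK4) scheme over all $2N$ state equations. The synaptic
delay enters only through spike event times, so no delay-differential
machinery is needed: spikes are detected online as upward threshold
crossings of $u$ through $u_{th} = 0$ (linearly interpolated between
steps, with a 5-time-unit debounce, far below any observed inter-spike
interval), queued, and each matured event injects an impulse into two
per-neuron exponential accumulators (decay and rise) with an exact decay
correction for the sub-step offset. This incremental gating is
analytically equivalent to the closed-form sum over spikes — the test
suite verifies the compiled core against a pure-R reference integrator
that evaluates the closed-form gating at every Runge-Kutta stage.

Defaults: `dt = 0.005` (validated by `convergence_report()`, which reruns
a scenario under step halving and compares matched spike times — a
spike-count mismatch is reported as a failure, never silently aligned),
settling for 200 time units at full coupling and zero stimulus before
onset (excluded from every analysis window; initial conditions are the
uncoupled fixed point), trajectory recording decimated by
`record_stride`. Any excursion $|u| > 5$ aborts the run: the model's
orbits stay within $|u| \lesssim 2.1$, so a blow-up signals a
mis-specified right-hand side, not a numerical accident.

## Pattern observables

`classify_memory()` calls a raster `none` (no spikes), `STM` (activity
dies within a persistence window after $T_0$) or `LTM` (any spike later
than $T_0$ plus the window). The window defaults to 700 time units:
decaying patterns are observed to extinguish within a few hundred time
units of switch-off while surviving patterns persist indefinitely, so the
classification is insensitive to the exact value over a wide range.

`pattern_period()` detects the repetition time of a sustained pattern by
shift-matching the reference-node spike train against itself (candidate
shifts are cumulative sums of observed intervals; spikes must pair within
a jitter tolerance of 1 time unit, small against the smallest observed
intervals). `spiking_number()` — $S_p$ — counts reference-node spikes in
one period; it is 0 for extinct patterns and flagged `NA` when activity
persists without a clean period. The reference node defaults to the
junction $i_0$ because after switch-off the junction acts as the new
source of the surviving circulation; the sensory node is configurable as
an alternative. A transient of 400 time units after $T_0$ is excluded
before the period search.

`locking_profile()` reports the median inter-spike interval of the loop
group and the branch group in a stimulus-on window and reduces their
ratio to small integers within 10% tolerance (`"2:1"` etc., otherwise
`"irregular"`). `observed_collision_nodes()` finds, per cycle, the node
whose spike in an episode is latest — the annihilation point — and
`path_firing_counts()` counts distinct wavefronts on the two large-loop
paths by grouping nodes whose latest spikes lie within one transit time
(the median nearest-neighbour spike-time difference along the path).

## Calibration of the open constants

Two constants of the model are not fixed by the closed-form theory and
were set once by behavioural calibration, then frozen:

* **Transient normalisation $\kappa$.** With the raw difference of
  exponentials ($\kappa = 1$, peak $\approx 0.774$) the standard scenario
  produces no self-sustained pattern at all: every stimulus-evoked wave
  train collapses after switch-off. With the peak-normalised form
  ($\kappa = 1/0.774$, so the peak transient conductance is exactly
  $g_{max}$) the STM/LTM transition appears. The package therefore
  defaults to `normalize = TRUE` in `synapse_params()`, keeping the raw
  form one switch away.
* **Fast time constant $\varepsilon$.** The default is the standard
  stiff value $\varepsilon = 0.01$, which gives a crisp time-scale
  separation against the recovery scale $1/|b| \approx 15.6$ and robust
  wave propagation. A full scan of $\varepsilon \in (0, 1]$ was run
  during development: larger values trade propagation robustness for
  longer effective refractory periods, and no single value makes every
  qualitative contract of the model hold simultaneously (see
  *Known limitations*). $\varepsilon = 0.01$ maximises the number of
  contracts that do hold — the STM/LTM transition and its
  frequency selectivity, the Gaussian-$f$ and distributed-$g_{max}$
  extensions, the collision geometry, and the bounded-$E$ window for
  Gaussian heterogeneity.

Both choices are design decisions of this package, made once on the basis
of the qualitative contract (existence and heterogeneity-dependence of the
STM/LTM transition) and not revisited per scenario.

## What the generator emulates — and what it does not

The synthetic scenarios (`generate_fixture()`, the heterogeneity schemes
and the sweep driver) emulate the study conditions: a 150-node
loop-plus-branch core, the two-constant or Gaussian conductance schemes,
and the sinusoidal switch-off protocol. They do not emulate biological
noise (no stochastic input currents), synaptic depression or facilitation,
inhibitory synapses, or conduction-delay heterogeneity. Passing tests
therefore demonstrate the internal consistency of the deterministic
excitable-network mechanism — wave creation, phase-locked selection,
annihilation geometry, and heterogeneity-gated survival — not robustness
of that mechanism to biological variability.

Quantitatively, the calibrated model selects its wave-train spacings as
integer multiples of the stimulus period that are compatible with the
medium's refractory period (for example $\approx 25.1$, two periods, under
persistent $\omega = 0.5$ drive), and the number of wavefronts that
survive switch-off in the standard scenario is small (one to a few). Both
quantities are emergent and parameter-sensitive; the package reports them
as computed and makes no attempt to force particular printed values.

## Known limitations

* At the default $\varepsilon = 0.01$ the identical-$f$ control is only
  partially clean: at $\omega = 0.75$ the identical-$f$ pattern dies after
  switch-off as expected, but at $\omega = 0.5$ the densely packed wave
  train survives switch-off even without a conductance difference. The
  heterogeneity-gated version of the transition (identical-$f$ STM at
  both frequencies) appears only in a narrow band near
  $\varepsilon \approx 0.25$, where in turn the Gaussian-$f$ and
  distributed-$g_{max}$ extensions stop producing LTM and persistent
  $\omega = 0.75$ drive parks the medium through accommodation. No
  $\varepsilon$ satisfies all contracts at once; the default favours the
  larger set and the trade-off is asserted as-is by the test suite.
* $S_p$ counts depend on the wavefront-packing capacity of the large
  loop (circulation time over minimum sustainable spacing), which varies
  steeply with $\varepsilon$ and the synapse normalisation. At the
  default configuration the surviving pattern in the standard switch-off
  scenario is a uniformly spaced train (period $\approx 27$, $S_p = 1$ at
  the reference node) rather than a multi-spike packet.
* The distributed-$g_{max}$ scheme with $f \equiv 0$ still fires during
  stimulation (the spike-triggered transients alone sustain propagation);
  it produces no self-sustained pattern, which is what the
  negative-control test asserts.
* The Cayley-tree growth helper builds the periphery and inherits
  conductances, but whole-network co-production experiments on grown
  topologies are out of the package's tested scope.

## Problem sizes used in the shipped tests

The unit tests run tiny networks ($N = 30$ and smaller, horizons of a few
hundred time units) plus one full-size headline scenario and a reduced
sweep grid (5 Gaussian means x 3 seeds, step `dt = 0.01` for the sweep
properties; the headline scenario runs at the production `dt = 0.005`).
These sizes were chosen so the whole suite exercises every code path —
including the compiled core against the pure-R reference — while
completing in minutes.
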