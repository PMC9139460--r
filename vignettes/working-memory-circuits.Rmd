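---
title: "Working-memory circuits: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working-memory circuits: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmcircuit)
```

This vignette is the package's own account of the science it
implements: the feedback memory models, the mean-field population, the
redundant storage bank, the storage distribution network (SDN), and the
behavioural readouts — together with the numerical and design choices
that were genuinely open, and what the simulations do and do not show.

## Single-unit feedback memory

A cortical memory trace must outlive the membrane leak. The package's
smallest model is a linear rate unit with recurrent positive feedback,

$$\tau \frac{dr}{dt} = -(1 - W_{pos})\,r + I(t),$$

whose behaviour is organised entirely by $W_{pos}$: exact holding at
$W_{pos} = 1$, exponential decay below, exponential growth above. The
negative-derivative mechanism arises from an E/I pair with a common
input but different decay strengths,

$$\tau \dot r_E = -W_{pos} r_E + I(t), \qquad
  \tau \dot r_I = -W_{der} r_I + I(t),$$

whose difference $r_E - r_I$ approximates the (negated) time derivative
of the stored signal when the inhibitory pathway is the faster one. The
hybrid (HPNF) unit feeds back both the rate and its derivative,

$$\tau \dot r = -r + W_{pos} r - W_{der} \dot r + I(t).$$

The derivative appears on both sides; we resolve it algebraically
before integration,

$$(\tau + W_{der})\, \dot r = -(1 - W_{pos})\, r + I(t),$$

so the effective time constant under subcritical feedback is
$(\tau + W_{der})/(1 - W_{pos})$. Two consequences worth naming. First,
$W_{der}$, though introduced as a synaptic strength, enters the
rearranged equation as a time-like quantity added to $\tau$ (ms); we
treat it as such throughout. Second, with $W_{pos}$ mistuned by 10%,
raising $W_{der}$ from 0 to 100 stretches the drift time scale from
200 ms to 1.2 s — this robustness to mistuning is the reason the hybrid
unit, not the bare positive-feedback unit, is the building block of the
storage network.

These three models are kept *linear* (no rectification): doubling the
input doubles the trace, which the test suite exploits. Rectification
enters only through the population transfer function below.

## Mean-field population and transfer function

One NSSU ("neural signal self-sustaining unit") is an E/I population
with six state variables: rates $r_E$, $r_I$ and synaptic activations
$s_{EE}, s_{EI}, s_{IE}, s_{II}$,

$$\tau_E \dot r_E = -r_E + f(J_{EE} s_{EE} - J_{EI} s_{EI}
  + J_{EO}\, i(t)),$$
$$\tau_I \dot r_I = -r_I + f(J_{IE} s_{IE} - J_{II} s_{II}),$$
$$\tau_{xy} \dot s_{xy} = -s_{xy} + r_y .$$

We index synapses target-first: $s_{EI}$ sits on the excitatory
population and relaxes toward the *inhibitory* rate, as the relaxation
equation requires. The kinetic asymmetry — $\tau_{EE} = 100$ ms
(NMDA-dominated recurrence) against 10 ms pathways through the
interneurons — is what converts balanced excitation and inhibition into
negative-derivative feedback at the population level.

The steady-state transfer is a thresholded Naka–Rushton function,

$$f(x) = M \frac{(x - x_\theta)^2}{x_0^2 + (x - x_\theta)^2}
  \, h(x - x_\theta),$$

with $M = 100$, $x_\theta = 30$, $x_0 = 30$ and the Heaviside
convention $h(0) = 0$, so $f(x_\theta) = 0$ exactly, $f$ is monotone,
and $f \le M$ everywhere. The denominator form was chosen so that
$x_\theta$ really is an input threshold and $x_0$ really is a
half-activation parameter ($f(x_\theta + x_0) = M/2$); no other reading
gives those constants their stated roles.

Default parameters (all dimensionless except time constants in ms):

| parameter | value | meaning |
|---|---|---|
| $\tau_E$, $\tau_I$ | 20, 10 | population time constants |
| $\tau_{EE}, \tau_{EI}, \tau_{IE}, \tau_{II}$ | 100, 25, 10, 10 | synaptic time constants |
| $J_{EE}, J_{EI}, J_{IE}, J_{II}$ (intra) | 300, 450, 900, 900 | coupling within an NSSU |
| $J_{EE}, J_{EI}, J_{IE}, J_{II}$ (inter) | 150, 300, 600, 600 | coupling between NSSUs |
| $J_{EO}$ | 3000 | external-input gain, admissible range 0–6000 |
| $M$, $x_\theta$, $x_0$ | 100, 30, 30 | transfer function |

$J_{EO}$ has no single stated value, only the range; we fix the
midpoint 3000 once as the default and use a unit-amplitude 200 ms pulse
as the standard storage stimulus. Stimulus noise, when enabled, is
additive Gaussian per time step with its own seed, scaled by $J_{EO}$
like the deterministic input; the default protocols are noiseless and
therefore fully deterministic.

## Integration scheme

All simulators use forward Euler, dt = 0.1 ms by default (single-unit
models require dt ≤ τ/10, populations dt ≤ min(τ)/5). Explicit Euler is
the conventional choice for rate models and makes traces bit-for-bit
reproducible; a classical RK4 integrator (via deSolve) serves as the
*independent oracle in the test suite only*, never as the
implementation. Two numerical facts the tests document:

* For the single-unit linear models, Euler converges to the RK4
  reference at first order, and the balanced case $W_{pos} = 1$ holds
  the post-offset rate *exactly* (the update increment is identically
  zero), so the 10-second holding check passes with zero drift.
* The engaged mean-field population is only piecewise smooth: the
  transfer threshold turns the post-stimulus dynamics into relaxation
  oscillations, and the crossing times of *any* two integrators drift
  apart, flooring pointwise trajectory error at a few percent
  regardless of step size. Euler-vs-RK4 agreement is therefore asserted
  on the smooth driven transient (50 ms), where it is well under 1% at
  dt = 0.01 ms; over multi-burst horizons only qualitative agreement is
  meaningful.

## The SET storage bank

A SET couples $n$ NSSUs (2–12) all-to-all: within a unit the intra
strengths apply, between units the weaker inter strengths, each acting
through the partner's synaptic variables. The *basic unit* (the fifth,
by convention; the last for banks smaller than five) receives the
external stimulus; backups receive it only through the coupling. A
build-time flag can instead broadcast the stimulus to every unit.

Stability of a storage run is assessed on the mean excitatory rate:
stable ⇔ the mean over the final 10% of the run differs from the mean
over the preceding 10% by less than 2% (relative), *and* the plateau
exceeds an activity floor of 1 rate unit — the floor prevents a network
that has simply collapsed to rest from counting as "stably storing".
The default horizon is 2000 ms with the stimulus in the first 200 ms.

An honest limitation must be stated here. Under the default coupling
strengths, inhibition onto the excitatory population exceeds excitation
at every bank size (450 > 300 intra, 300 > 150 inter, with the
inhibitory population tracking $r_E$ tightly through $J_{IE}, J_{II}
\sim 900$). A fixed-point analysis of the symmetric bank shows the only
attractor is rest, and numerically every $n$ in 2–12 collapses within
about 1.5 s of stimulus offset. The bank therefore *slows* decay — the
disturbance analysis below shows the redundancy doing real work — but
no bank size reaches a persistent plateau under these printed
parameters, and the bank-size sweep reports no minimal stable count.
The package implements the sweep and its criterion faithfully and
leaves the discrepancy visible rather than re-tuning the couplings.

**Disturbance protocol.** A perturbation scales one coupling pathway
(both its intra and inter strengths) by $1 + m$ (default $m = 5\%$)
for a rectangular window covering 2% of the horizon, after storage. We
measure the *deviation*: the maximum absolute difference between the
perturbed and the twin unperturbed mean-rate trajectories from
perturbation onset onward. Defining deviation against the unperturbed
twin (rather than against a pre-onset snapshot) makes the identity
perturbation score exactly zero even on a drifting baseline. *Recovery*
holds when the perturbed run's final plateau matches the unperturbed
one within 2% relative, with an absolute floor of one rate unit on the
reference so that near-rest trajectories are compared on an absolute
band. Under the defaults, larger banks damp disturbances: the measured
deviation at $n = 8$ is below that at $n = 4$ for every pathway, and
all four pathways recover at $n = 8$.

## The storage distribution network

The SDN is a fixed selector circuit: input cell E00 fans out to four
branches of pyramidal relay cells (E11–E12; E22–E23; E32–E33–E34;
E42–E43–E44–E45), each ending in a gate cell that activates one of four
SET handles. Guard interneurons (I11, I21, I31) enforce winner-take-all
within a routing event; lock interneurons (I12, I22, I32, I41), fired
by the gates, silence the guards and close used branches so successive
stimuli walk the branches in order, the fifth wrapping back to the
first branch.

The wiring is specified qualitatively (which cell inhibits which), not
quantitatively, so the package offers two abstraction levels:

* **logic mode** (default): nodes are binary threshold units and a
  routing event is resolved by a deterministic causal cascade in branch
  order, with interneuron effects applied immediately. Fast, exactly
  testable.
* **rate mode**: every node is a leaky firing-rate unit with
  Naka–Rushton transfer (interneurons faster than pyramidal cells,
  τ = 5 vs 10 ms); the winner is the first gate to cross a rate
  threshold. This demonstrates the same selection sequence emerging
  from continuous dynamics. Nodes are single rate units rather than
  full six-variable populations — the selection logic depends only on
  relative timing and dominance, not on synaptic filtering.

Weights must satisfy *inhibition dominance*: wherever the narrative
says a cell "is inhibited", the inhibitory weight must exceed the
excitatory drive converging on that cell; `build_sdn()` rejects any
configuration violating a constraint, naming the edge.

Two wiring decisions deserve a note. The lock interneuron I32 also
silences its own gate E34 (the published edge lists give this role to
I12, I22 and I41 for the other branches and describe E34 as having
"the same effect"); without it branch 3 would be re-selected on the
fourth stimulus. And tonic (between-stimulus) locking is tied to
*occupancy*: each occupied branch's lock holds its own gate down and
silences other interneurons, while cross-branch inhibition of gate
cells acts only within a routing event. Otherwise a SET freed by
forgetting would be unreachable, contradicting the storage rule that a
free SET is always chosen first.

**Storage, decay, forgetting.** A stored item's rate starts at the
stimulus amplitude (default 50) and decays under the closed-form HPNF
solution with marginally subcritical feedback — defaults τ = 20 ms,
$W_{der} = 100$, $W_{pos} = 0.999$, giving an effective time constant
of 120 s. The closed form is exact for the linear unit, so long
retention intervals cost nothing to simulate and decay is strictly
monotone between rehearsals. An item is *forgotten* (SET freed, event
logged at the exact crossing time) when its rate falls below 10% of
the storage plateau; re-presenting a held feature re-selects its SET
and resets the rate to the plateau ("memory retelling"). With all four
SETs occupied, a new item replaces the one with the lowest current
rate, ties broken by earliest store time — under equal amplitudes and
no rehearsal this is exactly first-in-first-out, which the test suite
verifies against an independent discrete-event oracle on randomized
schedules.

## Behavioural readouts

Recall probability is a logistic function of the normalized rate,
$p = 1/(1 + e^{-k(r/r_{plateau} - c)})$ with $k = 10$, $c = 0.5$,
clamped to 0 at the forgetting threshold. The mapping from rate to
behaviour is not specified by the underlying theory; any monotone link
preserves every asserted trend, so the particular sigmoid is a
convenience. The five experiment protocols use conventional pacing
(200 ms character + 800 ms blank for sequence recall; 1 s words at 2 s
onsets for the serial-position list; a 906 ms retention blank for
change detection) and a single standard amplitude.

Association and binding are conjunctions: one SDN per feature channel
(identity + position; colour + shape + their conjunction), items
recallable only when every required channel is above threshold, so
binding performance can never exceed single-feature performance.
Rehearsal in the serial-position experiment covertly re-presents the
earliest list positions (default 1–2) during each inter-word gap: those
items stay at plateau, escape eviction, and produce a primacy limb,
while the recency limb arises from decay + FIFO alone. Rehearsing early
items necessarily displaces middle items — the improvement guarantee
applies at the rehearsed positions.

## What the simulations do and do not show

The stimulus generator produces rectangular, noiseless (by default)
current pulses with exact timing; real sensory drive is none of those
things. Passing trend tests therefore shows that the circuit logic —
capacity, eviction order, refresh, conjunction readout, rehearsal
benefit — follows from the model's structure, not that the model
quantitatively fits behavioural data; no published behavioural curve is
fit or compared numerically. Problem sizes were chosen at desk scale:
2000 ms storage runs at dt = 0.1 ms, bank sizes 2–12, schedules of a
dozen events, five random schedules per property test under a fixed
seed.

Known limitations, collected: the printed coupling strengths give the
storage bank no persistent attractor (see above); pointwise Euler/RK4
agreement is limited to smooth phases by threshold-crossing phase
drift; SDN synaptic weights are abstract (dominance-constrained, not
fitted); and the rate-to-probability link is a modelling convenience.
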