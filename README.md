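# wmcircuit

Firing-rate simulators for circuit-level models of working memory (WM):
how a cortical circuit can hold a handful of items "online" for seconds,
refresh them by rehearsal, and forget them — first gradually, then
completely — without any synaptic learning.

The package is aimed at computational neuroscientists and students who
want a small, fully inspectable rate-model stack: every equation is a
plain forward-Euler recursion over explicit state variables, every
experiment is a deterministic schedule of current pulses, and every run
is reproducible from a config file and a seed.

## The models

**Single-unit feedback memory.** A leaky rate unit with recurrent
positive feedback,

τ dr/dt = −(1 − W_pos) r + I(t),

holds its post-stimulus rate exactly when W_pos = 1, decays when
W_pos < 1 and diverges when W_pos > 1. A parallel excitatory/inhibitory
pair driven by the same input,

τ dr_E/dt = −W_pos r_E + I(t),  τ dr_I/dt = −W_der r_I + I(t),

yields, via the difference r_E − r_I, a negative-derivative feedback
signal. The hybrid (HPNF) unit combines both,

τ dr/dt = −r + W_pos r − W_der dr/dt + I(t),

equivalently (τ + W_der) dr/dt = −(1 − W_pos) r + I(t): derivative
feedback stretches the effective time constant to
(τ + W_der)/(1 − W_pos), so a mistuned W_pos causes only slow drift.

**Mean-field population (NSSU).** Each neural signal self-sustaining
unit is an E/I population with six state variables (two rates, four
synaptic activations), Naka–Rushton steady-state transfer
f(x) = M (x − x_θ)² / (x_0² + (x − x_θ)²) · h(x − x_θ), slow E→E
kinetics (100 ms) and fast inhibitory kinetics (10 ms).

**SET storage bank.** n parallel NSSUs (one *basic* unit receiving the
stimulus, the rest *backups*) coupled all-to-all with weaker inter-unit
strengths; protocols sweep the bank size for plateau stability and
probe robustness with transient coupling disturbances.

**Storage distribution network (SDN).** A selector circuit of pyramidal
cells and interneurons routes each stimulus to exactly one of four SETs
(winner-take-all), locks used branches, refreshes a re-presented item in
place, and — when all four SETs are occupied — evicts the item with the
lowest firing rate, which under pure decay is the oldest (FIFO
forgetting). Stored items decay under marginally subcritical HPNF
dynamics and are totally forgotten at 10% of their storage plateau.

**Experiments.** Stimulus schedules and a logistic rate-to-probability
readout reproduce, at trend level, delayed-response forgetting,
number–position association, last-three-letter recall with updating,
colour–shape binding, and the serial-position curve with and without
rehearsal.

## Worked example

Six distinct items presented 500 ms apart against a four-SET capacity:

```r
library(wmcircuit)
st <- build_sdn()
for (k in 1:6) {
  st <- advance_time(st, 500)
  st <- present_stimulus(st, paste0("f", k), 50)
}
sdn_events(st)
#>      t   event feature_id set_id     rate
#> 1  500  stored         f1  set11 50.00000
#> 2 1000  stored         f2  set21 50.00000
#> 3 1500  stored         f3  set31 50.00000
#> 4 2000  stored         f4  set41 50.00000
#> 5 2500 evicted         f1  set11 49.17357
#> 6 2500  stored         f5  set11 50.00000
#> 7 3000 evicted         f2  set21 49.17357
#> 8 3000  stored         f6  set21 50.00000
```

The first four items fill the four SETs in branch order; the fifth and
sixth evict the earliest-stored (weakest) items, so the held count never
exceeds four. Forgetting over longer delays shows up as a monotone drop
in recall probability:

```r
run_delay_experiment(c(0, 500, 2000, 6000, 300000))$grid
#>   delay_ms  recall_p     rate rate_spread
#> 1    0e+00 0.9933071 50.00000    50.00000
#> 2    5e+02 0.9930250 49.79210    49.79210
#> 3    2e+03 0.9921137 49.17357    49.17357
#> 4    6e+03 0.9891458 47.56147    47.56147
#> 5    3e+05 0.0000000  0.00000     0.00000
```

(at 300 s the trace has crossed the forgetting threshold: total
forgetting, recall probability 0).

A command-line front end over the same functions lives in
`inst/cli/wmcircuit.R` (subcommands `simulate-unit`,
`simulate-population`, `sweep-nssu`, `perturb`, `run-sdn`,
`run-experiment`).

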