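---
title: "The phase-ternary pulse model and its simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The phase-ternary pulse model and its simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnet)
```

## The model

capnet simulates action potentials as *computational* pulses: each pulse is
a ternary signal in time, with resting membrane as 0, the all-or-none
threshold front as +1, and the analog refractory tail as −1 for a duration
τ behind the front. The front travels at the local conduction velocity *v*
and carries a scalar soliton energy budget *E* that dissipates linearly
with distance (*E*~d~ = *E* − *e*, floored at zero). Everything the
simulator does follows from four interaction rules:

1. **Head-on annihilation.** Two fronts approaching each other on one
   segment meet where their linear trajectories cross and both die. A
   threshold front cannot cross the refractory zone trailing the opposing
   front, and by symmetry neither survives. `resolveHeadOn()` computes the
   meeting analytically; the engine never lets two opposing fronts pass
   through each other.
2. **Junction gating.** Each node where at least two afferent segments
   converge keeps a refractory memory: the time the threshold last passed,
   and the τ it left behind. A new arrival with delay Δ since that passage
   is classified by `resolveNodeArrival()`: Δ ≤ tol → **MERGE** (in-phase
   arrivals map together; the earlier pulse continues), tol < Δ < τ →
   **ANNUL** (occlusion by the trailing refractory period), Δ ≥ τ →
   **PASS**.
3. **Phase diffraction.** A pulse that passes a node is copied down every
   outgoing segment, each copy carrying the parent's residual energy.
   Energy is a viability token, not a conserved fluid: the pulse
   regenerates at each channel, so branching does not split it.
4. **Energy-limited propagation.** On arriving at the far node of a
   segment of length *L* with dissipation rate *r*, the pulse's residual is
   `max(E − r·L, 0)` and is checked against that segment's activation
   threshold (boundary inclusive: residual exactly at threshold
   activates). Failure emits `PULSE_FAILURE` and kills the pulse —
   insufficient channels along a stretch mean the pulse cannot trigger the
   next ones.

## Parameters and defaults

| parameter | units | default | why |
|---|---|---|---|
| `velocity` | m/s | 1.0 | conduction maximum for small unmyelinated fibres |
| `refractoryDuration` (τ) | s | 2e-3 | typical absolute refractory period; only the absolute window is modelled |
| `channelSpacing` | µm | 1.5 | the minimum spacing resolvable by single-channel patch recording |
| `dissipationRate` | energy/µm | 0 | energy modelling is opt-in; lossless by default |
| `activationThreshold` | energy | 0 | idem |
| `mergeTolerance` | s | spacing/velocity | the membrane's own temporal accuracy (1.5 µs at defaults); configurable via `runConfig()` |
| `initialEnergy` | energy | 1 | arbitrary unit; only ratios to thresholds matter |

Velocity in m/s is numerically µm/µs, which keeps segment lengths in µm
and times in seconds consistent (`transit = length / (v·10⁶)`).

Only the velocity and the spacing are quantified measurements; the other
defaults are explicit modelling choices and every experiment that depends
on them takes them as arguments.

## Where the refractory gate applies

The occlusion rule is implemented as a *junction* phenomenon: the gate is
evaluated only at nodes with in-degree ≥ 2, where pulses from distinct
afferent fibres can actually meet. Three consequences, all deliberate:

- **Stimuli are taken as given.** An entry node represents the boundary of
  the modelled network; its schedule is assumed to be a physically
  realizable spike train on each afferent, so spawning is not gated. A
  trailing spike closer than τ to its predecessor *on the same fibre*
  could not have been initiated in reality; the package does not second-
  guess the schedule, it simulates what was injected.
- **Same-direction pulses on one segment do not interact.** With uniform
  velocity per segment their separation is constant, so a trailing pulse
  that could exist at injection still exists at the far node. Any
  occlusion it should suffer happens where pathways actually converge.
- **Pass-through nodes (in-degree 1) relay without gating.** This is what
  makes a single chain redaction-free: nothing converges, so nothing is
  annulled, and the redaction fraction of noise on a chain is exactly 0.
  Redaction is a property of parallel structure, not of propagation.

An alternative reading — applying the refractory gate at every node —
would annul any trailing spike within τ anywhere, making even an isolated
fibre a perfect noise filter and erasing the distinction between serial
and parallel structure that the redaction experiments exist to measure.

## The event-driven engine and its oracle

`simulatePulses()` processes a priority queue of stimuli, analytically
computed head-on meetings, and node arrivals, ordered by time with a
deterministic tie-break (stimuli, then meetings, then arrivals in pulse-id
order). Outcomes at a junction are order-independent: simultaneous
arrivals within the merge tolerance merge regardless of processing order.
Identical inputs give byte-identical canonical logs; there is no hidden
randomness in the engine itself.

Every run satisfies, exactly,
`spawned = exited + annihilated + annulled + merged + failed + active`:
each pulse is assigned exactly one fate (or is still in flight at the
horizon). With all stimuli at t = 0, doubling every segment velocity
exactly halves every event time; with nonzero stimulus times the law
applies to the travel-time component only, since stimulus times are
inputs, not dynamics.

`oracleSimulate()` is an independent check: it advances every front by
`v·dt` per step and detects arrivals and crossings by interval overlap,
applying the same interaction rules. Overshoot past a node is carried onto
the next segment so the timing error stays below `dt` regardless of how
many nodes a pulse crosses. The test suite replays randomized small graphs
(≤ 10 nodes) through both engines and requires identical event sequences
with times within `dt`. Test scenarios use segment lengths and stimulus
offsets whose event separations are far larger than `dt`, so event order
is unambiguous; the oracle warns when `dt` exceeds a tenth of the fastest
segment transit.

## Synthetic networks and what they do (not) emulate

The generators produce the motifs the model's claims are about: parallel
ladders (`generateLadder()`, one entry fanning into n parallel limbs that
reconverge at each of n~layers~ junctions), two-entry collision edges,
chains, and binary trees. Optional Gaussian length jitter desynchronises
parallel limbs. SWC morphology import maps reconstruction samples to nodes
and parent links to segments with Euclidean lengths; the radius column is
ignored because the model has no radius–velocity law — conduction velocity
is a segment parameter.

These are idealized structures: uniform dynamics per segment, noiseless
conduction times, point-like junctions with a single-slot refractory
memory (only the latest passage is remembered, which is sufficient while
inter-spike intervals exceed τ but is a documented limitation for
high-rate input). Passing tests on these motifs demonstrates the collision
algebra, not biological realism: real neurites have distributed channel
densities, relative refractory periods modulated by inhibition, and
branch-point geometries none of which are modelled.

## Noise redaction

`runRedactionExperiment()` drives a ladder with a periodic signal train
plus injected noise and reports
`redaction fraction = 1 − noise exits / noise injected`. Choices made:

- *Out-of-phase* noise means offsets inside the open window (tol, τ)
  relative to the preceding signal spike. For such noise on limbs of equal
  length the gate at the first junction annuls every copy, so the fraction
  is exactly 1 at every depth ≥ 1 — the exhaustive offset sweep and the
  paired-seed depth comparison in the tests confirm both the value and its
  monotonicity in depth.
- *In-phase* noise (offset ≤ tol) merges with the signal. The mechanism
  cannot distinguish it from signal by construction, so it is reported
  separately (`noiseMerged`), not counted as a redaction failure; it never
  produces a duplicate exit either, since merging absorbs it.
- The signal period defaults to 5τ so the signal never self-occludes and
  the redaction effect is isolated.
- Poisson noise (`injectNoise()`, homogeneous per entry node, seeded) is
  also available; offsets that land outside every refractory window simply
  propagate, which is honest behaviour for a mechanism that only deletes
  out-of-phase events. A dispersion metric (sd of successive terminal
  inter-arrival intervals) is emitted for synchronization analyses, with
  no claimed target value.

## Feasibility arithmetic

- Diffusion time uses the 1-D mean-squared-displacement relation
  `t = x²/(2D)` — the most conservative (fastest) spreading estimate, so
  the resulting speed limit errs in favour of the diffusion hypothesis.
  The default D = 1.33×10⁻⁹ m²/s is the handbook value for Na⁺ in water at
  25 °C, configurable.
- The effective charge speed is `x / t = 2D/x`, strictly decreasing in
  spacing, so the verdict "insufficient" at the 5 µm upper end holds a
  fortiori across the whole 1.5–5 µm range (asserted in the tests).
- The Moens–Korteweg velocity is implemented in its textbook form
  `PWV = √(E·h/(ρ·d))`, the standard statement of the square-root
  dependence on the wall's elastic modulus.
- The report states its own parameter choices alongside the ratio, since
  the headline "< 1/1000" depends on spacing, D, and the required speed.

## Numerical conventions

- Refractory windows are half-open `[0, τ)`: an arrival exactly τ after
  the last passage passes. Energy thresholds are inclusive: residual
  exactly at threshold activates. Both conventions avoid double-counting
  at boundaries and are asserted in the tests.
- Head-on meetings are scheduled only strictly inside a segment; a meeting
  exactly at a node is handled by the node gate instead.
- The native JSON graph format is canonical (rows sorted by id, fixed
  column order, full-precision floats), so write → read → write is
  byte-identical and graphs round-trip exactly.
- Problem sizes in the test suite are deliberately small — motifs of 2–10
  nodes, 20 randomized oracle comparisons, 100 paired seeds for the depth
  comparison, 200 seeds for the Poisson-mean check — chosen so the full
  suite documents the model's behaviour in a few seconds while still
  exercising every rule.

## Known limitations

- Only the absolute refractory period is modelled; there is no relative
  refractory period and no synaptic (IPSP) prolongation of τ.
- Node memory holds one passage; bursts with intervals below τ at a
  junction are resolved against the latest passage only.
- A pulse blocked from one daughter branch is routed to the others with no
  added delay; whether rerouting at a refractory branch point costs time
  is an open interpretation, and zero delay is the simplest reading.
- Energy is per-pulse and branch copies inherit it undivided; there is no
  sub-threshold summation, no graded potentials, and no ionic state beyond
  the energy scalar.
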