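---
title: "The circular respiratory model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The circular respiratory model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songcircuit)
```

## The model and its assumptions

`songcircuit` simulates a four-population additive rate network of the
songbird respiratory motor pathway. Each population carries a dimensionless
mean activity $x_i \in (0,1)$ obeying

$$\frac{dx_i}{dt} = r_i\left(-x_i + S\!\big(\rho_i + \textstyle\sum_j a_{ij}
x_j + \text{drives}_i(t)\big)\right), \qquad S(x) = \frac{1}{1+e^{-x}},$$

the usual mean-field abstraction in which more excitatory input makes a
population more active, synaptic transmission delays between directly
connected nuclei are neglected, and spiking structure is not represented.
The four populations are the expiratory-related pair ER$_e$/ER$_i$ (ER$_e$
is the proxy for air-sac pressure; the pair most plausibly maps to RAm) and
the RA pair RA$_e$/RA$_i$. Three square-pulse drives of height 10 enter the
network: $F(t)$, a brainstem initiating-area burst driving ER$_e$ directly,
and $F_d(t)$, $F_{d2}(t)$, HVC bursts driving RA, which relays a processed
copy of the same command back to ER. HVC's internal dynamics are
deliberately not modelled — its bursts are inputs, which is what makes the
cooling experiment expressible as a pure transformation of the drive
schedule.

The ER pair's fixed wiring (biases $-7.5$, $-11.5$; weights $+10$, $-10$,
$+10$, $+2$) makes it bistable over a range of constant RA input
$\rho' = \alpha_{eer,ra}\, e_{ra}$: an "off" branch near 0 and an "on"
branch near 0.98 coexist for $\rho'$ roughly between 1.5 and 4.3
(`find_equilibria()` exposes this structure). The pattern mechanisms all
live on this skeleton:

* **P0** — the 20 ms IA pulse produces the brief leading pressure peak; the
  10 ms HVC burst drives RA$_e$ to $\approx 0.44$, just below its own
  saddle at 0.5, so RA output decays slowly. Its peak input
  $\rho' \approx 4.4$ exceeds the ER fold: the off state disappears, ER
  latches onto the on plateau and stays there while RA decays, ending
  abruptly when $\rho'$ drops below the fold — the long gesture with slow
  decay and abrupt end.
* **P2** — identical ER couplings, but the weaker RA parameters peak at
  $\rho' \approx 3.9 < 4.3$: RA is not strong enough to remove the off
  state, and its contribution remains a small second lobe below the P0
  plateau.
* **pulsatile / P1** — the ER motif itself oscillates under sustained RA
  input. For pulsatile parameters a brief HVC kick sends RA$_e$ on a slow
  self-sustained climb to its high fixed point (0.97) while ER already
  oscillates: fast small ripples on a rising DC. For P1 the long (140 ms)
  saturating HVC burst pins RA$_e$ near 1 first; the oscillation then runs
  at constant amplitude until $F_{d2}$ recruits RA$_i$ and shuts the
  segment down. The interval between $F_d$ and $F_{d2}$ onsets *is* the
  pulsating-segment duration.
* **cooling** — stretching the HVC bursts (+15 ms) lengthens RA's active
  period (stretching); additionally delaying them (+5 ms) widens the gap
  between the decaying direct pulse and the rising telencephalic lobe, so
  the interior minimum falls through the phonation threshold and the
  gesture breaks in two.

## Rate constants: the one genuinely open parameter

The model's printed prefactors are typographically ambiguous (collapsed
fractions). `rate_constants()` exposes three parses; the package default is
`"fast"`: $r_{er} = 1/4.95$ ms$^{-1}$ ($\tau_{ER} \approx 5$ ms) and
$r_{ra} = 1/20$ ms$^{-1}$ ($\tau_{RA} = 20$ ms). The reasoning, from a
systematic scan of $(\tau_{ER}, \tau_{RA})$ against the full phenomenology:

* A *literal* reading (149.5 and 20 per ms) makes both areas equilibrate in
  well under a millisecond: activities slave to the sigmoids, traces become
  square, and RA shows no exponential decay. Nothing works.
* A *reciprocal* reading ($\tau_{ER} = 49.5$ ms, $\tau_{RA} = 20$ ms)
  preserves RA's pulse response but makes the ER motif an order of
  magnitude too slow: its oscillation period is 270–600 ms (canary
  pulsatile ripples are tens of Hz), P0 never reaches the on plateau, no
  interior minimum forms, and no cooling perturbation of the published
  size breaks the pattern.
* With $\tau_{ER} \approx 5$ ms — the printed digits with the decimal
  shifted one place — every published phenomenon appears at the published
  pulse widths and delays: pulsatile ripple at ~37 Hz, P1 at ~17 Hz, P0's
  peak–minimum–plateau shape, P2 sub-fold, and the cooling dichotomy at
  exactly (+15 ms, +5 ms). The ~200 s$^{-1}$ rate is ordinary for this
  model family.

Millisecond-scale structure (the 5 ms cooling delay mattering at all, the
22 ms P2 interval producing a visible relative minimum) requires the ER
response time to be commensurate with those intervals; that is the physical
content of the choice. The other parses remain selectable for comparison.

## Drive-schedule parameters

| parameter | default | status |
|---|---|---|
| pulse height | 10 (arb.) | published, all pulses |
| F width | 20 / 50 / 20 / 40 ms (P0/pulsatile/P2/P1) | published |
| Fd width | 10 / 20 / 10 / 140 ms | P0, P1 published; others chosen (HVC bursts are 10 ms; the pulsatile kick uses 20 ms) |
| Fd2 width | 20 (pulsatile) / 100 (P1) ms | P1 published |
| `d_total` | 26 ms (P2: 22 ms) | see below |
| `segment_duration` | 300 ms | chosen: gives ~11 pulsatile and ~5 P1 cycles |

`d_total` lumps the unmeasured brainstem→thalamus→HVC leg with the known
10 ms HVC→RA conduction delay. Only their sum affects the dynamics. The
default 26 ms (i.e. a 16 ms thalamic leg) was fixed once from the same
scan: it yields a normal P0 whose interior minimum sits at ~0.42 of the
maximum — clearly above the 10 % phonation threshold, but close enough
that the published +5 ms cooling delay pushes it through. P2's total of
22 ms is published and used verbatim. All schedule parameters are
overridable per run.

## Numerics

* **Integrator** — classical fixed-step RK4, default `dt = 0.05` ms,
  written in the package rather than delegated: the drives are
  discontinuous squares, and the final stage (at $t+h$) samples their
  *left* limit, so the forcing is constant within any step whose interior
  contains no pulse edge. With edges on the grid the scheme keeps its full
  fourth order (observed order ≈ 4.0 on the P0 preset); an edge interior
  to a step costs one locally first-order step, bounded by `dt`. A test
  cross-checks the integrator against `deSolve::ode(method = "rk4")` on a
  smooth (constant-drive) problem. Everything is deterministic —
  bit-identical across runs.
* **Initial condition** — the presets start from the resting state reached
  after 500 ms of drive-free integration from the origin (`init = "rest"`);
  `"origin"` and explicit states are available.
* **Equilibria** — damped Newton with numerical Jacobian from a
  $4^4$ grid of starts; residual tolerance $10^{-10}$, merge radius
  $10^{-6}$, sorted by $e_{er}$. Rates scale the vector field but not its
  zeros, so equilibria are rate-invariant (tested). The test suite
  confirms the roots against an exhaustive residual scan of $[0,1]^4$ at
  resolution 0.01; the scan also flags slow-manifold regions, which is why
  the confirmation runs root → scan, not the reverse.
* **Sigmoid** — argument clamped to ±700 before exponentiation; at model
  scales ($|x| < 400$) the clamp is inert.

## Feature extraction

All thresholds are fixed constants committed with the package, not fitted:

* **Extrema** — topographic prominence (height above the higher flanking
  key saddle), default 0.02 activity units to suppress grid ripple;
  alternation of maxima and minima is enforced by restoring the opposite
  turning point between same-kind neighbours.
* **Phonation threshold** — 10 % of the trace's global maximum. The
  concept is physiological but no value is published; a relative threshold
  keeps pulse segmentation meaningful across amplitude conventions. Pulses
  shorter than 2 ms are discarded.
* **Dominant period** — median inter-maximum interval in a window.
* **RA amplitude trend** — the preset RA traces are monotone saturating
  transients with no interior maxima, so the maxima-height regression is
  undefined on them and raw-series slopes cannot separate pulsatile from
  P1 (the ramps are similar). The statistic therefore samples $e_{ra}$ at
  the times of the prominent $e_{er}$ maxima — the RA drive behind
  successive expiratory pulses. Pulsatile's ER oscillates while RA still
  climbs (increasing); P1's oscillation only starts once RA has saturated
  (constant). Relative change within ±0.1 over the window counts as
  constant; traces with their own maxima (e.g. the decaying-train fixture)
  use those directly.
* **Classifier** — fixed rules: ≥ 4 major maxima (≥ 50 % of max) with
  interval CV ≤ 0.35 is oscillatory, split pulsatile vs P1 by whether the
  cycle minima stay above 20 % of the maximum (ripple riding a sustained
  expiration) or return near baseline; otherwise a two-lobe pulse is P0
  when the lobe after the interior minimum lasts ≥ 2.5× the leading lobe,
  else P2; near-silent traces are unknown. The four presets map to their
  own labels (regression-tested); the classifier is a heuristic over
  simulated traces, not a validated classifier of recorded pressure data.

## Synthetic fixtures

`generate_fixture()` produces analytic traces — sines, a raised-cosine
bump pair with exactly known peak/valley levels, and an exponentially
decaying arch train — whose extrema, periods and trends are known in
closed form. They exercise the feature operators; they do not emulate
recorded air-sac pressure (no measurement noise, no baseline drift, no
inspiratory undershoot), so passing feature tests demonstrates correctness
of the operators, not robustness on experimental recordings.
`read_pressure_series()` linearly resamples non-uniform recordings to
their median step and optionally min-max normalises them; recorded
pressure units are arbitrary.

## Problem sizes

Default runs integrate 600 ms (P0, P2) or 800 ms (pulsatile, P1) at
`dt = 0.05` ms (12 001–16 001 points). The randomized boundedness check in
the acceptance script integrates 50 configurations for 1 s each at
`dt = 0.1` ms; the test suite uses the same generator with 100 draws.

## Known limitations

* The rate-constant parse is a reasoned reconstruction, not a published
  value; the reciprocal and literal parses are provided for scrutiny.
* Only the sum of the two processing delays is constrained by the
  dynamics; the split between the thalamic and HVC→RA legs is a
  convention.
* No periodic HVC drive trains: the P1/pulsatile mechanism here uses a
  single sustaining burst, and cooling-induced *stretching of oscillatory
  patterns* via slowed periodic HVC forcing is out of scope.
* Bilateral syringeal mechanics, sound synthesis, and classification of
  recorded (as opposed to simulated) pressure patterns are out of scope.
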