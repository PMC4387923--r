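# songcircuit

Canaries (*Serinus canaria*) build their song from four stereotyped air-sac
pressure patterns: **P0** (a long expiratory gesture with a brief leading
peak), **P1** (near-harmonic oscillations), **P2** (double-length pulses with
an interior minimum), and **pulsatile** (fast small ripples riding a
sustained expiration). `songcircuit` implements a *circular* (rather than
top-down) rate model of the respiratory motor pathway in which an
expiratory-related brainstem area reproduces these patterns from two inputs:
a direct square-pulse command from a brainstem initiating area (IA), and a
delayed copy of the same command processed by the telencephalic song nuclei
(HVC and RA). The package is for computational neuroscientists studying
birdsong motor control, central pattern generation, or pulse-driven
excitatory–inhibitory circuit motifs.

## The model

Each of four neural populations carries a dimensionless mean activity
obeying the additive (firing-rate) equation

    dx_i/dt = r_i ( -x_i + S( rho_i + sum_j a_ij x_j + inputs_i(t) ) ),
    S(x) = 1 / (1 + e^(-x))

The populations are an expiratory-related excitatory/inhibitory pair
(`e_er`, `i_er`; `e_er` stands in for air-sac pressure) and the RA
excitatory/inhibitory pair (`e_ra`, `i_ra`). The drives are three square
pulses of height 10: `F(t)` (the IA burst, onto `e_er`), and `Fd(t)`,
`Fd2(t)` (HVC bursts, onto RA). The internal ER wiring is fixed
(biases −7.5/−11.5, weights +10, −10, +10, +2); per-pattern couplings are
the published ER triples `(alpha_eer_F, alpha_eer_ra, alpha_ier_ra)` and RA
quintuples `(rho, a_Fd, a_Fd2, a_ra, b_ra)`. Time constants are
tau_ER ≈ 5 ms and tau_RA = 20 ms (see the methods vignette for the
rate-constant parses and why this one is the default).

The ER pair is bistable over a range of RA input: P0 arises when the
RA pulse response (sharp growth, then slow near-saddle decay) momentarily
removes the ER "off" state and latches the system onto its "on" plateau,
while P2's weaker RA output never does — its contribution stays a small
modulation. Cooling HVC is modelled as stretching its bursts (+15 ms) and
delaying them (+5 ms): stretching alone lengthens the P0 gesture;
stretching plus delay additionally drops the interior minimum through the
phonation threshold, breaking the syllable in two.

## Worked example

```r
library(songcircuit)

tr <- run_pattern("P0")      # published preset, RK4 at dt = 0.05 ms
print(tr)
#> song_trajectory (preset P0): 12001 points, t = [0, 600] ms, dt = 0.05 ms
#>   e_er  in [0.0011, 0.9850]
#>   i_er  in [0.0000, 0.2137]
#>   e_ra  in [0.0695, 0.4356]
#>   i_ra  in [0.0038, 0.0248]

summary(tr)                  # feature extraction on the pressure proxy e_er
#> Trace features
#>   label:           P0
#>   pulses >= 0.0985:  1
#>   dominant period: 38.7 ms
#>   RA trend:        decreasing
#>   extrema:         3 (2 max, 1 min)

run_cooling_experiment(stretch = 15, extra_delay = 5, mode = "both")
#> HVC cooling experiment (stretch 15 ms, delay 5 ms, mode both)
#>   normal: 1 pressure pulse(s) above 10% of max, total 166.9 ms
#>   cooled: 2 pressure pulse(s) above 10% of max, total 172.5 ms
```

The P0 trace is a single supra-threshold pressure pulse: a brief peak
(`e_er` ≈ 0.98 at the end of the 20 ms IA pulse), an interior minimum
(≈ 0.41 of the maximum) where the direct drive has decayed and the
telencephalic copy is still building, then the long "on"-plateau lobe
sustained by RA's slowly decaying output. Under cooling, the delayed HVC
burst lets the minimum fall below the 10 %-of-max phonation threshold: the
gesture breaks into two pulses while its total duration grows — exactly the
stretch-and-break phenomenology seen in canary cooling experiments.
`plot(tr)` draws the drives, RA, and ER traces; `run_pattern("pulsatile")`,
`"P2"`, `"P1"` reproduce the other patterns, and
`classify_pattern()` labels each correctly.

A command-line interface wraps the same functions:

```sh
inst/scripts/songcircuit simulate --pattern P0 --dt 0.05 --t-end 600 --out p0.csv
inst/scripts/songcircuit cool --stretch 15 --delay 5 --mode both --out-prefix cool_
inst/scripts/songcircuit features --in p0.csv
```

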