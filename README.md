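# rher

Human–animal discrimination for non-contact vital-sign monitoring with
impulse-radio ultrawideband (IR-UWB) radar.

## Why

Radar vital-sign monitors sense chest-wall motion at millimeter
sensitivity. A pet resting in the beam — a dog, cat or rabbit — produces a
respiration-like echo whose breathing and heart rates overlap the human
range, and silently corrupts the monitoring (or raises false alarms) if it
is mistaken for the patient. Neither rate ranges nor echo energy alone can
tell the species apart: large dogs reflect as strongly as people.

`rher` implements a two-stage discriminator for radar data cubes
(fast-time × slow-time amplitude matrices):

1. **Energy gate.** After slow-time clutter/DC removal (sliding-mean
   subtraction) and 5 Hz low-pass FIR filtering, the target is located at
   the maximum-energy range bin and its energy `E_i` is compared with a
   segment-calibrated human reference: `α_E = E_human / E_i`. Targets with
   `α_E ≥ 10` (echoes an order of magnitude weaker than a human's) are
   labelled animals immediately — this stops cats and rabbits cheaply.
2. **RHER.** Gate passers are decomposed by variational mode decomposition
   (VMD, the ADMM spectral iteration with Wiener-filter mode updates and
   center-of-gravity frequency updates; defaults K = 4, balancing
   parameter α = 9000, tolerance 1e−6). The respiration and heartbeat
   modes are selected by the *human* frequency bands and the
   respiratory-and-heartbeat energy ratio

   RHER = Σ u_r(t)² / Σ u_h(t)²

   decides the label: `log10(RHER) > 0` → human, else animal. Human chest
   returns are respiration-dominated (RHER ≫ 1); dog and cat returns carry
   a heartbeat component of comparable or larger energy (RHER ≤ 1),
   consistent with their lung-to-heart weight ratio of 1.1–1.5 versus ~3
   in adult humans.

A physics-based echo simulator (sinusoidal chest kinematics modulating the
delay and carrier phase of a Gaussian-envelope UWB pulse, plus static
multipath and noise, at the 7.29 GHz / 1.4 GHz / 23.328 GS/s operating
point) and species presets make the whole pipeline testable without
hardware.

## Worked example

```r
library(rher)

# calibrate the human energy standard from five simulated subjects
std <- calibrate_standard(
  lapply(1:5, function(i) synthesize_subject("human", seed = 100 + i)))

run_pipeline(synthesize_subject("human", seed = 301), std)
#> <target_report>
#>   target: bin 159 (1.015 m), energy 64.09
#>   energy gate: alpha_E = 3.23 -> human-candidate
#>   RHER = 39.82 (log10 = 1.60)
#>   rates: respiration 0.39 Hz, heartbeat 1.09 Hz
#>   final label: human

run_pipeline(synthesize_subject("dog", seed = 303), std)
#> <target_report>
#>   target: bin 159 (1.015 m), energy 198.4
#>   energy gate: alpha_E = 1.04 -> human-candidate
#>   RHER = 0.3255 (log10 = -0.49)
#>   rates: respiration 0.29 Hz, heartbeat 1.90 Hz
#>   final label: animal

run_pipeline(synthesize_subject("cat", seed = 302), std)
#> <target_report>
#>   target: bin 159 (1.015 m), energy 3.527
#>   energy gate: alpha_E = 58.7 -> animal
#>   final label: animal
```

Reading the output: every subject sits ~1 m from the radar (bin 159 of the
6.43 mm range grid). The human passes the gate (`α_E` ≈ 3) and its
respiration mode carries ~40× the heartbeat-mode energy → human. The dog's
echo is as strong as a human's (`α_E` ≈ 1), so the gate cannot reject it —
but its heartbeat mode out-powers respiration (RHER ≈ 0.33) → animal. The
cat's echo is ~60× weaker than the human reference → rejected by the gate
without running VMD.

A command-line wrapper with `simulate` / `calibrate` / `classify` /
`decompose` / `demo` subcommands lives at `inst/cli/rher-cli.R`; radar
cubes travel as tab-delimited matrices with YAML metadata sidecars.

See `vignettes/radar-vital-discrimination.Rmd` for the model, parameter
choices, and known limitations.

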