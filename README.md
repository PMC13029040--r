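# mmtc

Quantifying mesozooplankton-mediated trophic cascades in plankton food
webs.

Mesozooplankton (0.2–20 mm copepods, cladocerans and gelatinous taxa)
prey on the microzooplankton that are themselves the main grazers of
phytoplankton. That predation indirectly releases phytoplankton — a
trophic cascade — and it contaminates the classical bottle-incubation
estimate of mesozooplankton grazing: the control/treatment log-ratio
shrinks and the apparent grazing rate is biased low, sometimes negative.
`mmtc` is for plankton ecologists who run grazing incubations or model
pelagic food webs. It provides:

* **Functional-response tools** — Michaelis–Menten ingestion
  `I(x) = Imax·x/(kd + x)` with bounded nonlinear least-squares fitting,
  the two-factor community grazing map `g(x, y) = y·Imax/(kd + x)`, and
  dilution-method regression `k = µ − g·d`.
* **Three-level grazing correction** — the Frost log-ratio
  `ln(C_control/C_treatment)/(t·Z)` (Level 1), microzooplankton
  background subtraction `g_raw + g_micro − g′_micro` (Level 2), and
  trophic-cascade compensation `g_raw + TC` with
  `TC = g_micro·[1 − exp(−α·CI·B_meso)]` (Level 3), plus the three-step
  estimation workflow that infers TC from paired bottle means.
* **Cascade metrics** — the Cascade Strength index
  `CS = ((g − g′)/g)·ln(B_meso/B_micro)`, the density-mediated cascade
  ratio, a predator:prey size-matching efficiency kernel (peak α = 0.42
  at a 10:1 length ratio, half-decline at 5:1 and 20:1), and
  temperature-response functions for warming scenarios.
* **The NPMZ model** — a mass-conserving four-compartment
  nutrient–phytoplankton–microzooplankton–mesozooplankton ODE system
  with adaptive integration, equilibrium location, elasticity-based
  sensitivity analysis and a +ΔT warming scenario runner.
* **Synthetic experiments** — generators for functional-response data,
  dilution series and paired bottle incubations with stored ground
  truth, so every estimator is validated by parameter recovery.

See `vignettes/mmtc-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate a default bottle experiment (24 h, 6 replicates, 10 %
measurement noise, strong cascade) and correct the grazing rates:

```r
library(mmtc)

p <- fr_params(Imax = 38, kd = 1093)          # ciliate feeding curve
exps <- generate_bottle_experiment(experiment_design(seed = 42), p)
b <- estimator_bias(exps, p)
round(b$estimates[, c("replicate_id", "g_raw", "TC", "g_level3")], 4)
#>   replicate_id   g_raw     TC g_level3
#> 1            1 -0.1319 0.0582  -0.0737
#> 2            2 -0.2468 0.0554  -0.1914
#> 3            3 -0.4091 0.0744  -0.3347
#> 4            4  0.1205 0.0721   0.1926
#> 5            5  0.0981 0.0800   0.1781
#> 6            6  0.0240 0.0600   0.0841
```

`g_raw` is the uncorrected community log-ratio rate (d⁻¹): half the
replicates are *negative* even though the mesozooplankton are genuinely
grazing — the cascade released the treatment phytoplankton. `TC` is the
workflow's cascade rate and `g_level3 = g_raw + TC` the corrected rate.
Against the generator's stored truth:

```r
c(median_TC = b$median_TC, true_TC = attr(exps, "truth")$TC)
#> median_TC = 0.06604487, true_TC = 0.06572567   (0.5 % off)
c(bias_level1 = b$bias_level1, bias_level3 = b$bias_level3)
#> bias_level1 = -0.1409, bias_level3 = -0.0742   (true rate 0.05 d^-1)
```

The Level-3 correction roughly halves the raw estimator's bias in this
noisy draw; noiselessly it removes it entirely (see the test suite). A
warming scenario on the ecosystem model:

```r
ws <- warming_scenario(npmz_params(), delta_T = 2)
#> dGZ = 0.175 d^-1; cascade intensity 0.444 -> 0.485 (+9.1 %)
```

A +2 °C warming raises the mesozooplankton-on-microzooplankton grazing
coefficient by 0.175 d⁻¹ (inside the expected 0.15–0.2 d⁻¹ band) and
strengthens the modelled cascade.

A command-line wrapper is installed with the package
(`system.file("cli", "mmtc", package = "mmtc")`) exposing subcommands
`fit-fr`, `dilution`, `correct-grazing`, `cascade-index`, `size-alpha`,
`npmz-run`, `npmz-sensitivity`, `scenario` and `simulate`.

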