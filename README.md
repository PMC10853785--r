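# growthswitch

Deterministic multiscale modelling of a bistable self-activation gene
circuit under growth feedback, and of the stabilising effect of an
auxiliary repressive link.

## The problem

Synthetic gene circuits run on growing hosts. Growth dilutes every
protein at the specific rate `(1/N) dN/dt`, and circuit expression in
turn burdens growth. For a bistable self-activation switch — AraC
activating its own pBad promoter, reported by GFP — this coupling is
dangerous: a burst of fast growth after dilution into fresh media can
push the output below the separatrix and erase the stored state
(hysteresis collapse). Adding a repressive link (constitutive TetR
binding a tetO site in the promoter, tunable by aTc) turns growth into
an incoherent feed-forward input: fast growth dilutes the repressor
along with the target, transiently removing repression. That produces
pulse-like transients, buffers how far the output falls during log
phase ("drop-rescue"), and makes the circuit's hysteresis more robust
against growth.

The package is for systems/synthetic biologists who want to simulate and
analyse this class of circuit: it implements the coupled ODE model,
plate-reader-style experiment protocols, fixed-point/separatrix/
dose-response analysis, the derived scalar metrics, synthetic
plate-reader and flow-cytometry data generators, and least-squares
parameter calibration with recovery diagnostics.

## The model

Per-cell AraC (`A`), TetR (`T`) and population density `N`:

    dA/dt = k0_a + k1_a * F_A(A) * F_T(T, aTc) - (db_a + delta) * A
    dT/dt = k0_t - (db_t + delta) * T
    dN/dt = k_g * F_g(A, T) * (1 - N/N0) * N,   delta = (1/N) dN/dt

with `F_A = S_a A^2 / (1 + S_a A^2)`, an L-arabinose-dependent binding
activity `S_a`, a TetR/aTc repression function `F_T` (identically 1 for
the control circuit, `lam = 0`), and a burden factor
`F_g = 1/(1 + A/J_a + T/J_t)` that slows growth when the circuit is
expressed. Defaults are a calibrated, frozen parameter set (see
`?default_circuit` and the methods vignette).

## Worked example

Zero-growth anatomy of the experimental circuit at its reference dose,
then the drop-rescue comparison at four L-arabinose doses:

```r
library(growthswitch)

p <- default_circuit("experimental")
d <- reference_dose(p)         # geometric midpoint of its bistable window
d
#> [1] 0.0009429
fixed_points(p, d, atc = 20)
#>     araC tetR stability
#> 1 0.0439    1    stable
#> 2 0.2828    1  unstable
#> 3 1.7993    1    stable
separatrix(p, d, 20)
#> [1] 0.283

dr <- run_drop_rescue(experiment_config(
  lara_grid = c(0.33e-3, 0.67e-3, 1e-3, 1.33e-3), grid_step = 0.5))
dr
#>      dose percent_fall_exp percent_fall_ctrl fold_min_increase
#> 1 0.00033             78.7              98.5             14.57
#> 2 0.00067             78.6              98.1             11.58
#> 3 0.00100             78.4              97.1              7.46
#> 4 0.00133             78.2              92.9              3.06
```

Reading this: at the reference dose the switch has a low OFF state
(AraC 0.044), a high ON state (1.80) and a separatrix at 0.28 — initial
conditions above/below it resolve ON/OFF. After dilution into fresh
media, the control circuit's output falls by 93–99% of its starting
level within 10 h, while the repressive link holds the experimental
circuit's fall to ~78%, leaving its minimum 3–15-fold higher. The
growth-robustness headline:

```r
collapse_threshold(default_circuit("control"))       # ~0.15 per hour
collapse_threshold(default_circuit("experimental"))  # ~0.23 per hour
```

the ON state of the experimental circuit survives dilution into fresh
media up to a ~50% higher maximum growth rate than the control's.

## Documentation

The methods vignette (`vignettes/growth-feedback-methods.Rmd`) documents
the model assumptions, the frozen parameter calibration, the assay
conventions (per-circuit reference doses, aTc-assisted ON induction,
endpoint classification), numerical settings, and known limitations.
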