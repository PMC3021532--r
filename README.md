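# dosepulse

Dynamic hysteresis and dose-effect scaling for periodically treated
tumor–immune dynamics.

## The problem

Fractionated radiotherapy and pulsed chemotherapy deliver dose in cycles:
a drug-taking window of length `T0` followed by a recovery window, with
duty-cycle `d = T0/T`.  How should the dose per cycle be scheduled so that
each unit of intensity does the most damage?  `dosepulse` answers this for
a minimal tumor–immune model,

```
dx/dt = a·x·(1 − b·x) − β·x²/(ε + x²) − c(t)
```

logistic growth (rate `a`, capacity `1/b`) minus a saturating
immunosurveillance term (ceiling `β`, activation threshold `ε`) minus a
periodic kill term `c(t)` — either an additive flux `h(t)` or a log-kill
term `h(t)·x` — where `h(t)` is a rectangular (abrupt, radiotherapy-like)
or half-sine (gradual, chemotherapy-like) pulse of amplitude `h0`.

Because the tumor's response lags the dose, one steady treatment cycle
traces a closed curve in the `(h, x)` plane — a **dynamic hysteresis
loop**.  The package measures its area `S = |∮ x dh|` (shoelace rule),
the per-cycle dose cumulant `I = ∫ h dt`, the cycle-averaged burden `⟨x⟩`
and excursion `Δx`, and then collapses the amplitude × duty-cycle surface
of the **therapy effect** `Y = S/h0` by per-amplitude max-normalization
onto one universal quadratic law

```
Y' = m·I'² + n·I'        (least squares through the origin)
```

whose interior peak identifies the reduced dose of maximal effectiveness.
It is intended for modelers of treatment scheduling and for anyone who
needs a tested reference implementation of loop-area/data-collapse
analysis for periodically forced ODEs.

## Worked example

```r
library(dosepulse)

p <- model_params(coupling = "multiplicative")
untreated_steady_states(p)
#>          x stable     residual
#> 1 0.000000  FALSE 0.000000e+00
#> 2 8.889084   TRUE 5.551115e-16
```

The treatment-naive tumor sits at `x* ≈ 8.889`.  One steady cycle under a
rectangular pulse (`h0 = 0.5`, `T = 1`, 30% duty-cycle):

```r
spec <- intervention_spec("rectangular", h0 = 0.5, T = 1, d = 0.3)
tr <- integrate_to_limit_cycle(p, spec)
tr
#> <trajectory> rectangular h0=0.5 T=1 d=0.3 | 2001 samples, converged=TRUE (24 transients), eradicated=FALSE
c(S = loop_area(tr), I = dose_cumulant(spec), mean_x = cycle_stats(tr)$mean_x)
#>      S = 0.3706   I = 0.1500   mean_x = 7.1219
```

The loop encloses area 0.37 for 0.15 units of dose per cycle, while the
mean burden drops from 8.89 to 7.12.  The full analysis sweeps both
waveforms over `h0 = 0.1…1.0`, `d = 0.1…0.9`:

```r
cfg  <- default_run_config()
sv   <- do.call(solver_config, cfg$solver)
rect <- sweep_grid(p, "rectangular", cfg$grids$h0, cfg$grids$d, T = 1, config = sv)
sine <- sweep_grid(p, "halfsine",    cfg$grids$h0, cfg$grids$d, T = 1, config = sv)

peak_duty_cycle(rect)$consensus   # 0.3  — abrupt pulses peak at d ≈ 30%
peak_duty_cycle(sine)$consensus   # 0.5  — gradual pulses peak at d ≈ 50%

collapse_surfaces(sine, rect)
#> <collapse_result> 177 reduced points (max reduction, 0 rows excluded)
#>   Y' = -3.3487 I'^2 + 3.5271 I'   R^2 = 0.8784
#>   peak at I' = 0.5266, Y' = 0.9288
```

Both waveforms, all ten amplitudes, fall on one downward-opening
quadratic: per-unit-intensity effectiveness is maximal at an intermediate
reduced dose, small duty-cycles under-dose and large ones leave too little
tumor regrowth to act on.  (Three slow-relaxing half-sine cells are
flagged unconverged at the default 200-cycle budget and excluded from the
fit, 180 − 3 = 177 points.)

`run_full_pipeline(cfg, "out/")` writes the tidy surface CSVs,
`reduced.csv`, `collapse.json` and the echoed config; the same pipeline is
scriptable via the CLI (`simulate`, `sweep`, `analyze`, `collapse`,
`fixtures`, `run-all` — see `?dosepulse_cli`).

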