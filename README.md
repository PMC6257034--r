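# mangofirm

Kinetic modelling of mango firmness loss under temperature and ethylene.

Ripening facilities and postharvest researchers need to know how fast a
batch of mangoes will soften to "ready to eat" under a given storage
chain. `mangofirm` implements a first-order kinetic model of acoustic
firmness loss for 'Keitt' and 'Kent' mangoes: a constant internal
ethylene driver *Eth* induces production of a cell-wall-degrading enzyme
pool, the pool turns over with first-order degradation, and firmness *F*
decays towards a residual level *F*<sub>fix</sub> at a rate proportional
to the enzyme level. With the initial enzyme level fixed at zero
(ripening is inhibited on the tree and by chilling during reefer
transport), the constant-temperature solution is

```
F(t) = F_fix + (F0 - F_fix) * exp( k_fenz * Eth * ((1 - exp(-k_d t)) / k_d^2 - t / k_d) )
```

where `k_fenz = k_f * k_enz` is a lumped rate constant and every rate
follows Arrhenius temperature dependence,
`k_i(T) = k_i_ref * exp((E_i / R) (1/T_ref - 1/T))` with
`T_ref = 295.15 K`. The interpretable summary of a batch's response to
ethylene is the **ethylene factor** `EF = k_fenz(T_mean) * Eth`,
evaluated at the time-weighted mean storage temperature.

The package provides:

* forward simulation under piecewise-constant temperature scenarios
  (exact chained analytical solution) and logged temperature traces
  (ODE integration, `deSolve`), plus the acoustic firmness-index
  conversion `FI = f^2 m^(2/3) / 1e4`;
* indexed nonlinear least-squares estimation (`minpack.lm`) with staged
  attribution of variation — common parameters, per-batch
  *F*<sub>fix</sub>/*Eth*, per-fruit *F*<sub>0</sub>, optionally
  per-fruit *Eth* — with Gauss–Newton standard errors and adjusted R²;
* the published cultivar kinetics, batch estimates and storage
  scenarios as packaged tables, and an EF calculator reproducing the
  published per-sub-batch EF values;
* a seed-controlled synthetic-data generator emulating the study's
  batch geometries, so every estimation path is testable without any
  external data;
* a command-line front-end (`exec/mangofirm`) with `simulate`, `fit`,
  `predict` and `ef` subcommands.

## Worked example

Simulate a fruit through a ripening-then-transport scenario (3 d at
18 °C, then 10 d at 22 °C), using the packaged 'Keitt' kinetics:

```r
library(mangofirm)
kp <- cultivar_params("Keitt")
fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
firmness_analytic(temp_scenario(c(3, 10), c(18, 22)), kp, fs, times = 0:13)
#>    time_d firmness_fi enzyme
#> 1       0       60.00   0.00
#> 4       3       50.94   0.13
#> 8       7       23.57   0.45
#> 14     13       13.08   0.62   (abridged)
```

Firmness falls from 60 FI towards the residual 12.7 FI, accelerating
after the switch to 22 °C as the enzyme pool (arbitrary lumped units)
builds up. The ethylene factor of an untreated batch stored 16 d at
20 °C with `Eth = 2.23`:

```r
ethylene_factor(kp, 2.23, temp_scenario(16, 20))
#> [1] 0.1376554
```

Generate a synthetic four-temperature trial and recover its parameters
(truth: `Eth = 1.52`, `F_fix = 12.7`, 120 fruit, noise sd 2 FI):

```r
ds <- generate_dataset(design_preset("keitt_batch2"), seed = 1)
fit <- fit_firmness(ds, param_structure(eth = "group", ffix = "group"), kp)
fit
#> Softening-model fit: 1080 observations, 122 parameters
#>   RSS = 4052, sigma = 2.057 FI, adjusted R2 = 99.2%
#>   converged: TRUE (6 iterations, max gradient 0.0023)
#>   batch/common parameters:
#>  parameter level         cell estimate      se
#>       ffix group keitt_batch2   12.597 0.10415
#>        eth group keitt_batch2    1.518 0.01328
```

Both batch-level parameters are recovered within two standard errors,
and the residual scale (2.06 FI) matches the simulated measurement
noise. From the shell, the same EF computation is:

```sh
mangofirm ef --cultivar Keitt --eth 2.23 --scenario "16:20"
# 0.138
```

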