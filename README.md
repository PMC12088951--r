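# facme

Protein turnover inference for focal adhesions (FAs) from FRAP/FLAP
time–intensity curves, via the closed-form solution of a one-dimensional
birth–death chemical master equation.

## The problem

FRAP and FLAP experiments record how fast a fluorescently tagged protein
exchanges between a region of interest (here, a focal adhesion) and the
surrounding pool. The standard analysis fits the recovery/loss curve with
`y = y0 + A·exp(R0·t)` and reports a single mobility number, the turnover
rate `kT = |R0|`. That one number hides *why* a protein is fast or slow: is
it entering rarely, or leaving quickly?

`facme` resolves `kT` into the two per-capita rates of the underlying
exchange process. With the labelled pool conserved
(`n_tot = n_in + n_out`), the interior concentration relaxes exponentially
at `kT = k_in + k_out` toward the stationary interior fraction `n̄_in`, and
the model ties the plateau to the exit rate:

```
k_out = n̄_in · kT        k_in = kT − k_out
```

Both observables (`kT`, `n̄_in`) come straight from the exponential fit of
the normalized curve, so the inversion needs no extra assumptions. The
inverted rates then drive:

* closed-form curve predictions and residual diagnostics,
* repeated K-fold cross-validation scored by MAPE (with the
  <10 / 10–20 / 20–50 / ≥50 % interpretation bands),
* replicate outlier removal by Tukey fences on the fitted `R0` values,
* exact Gillespie ensemble simulation of protein-interaction
  perturbations: removing a stabilizing partner (vinculin-type interior
  loss channel) or adding a constitutive cytoskeletal coupling
  (α-actinin/actomyosin-type interior gain channel), with mean-field
  oracles.

A reference table of published rates for twelve core FA proteins (tensin1,
talin1, vinculin, α-actinin, ILK, α-parvin, kindlin2, paxillin, p130Cas,
VASP, FAK, zyxin) ships with the package: `fa_reference_rates()`.

Intended users: cell biologists and modelers with replicate FRAP/FLAP
traces (delimited text: one time column, replicate intensity columns) who
want per-protein entry/exit rates with uncertainties, validation, and
in-silico perturbation experiments.

## Worked example

Simulate a tensin-like FRAP experiment (12 replicates, 2% Gaussian noise)
and run the full pipeline — per-replicate fits, outlier fences, average
curve, inversion:

```r
library(facme)

r <- fa_protein_rates("tensin1")      # published kT = 11.29e-3 /s, n_in_bar = 0.562
spec <- generator_spec(k_in = r$k_in, k_out = r$k_out, modality = "FRAP",
                       n_traces = 12, noise_sigma = 0.02, seed = 101)
fit <- fa_fit(generate_traces(spec))
fit
#> Exchange-model fit: synthetic (FRAP, 12 replicate(s), 0 removed)
#>   k_t      =   11.608 e-3 /s  (+/- 0.191)
#>   k_in     =    5.359 e-3 /s  (+/- 0.106)
#>   k_out    =    6.249 e-3 /s  (+/- 0.118)
#>   n_in_bar =    0.538         (+/- 0.005)
```

The estimates bracket the generating truth (`k_in = 4.945e-3`,
`k_out = 6.345e-3`; the plateau is read at the literal 300-s end point,
which for a protein this slow sits ~3% under the true stationary value —
see the vignette). Validate predictiveness and simulate the fitted process:

```r
kfold_cv(generate_traces(spec), k = 5, reps = 20, seed = 1)
#> <cv_result> synthetic: K = 5, 20 repetition(s), MAPE = 7.53 +/- 0.0487% (Highly accurate)

ensemble(build_base(r, n_tot = 1000), n_runs = 300, t_max = 900,
         grid_dt = 10, init_fraction = 0, seed = 1)
#> <ensemble_result> tensin1: 300 runs, 91 grid points, final mean 0.5612 +/- 0.00086
```

A MAPE of 7.5% lands in the "highly accurate" band, and the stochastic
ensemble plateaus on the published stationary fraction 0.562 within Monte
Carlo error. `predict()`, `residuals()`, `plot()` and `simulate()` methods
work on the fitted object; `write_rates_table()` exports the rates.

## Command line

A thin wrapper over the same functions lives in `exec/facme`:

```sh
Rscript exec/facme synth --k-in 0.00494 --k-out 0.00635 --sigma 0.02 --seed 3 --out traces.csv
Rscript exec/facme fit --input traces.csv --modality frap --out-dir out/
Rscript exec/facme validate --input traces.csv --modality frap --k 3,5,10 --seed 1 --out-dir out/
Rscript exec/facme simulate --scenario vinculin_loss --protein talin1 --partner-k-in 0.0052 --out-dir out/
```

Every output embeds its resolved configuration and seed in a `#` header
line.

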