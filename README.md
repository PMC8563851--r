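# furaSE — standard errors for the ratiometric (Fura-2) calcium estimator

Fura-2 ratiometric imaging turns four raw camera counts per time point —
region-of-interest (ROI) and background counts under 340 nm and 380 nm
excitation — into a free-calcium estimate

```
f_λ  = (adu_λ/P − adu_λ,B/P_B) / T_λ         (background-corrected flux)
r    = f340 / f380                            (fluorescence ratio)
Ca^  = K_eff (r − R_min) / (R_max − r)        (ratiometric estimator, µM)
```

Fitting calcium-dynamics models to a **single transient** — the normal
situation when the indicator itself perturbs the dynamics — needs a
standard error on every `Ca^(t_i)`. `furaSE` provides them two ways from
the data alone, using the Gaussian CCD noise model
`σ²_ADU = G·adu + G²·P·σ²_readout`:

- **delta method**: first-order propagation through flux, ratio and the
  calcium transform;
- **Monte-Carlo**: k = 10⁴ Gaussian count quadruples per time point pushed
  through the same chain, SE = sample SD of the resulting calcium values.

A forward simulator (intensity model + CCD noise) and a validation
pipeline (normalized residuals, Shapiro–Wilk, ECDF vs exact Kolmogorov
confidence bands, weighted monoexponential fits) verify on synthetic
transients with known truth that the standard errors are correctly
calibrated. For whom: experimental physiologists doing quantitative
calcium imaging, and anyone who needs honest per-point error bars on a
ratio-of-noisy-quantities estimator.

## Worked example

```r
library(furaSE)
p <- fura_default_params()      # calibrated constants of a reference
                                # recording + its transient's decay params
sim <- simulate_transient(decay_grid(p$decay), p$decay,
                          p$illumination, p$acquisition, seed = 42)
est <- estimate_transient(sim$series, p$acquisition,
                          method = "both", k = 10000, seed = 43)
head(est[, c("time", "ratio", "ca", "se_delta", "se_mc")], 5)
#>       time  ratio     ca se_delta  se_mc
#> 1 2283.415 0.3518 0.1795   0.0098 0.0099
#> 2 2283.565 0.3306 0.1582   0.0088 0.0089
#> 3 2283.715 0.3360 0.1636   0.0090 0.0090
#> 4 2283.865 0.3182 0.1461   0.0085 0.0086
#> 5 2284.015 0.3355 0.1631   0.0093 0.0093
```

Each row: fluorescence ratio, estimated calcium (µM) and its SE by both
routes — note they agree to ~1% and that the SE (~0.009 µM near the
0.17 µM peak, shrinking towards baseline) grows with calcium. Fit the
decay with those SEs as weights:

```r
fit_monoexp_weighted(est, t0 = p$decay$t0)
#> Weighted monoexponential fit (Ca0 + delta exp(-(t-t0)/tau))
#>   ca0   = 0.05871 +/- 0.000434 uM
#>   delta = 0.1202 +/- 0.00401 uM
#>   tau   = 2.306 +/- 0.0966 s
#>   chi-square 183.3 on 198 df (n = 201, mc-method weights)
```

The simulation truth (ca0 = 0.059, delta = 0.114, tau = 2.339) is inside
every interval, and the weighted residual sum of squares matches its
χ²₁₉₈ expectation — the error bars are the right size. The full
calibration check in one call:

```r
run_validation(seed = 44)
#> Standard-error validation (201 points, mc method, k = 10000, seed = 44)
#>   residuals: mean -0.018, SD 1.032
#>   Shapiro-Wilk: W = 0.9966, p = 0.9370
#>   95% Kolmogorov band (exact): inside (max dev 0.0433, half-width 0.0949)
#>   99% Kolmogorov band (exact): inside (max dev 0.0433, half-width 0.1139)
```

Residuals `(Ca^ − Ca_true)/SE` are standard normal: mean ≈ 0, SD ≈ 1,
normality not rejected, ECDF inside both simultaneous bands.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fura", package = "furaSE"))')
Rscript $CLI simulate --config cfg.json --out sim.csv
Rscript $CLI estimate --in sim.csv --out est.csv --method both --k 10000 --seed 7
Rscript $CLI validate --out report.json --seed 7 --plots figs/
```

Configs are flat JSON/YAML (keys `r_min`, `r_max`, `k_eff`, `gain`,
`readout_variance`, `tau`, `grid`, ...); unset keys take the packaged
defaults shown by `fura_default_params()`.

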