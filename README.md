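# rppgtime

Low-complexity timing correction and heart-rate estimation for remote
photoplethysmography (rPPG) signals.

Camera-based pulse measurement averages the green channel of a facial region
of interest frame by frame and reads the heart rate (HR) off the dominant
FFT frequency in the resting band (0.8–1.8 Hz; HR = 60·f bpm). That works
only if frames arrive at a fixed rate. In practice frame intervals jitter
and frames drop; treating the surviving samples as uniform compresses the
time axis and biases the dominant frequency by roughly n/(n−k) for k drops
in an n-sample window. `rppgtime` implements three O(n) corrections that
resample a timestamped, irregular, lossy series x(s₁), …, x(sₙ) onto a
uniform grid t₁, …, tₘ before spectral analysis:

* **linear interpolation** — x̂(t) = x(sᵢ) + (x(sᵢ₊₁)−x(sᵢ))/(sᵢ₊₁−sᵢ)·(t−sᵢ);
* **natural cubic-spline interpolation** — per-interval cubics
  aᵢτ³+bᵢτ²+cᵢτ+dᵢ with C¹/C² continuity at the knots, solved by the Thomas
  algorithm;
* **cascaded integrator–comb (CIC) filter interpolation** — a
  multiplier-free multirate low-pass (defaults R = 10, N = 4, M = 2) with an
  occupancy-normalized handling of irregular/lossy input.

Around the correctors the package provides the full estimation chain
(ROI green-channel averaging, windowless mean-removed FFT, band-limited peak
pick), synthetic signal generators with the two corruption models
(clipped-Gaussian timing jitter, uniform sample loss), Monte-Carlo
benchmarks of reconstruction RMSE and HR RMSE/MAE versus corruption level,
CSV I/O for timestamped series, and a small command line. The methods
vignette (`vignettes/timing-correction.Rmd`) documents the model choices,
numerics, and known limitations.

## Worked example

A 30 s synthetic rPPG-like trace at 72 bpm, nominally sampled at 25 Hz
(750 samples), with 40 frames dropped at random:

```r
library(rppgtime)

dense <- generate_rppg_like(duration_s = 30, hr_bpm = 72, seed = 42)
grid  <- uniform_grid(start_s = 0, rate_hz = 25, count = 750)
clean <- sample_regular(dense, grid)
lossy <- apply_sample_loss(clean, loss_spec(40, seed = 7))

estimate_hr_from_series(lossy, "none",  grid)  # uncorrected baseline
#> <hr_result> 76.06 bpm (peak 1.2676 Hz, 29 band bins)
estimate_hr_from_series(lossy, "cubic", grid)  # after timing correction
#> <hr_result> 72.00 bpm (peak 1.2000 Hz, 31 band bins)

rmse(reconstruct(lossy, grid, "linear"), clean$values)
#> [1] 0.08784107
rmse(reconstruct(lossy, grid, "cubic"), clean$values)
#> [1] 0.110076
rmse(reconstruct(lossy, grid, "cic"), clean$values)
#> [1] 0.2581159
```

Untreated, 40 dropped frames shift the estimate by +4 bpm (the time axis
shrinks by 750/710); every corrector restores the true 72 bpm. The
reconstruction RMSEs are in units of the unit-power signal: on this noisy
trace linear and cubic track the samples closely, while CIC pays its
intrinsic passband droop plus smoothing of the noise — harmless for the
spectral peak, visible in waveform error.

The Monte-Carlo driver reproduces the benchmark tables on pure band tones
(here at a reduced 200 trials per condition):

```r
tbl <- run_reconstruction_experiment(
  experiment_config(n_trials = 200, loss_grid = c(0, 10, 50), master_seed = 1),
  "loss")
tbl
#> <metric_table> metric: rmse, condition: loss_count
#>    condition method metric_mean metric_std
#> 1          0   none    0.000000    0.00000
#> 2          0 linear    0.000000    0.00000
#> 3          0  cubic    0.000000    0.00000
#> 4          0    cic    0.070580    0.02927
#> 5         10   none    1.372460    0.20048
#> 6         10 linear    0.006413    0.00324
#> 7         10  cubic    0.000406    0.00211
#> 8         10    cic    0.071163    0.02811
#> 9         50   none    1.410624    0.08354
#> 10        50 linear    0.018241    0.00857
#> 11        50  cubic    0.002195    0.00588
#> 12        50    cic    0.088628    0.03109
```

Ten dropped frames already push the uncorrected error to ~1.4 signal units
(full decorrelation of a unit-power tone), while the interpolators hold it
one to three orders of magnitude lower; CIC's floor is its band-averaged
droop (≈ 0.07).

## Command line

A thin wrapper over the same functions lives at `inst/cli/rppgtime`
(installed under `system.file("cli", "rppgtime", package = "rppgtime")`):

```sh
rppgtime simulate --duration 30 --rate 25 --seed 1 --out clean.csv
rppgtime corrupt  --in clean.csv --out lossy.csv --loss 40 --seed 7
rppgtime correct  --in lossy.csv --out fixed.csv --method cubic
rppgtime hr       --in fixed.csv --method none
rppgtime bench-recon --mode loss --out recon.csv --seed 1
```

All subcommands are deterministic under `--seed`.

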