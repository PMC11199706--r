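# photonup

Quantification toolkit for genetically encoded fluorescent neuropeptide
sensor recordings — from in vitro sensor characterization to in vivo fiber
photometry.

GPCR-based fluorescent sensors (the dLight/GRAB family and, here
specifically, a nociceptin/orphanin-FQ sensor built on the NOP receptor)
report peptide binding as a fractional fluorescence increase. Characterizing
such a sensor and using it in vivo requires a chain of standard but
fiddly computations that this package implements as tested, reusable
functions:

- **ΔF/F₀ quantification** — `compute_dff()` implements
  ΔF/F₀ = (F_t − F₀)/F₀ with F₀ the mean over a baseline window, plus
  membrane ROI selection (`select_membrane_rois()`: 65 % peak-ΔF/F₀
  criterion or Otsu auto-threshold), biexponential bleach correction
  (`correct_bleaching_biexp()`), and staircase bath-application
  quantification with 3-min averaging windows (`stepwise_response()`).
- **Kinetics** — mono-exponential association/decay fits
  y = c + A(1 − e^(−t/τ)) and y = c + A e^(−t/τ)
  (`fit_mono_exponential()`), per-pixel activation time constants on
  800 Hz line scans (`pixelwise_tau_on()`), and the 85 %-of-plateau /
  50 ms onset-latency gate for bolus application experiments
  (`onset_latency()`).
- **Concentration–response** — three-parameter Hill fitting
  R(c) = R_max·c^h / (EC50^h + c^h) with zero lower asymptote
  (`fit_hill3()`), pEC50 conversion, response normalization.
- **Fiber-photometry preprocessing** — the three standard two-channel
  (signal + isosbestic control) pipelines: power-like baseline ΔF/F with
  median fallback (`preprocess_arc()`), baseline-window LLS subtraction
  with 10-s smoothing and baseline z-scoring (`preprocess_baseline_lls()`),
  and whole-session polynomial detrend + LLS division
  (`preprocess_session_lls()`), each with full provenance replay.
- **Epoch analysis** — event-aligned windows with per-epoch z-scores
  (`extract_epochs()`), signed trapezoidal AUC over 5-s bins
  (`auc_bins()`), post-injection window means (`summarize_window()`), and
  event counting.
- **Simulators** — forward models with known ground truth for every input:
  two-state mass-action ligand binding (dB/dt = k_on·L·(1−B) − k_off·B,
  F = f₀(1 + R_max·B)), two-channel photometry sessions at 1017.25 Hz with
  bleaching, shared motion artifacts and event-driven transients, line-scan
  pixel stacks, dose–response plates, and behavioral event schedules
  including the progressive-ratio progression n_i = 5e^(i/5) − 5
  (1, 2, 4, 6, 9, 12, …).

## Worked example

Simulate an agonist-injection photometry session, run the baseline-LLS
pipeline, and characterize the simulated sensor:

```r
library(photonup)

params   <- sensor_params(noise_sd = 0.01, motion_sd = 0.03,
                          bleach_model = "power_like", seed = 42)
schedule <- generate_event_schedule("injection", seed = 42)
rec      <- simulate_photometry_session(params, schedule, rate = 200)
rec
#> Two-channel recording: 360200 samples at 200.00 Hz (1801.0 s)
#>   events: 1 (injection)

trace <- preprocess_baseline_lls(rec)
summarize_window(trace, c(1800, 2100))   # 20-25 min after injection
#> [1] 369.5
```

The window mean is in z-units relative to the 10-min pre-injection
baseline: the simulated agonist (4 × Kd sustained) drives the sensor ~370
baseline-SDs above its pre-injection noise — large because the simulated
noise floor is clean; the number is the same quantity one would report for
a real post-injection dose comparison.

```r
plate <- simulate_dose_response(seed = 42)   # truth: EC50 28.65 nM, h = 1
fit_hill3(plate)
#> Three-parameter Hill fit:
#>   R_max = 3.75  EC50 = 2.35e-08 M (23.46 nM)  h = 1.12  pEC50 = 7.63
```

With 5 % multiplicative noise and 3 replicates the fitted EC50 (23.5 nM)
recovers the generating 28.65 nM within the sampling error expected of an
8-point plate.

```r
scan <- simulate_linescan(sensor_params(noise_sd = 0.05, seed = 42))
mask <- select_membrane_rois(scan, "dff_fraction")   # 65% criterion
pixelwise_tau_on(scan, mask, onset_s = scan$truth$onset_s)
#> Per-pixel tau_on: 595 +/- 1 ms (n = 50 converged, 0 failed)
```

The per-pixel association fits on the simulated 800 Hz line scan recover
the generating activation time constant (595 ms) with sub-percent error.

## Documentation

The methods vignette
(`vignettes/sensor-quantification-methods.Rmd`) describes the binding
model, the artifact models, each pipeline's numerical choices and the
design decisions taken where the underlying protocols are underspecified.
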