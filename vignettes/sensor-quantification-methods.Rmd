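---
title: "Models and methods for neuropeptide sensor quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for neuropeptide sensor quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonup)
```

# Scope

`photonup` quantifies recordings from genetically encoded fluorescent
neuropeptide sensors — GPCR-based probes whose fluorescence increases when
the peptide ligand binds. It covers the full desk-side analysis chain for
such a sensor: ΔF/F₀ quantification of imaging traces, membrane-pixel ROI
selection, photobleaching correction, mono-exponential activation/
deactivation kinetics with an onset-latency quality gate, three-parameter
Hill concentration–response fitting, three fiber-photometry preprocessing
pipelines, and event-aligned epoch summaries (z-scores, binned AUC,
post-injection window means). A set of forward simulators generates every
input with known ground truth, so each stage is testable without
experimental data.

# The binding and fluorescence model

The simulators treat the sensor as a two-state receptor with mass-action
kinetics. Fractional occupancy $B(t)$ obeys

$$\frac{dB}{dt} = k_{on} L(t) \, (1 - B) - k_{off} B,$$

and fluorescence is linear in occupancy, $F = f_0 (1 + R_{max} B)$. For a
ligand series held piecewise-constant between samples this ODE has an exact
per-segment solution — relaxation towards $L/(L + K_d)$ at rate
$k_{on} L + k_{off}$, with $K_d = k_{off}/k_{on}$ — and
`simulate_binding_response()` evaluates that solution directly rather than
integrating numerically. Two consequences matter for validation:

* the equilibrium response is a Hill curve with coefficient 1 and
  $EC_{50} = K_d$, the model class of `fit_hill3()`;
* the response to a concentration step is mono-exponential with time
  constant $1/(k_{on} L + k_{off})$, the model class of
  `fit_mono_exponential()`.

The test suite exploits both closed forms, and additionally cross-checks the
analytic solution against an independent stiff ODE integrator
(`deSolve::lsoda`) on time-varying ligand input.

Default parameters place $K_d$ at 28.65 nM and $R_{max}$ at 3.88 (a 388 %
maximal ΔF/F₀), matching the published in vitro characterization of the
nociceptin sensor this package was built around; $k_{on} = 10^6\,
\mathrm{M^{-1}s^{-1}}$ is a conventional order of magnitude for peptide–GPCR
association. Published characterizations of this sensor class do not report
$k_{on}$ and $k_{off}$ separately from the activation time constant at one
concentration, so the split between the two rates is a simulator
convenience, not a biological claim: only their ratio (the equilibrium curve) and the
step-response rate are constrained by data.

# What the simulators emulate — and what they do not

`simulate_photometry_session()` produces a two-channel recording at the
acquisition rate of a typical lock-in photometry system (1017.25 Hz by
default): a signal channel carrying the ligand-driven component and an
isosbestic control channel that shares the multiplicative nuisances but not
the ligand response. Nuisances are:

* **bleaching** — one of three parametric families (`bleach_curve()`):
  power-like $a(t+t_0)^{-b}+c$, biexponential, or polynomial (degree ≤ 4),
  chosen to match the three detrending models the analysis pipelines
  assume;
* **motion artifacts** — low-pass-filtered Gaussian noise (default cutoff
  2 Hz) applied multiplicatively and *identically* to both channels before
  channel gains, which is exactly the correlated-artifact structure
  isosbestic correction assumes, so perfect cancellation is achievable in
  the noise-free limit;
* **additive noise** — independent per-channel Gaussian noise.

Event schedules (`generate_event_schedule()`) reproduce the trial structures
of the supported paradigms: a single i.p.-injection session with a
pre-injection baseline; 15 cued-sucrose trials (5-s tone, then 5-s spout
access, inter-trial interval uniform on 45–75 s) between 5-min flanking
baselines; four 10-s tail lifts (ITI 120–300 s); and fixed- or
progressive-ratio operant sessions, the latter using the geometric
progression $n_i = 5e^{i/5} - 5$ rounded half away from zero
(1, 2, 4, 6, 9, 12, …). Rounding half *away from zero* is deliberate: it is
the only common rounding rule that reproduces that printed sequence
(2.459 → 2 but 8.591 → 9 are consistent with either rule; the choice is
fixed by matching the full sequence).

The mapping from behavioral events to ligand transients (sustained
post-injection rise, brief cue transients, consumption dips riding on a
tonic level) is a simulator parameter (`response_map`), not a model of
release biology; defaults scale amplitudes to $K_d$ so transients are
resolvable after the pipelines' smoothing windows.

What the simulators deliberately omit: excitation-spectrum physics, photon
shot noise, hemodynamic artifacts, and any within-channel artifact that is
*not* shared between signal and control. Passing recovery tests on these
simulations therefore demonstrates that the pipelines are correct for the
artifact structure they assume — not that real recordings contain no other
artifact classes.

# ΔF/F₀, ROI selection and bleach correction

`compute_dff()` implements the baseline-relative fractional change
$\Delta F/F_0 = (F_t - F_0)/F_0$ with $F_0$ the mean over a stated baseline
window. It is scale-invariant by construction; values below −1 are
physically impossible and are clipped with a warning since they indicate a
mis-chosen baseline.

`select_membrane_rois()` offers the two selection rules used at different
stages of sensor characterization: thresholding per-pixel peak ΔF/F₀ at a
fraction of the stack-wide maximum (default 0.65, the 65 % membrane-pixel
criterion used for line-scan kinetics), and Otsu's histogram threshold on
the temporal-mean image (via `EBImage::otsu`) as the automatic-threshold
analogue for confocal quantification. A contrast-free image yields an empty
mask plus a warning rather than an arbitrary split.

`correct_bleaching_biexp()` fits a biexponential to the segment *before*
ligand application and extrapolates it over the whole trace. Correction is
by division by default — division keeps subsequent ΔF/F₀ computation
scale-invariant, whereas subtraction does not — with subtraction available
as an option since the original quantification does not state which was
used. The ex vivo staircase quantification (`stepwise_response()`) compares
180-s averaging intervals (the "3-min" windows) at the end of each
application step against the interval immediately preceding it; correction
is applied before ΔF/F₀ conversion, and that ordering is recorded in the
result rather than assumed silently.

# Kinetics

`fit_mono_exponential()` fits $y = c + A(1 - e^{-t/\tau})$ (association) or
$y = c + A e^{-t/\tau}$ (decay) by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), initialized from a log-linear regression of the
decaying residual amplitude. $\tau$ is bounded in $(0, 10 \times$ trace
duration$]$; the amplitude is unconstrained in sign so inverted traces are
fitted and flagged instead of silently mangled. On noise-free members of the
model class recovery is exact to solver tolerance across $\tau$ from 0.1 s
to 100 s.

`onset_latency()` implements the diffusion-control gate for bolus
application experiments: the time for a co-applied reference dye to reach
85 % of its plateau, with experiments at or above 50 ms excluded. The
"plateau" is taken as the mean of the final 10 % of samples — the source
protocol says "maximal value at the plateau" without defining the plateau
window, and a tail mean is robust to noise where a pointwise maximum is not.
The baseline is the mean of samples before the stated application time
(default $t = 0$). `aggregate_gated_taus()` applies the gate to a batch and
reports the exclusion count, so gated-out experiments are visible rather
than silently dropped.

`pixelwise_tau_on()` min–max normalizes each masked pixel trace (the
protocol says "normalized" without naming the reference; min–max is the
choice that makes fits gain-invariant) and fits association kinetics per
pixel, summarizing converged fits only, with counts of failures.

# Concentration–response fitting

`fit_hill3()` fits the three-parameter Hill model
$R(c) = R_{max} c^h / (EC_{50}^h + c^h)$ with the lower asymptote fixed at
zero — the natural reading of "three-parameter" for responses expressed as
ΔF/F₀ over a ligand-free baseline. Replicates are pooled by default;
fitting per-concentration means is available because the source reports
"n = 3 independent experiments per concentration" without stating the
fitting granularity, and the two differ only in weighting. Numerical
choices: concentrations are internally rescaled by their geometric mean so
all three parameters are O(1) for the optimizer (unit invariance is exact);
the EC50 start is taken from the half-maximum crossing of the
per-concentration means, with a small spread of fallback starts to avoid
the degenerate flat-curve local minimum; a fitted EC50 more than 10× outside
the tested range marks the fit as not converged. `pec50_from_ec50()` is the
$-\log_{10}$ conversion (28.65 nM → 7.54).

# The three photometry pipelines

All three variants consume a `two_channel_recording` and emit a
`processed_trace` whose provenance list fully determines the output;
`replay_provenance()` re-runs the recorded variant with its recorded
parameters and reproduces the output bit-for-bit.

**Power-like ΔF/F (`preprocess_arc`)** — block-average each channel to 1 Hz,
trim the first and last second (the source says "the first and last
seconds"; the trim width is configurable), fit the time-varying baseline
$F_0(t) = a(t+t_0)^{-b} + c$ on the pre-event baseline period, convert each
channel to $\Delta F_t/F_0(t)$, and subtract the control ΔF/F₀ from the
signal ΔF/F₀. The cited "power-like model" has no published formula, so the
package adopts this three-term power form, which captures power-law-like
photobleaching with a non-zero asymptote. When no decay can be fitted —
optimizer failure, exponent collapsing to zero, or a fitted decline that
does not stand clear of the residual noise (less than 3 residual SDs or
0.1 % relative) — the median of the baseline period is substituted, which is
the failure path the source prescribes. Downsampling to 1 Hz groups samples
by integer second, which is exact for any acquisition rate including the
non-integer 1017.25 Hz.

**Baseline-window LLS with z-scoring (`preprocess_baseline_lls`)** — ordinary
least squares of the signal on the control over the pre-injection baseline
only, subtraction of the fitted control, block-mean downsampling by 300,
centered 10-s rolling mean, then z-scoring against the mean and SD of the
*processed* baseline segment (the source z-scores after smoothing, and the
package follows that order). Note one consequence probed by the tests:
because smoothing precedes z-scoring, samples within half a smoothing
window of the baseline/injection boundary leak post-injection signal into
the baseline SD; callers who need a conservative SD should end the baseline
window slightly before the injection.

**Whole-session polynomial detrend with LLS division
(`preprocess_session_lls`)** — fourth-degree polynomial fitted to each raw
channel and divided out, LLS of the detrended control onto the detrended
signal over the entire session, division of the signal by the fitted
control, downsampling by 100 and a 1-s rolling mean. The output is a
motion-corrected normalized ratio centered on 1; event-aligned z-scoring
happens downstream in `extract_epochs()`. An exactly constant detrended
control makes the regression singular; the pipeline then uses the
least-squares constant predictor (the mean of the detrended signal), which
reproduces the ideal ratio of 1 for artifact-free constant channels.

Both downsampling styles are non-overlapping block means — an anti-aliasing
choice the sources leave open — and rolling smoothing is a centered moving
average whose window shrinks to the valid range at the edges, specified in
seconds and converted at the post-downsampling rate (even sample widths are
widened by one to keep the window symmetric).

# Epochs, AUC and window summaries

`extract_epochs()` cuts windows $[-\mathrm{pre}, +\mathrm{post})$ around
event onsets on the processed sampling grid — the half-open convention makes
a (5 s, 10 s) window at 10 Hz exactly 150 samples — excluding and counting
events whose window leaves the recording, and optionally z-scoring each row
by its own mean and SD (zero-variance rows are excluded with a count, never
turned into infinities). `auc_bins()` integrates trapezoidally over
contiguous fixed-width bins (default 5 s) anchored at the event onset and
extending in both directions; bin edges snap to the nearest aligned sample
and every bin includes both edge samples, so additivity — the sum of
contiguous bins equals the integral over their union — holds exactly rather
than to within an edge error. AUC is signed. `summarize_window()` gives
post-injection window means (e.g. a 20–25-min window after an injection)
with a batch mode that aggregates per-recording means for downstream group
statistics; hypothesis testing itself is left to standard tools and is out
of scope here.

# Problem sizes and tolerances used in the tests

The test suite and acceptance script run entirely on synthetic data at desk
scale: photometry sessions of 5–40 min at 50–200 Hz (the full 1017.25 Hz
rate is exercised where the rate itself matters), line scans of 50–100
pixels × 4000 frames, dose–response plates of 8 concentrations × 3
replicates, and Monte-Carlo recovery runs of 5–100 seeded repetitions.
Exact identities (AUC additivity, z-score definition, scale invariance,
closed-form equilibria) are asserted near machine precision; noise-free
model-class recoveries at $10^{-6}$ relative; stochastic recoveries at the
10–15 % level dictated by their sampling variability. One property deserves
a note: for an artifacts-only session the 95th percentile of the
baseline-LLS output cannot fall below 1 z-unit,
because the output is z-scored against the same stationary noise that
dominates the rest of the session (a Gaussian residual has a 95th percentile
of |z| near 2); the corresponding test asserts the achievable property —
artifact leakage adds nothing beyond the noise floor (95th percentile < 3)
while the *pre-z-score* artifact cancellation is verified directly at the
< 1 % residual-variance level.

# Known limitations

* The power-like baseline family is one plausible reading of an unspecified
  published model; its extrapolation accuracy degrades when the baseline
  window is much shorter than the post-event period.
* Bleach correction by division assumes multiplicative bleaching; traces
  with strong additive offsets (e.g. autofluorescence) should use the
  subtraction option with care.
* The ROI methods are pure thresholding; no segmentation, registration or
  movie motion correction is attempted.
* Simulator behavioral transients are phenomenological; recovery tests
  validate the pipelines, not any claim about peptide release dynamics.
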