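---
title: "Measurement models and design choices in cardiotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and design choices in cardiotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotrace)
```

## Scope

cardiotrace quantifies cardiac function in zebrafish models of
phospholamban (PLN) R14del cardiomyopathy from five kinds of recordings:
GCaMP6f and Indo-1 calcium transients, patch-clamp action potentials and
membrane currents, Doppler echocardiography beat tables, high-speed
brightfield movies of the embryonic ventricle, and surface ECGs. PLN
inhibits SERCA2a, the pump that returns cytosolic Ca^2+^ to the
sarcoplasmic reticulum after each beat; the R14del variant strengthens that
inhibition, so its cellular signature is a smaller Ca^2+^ transient with a
slower mono-exponential decay, and at fast pacing a beat-to-beat
alternation of action-potential duration (APD alternans). Every analysis
stage is paired with a seeded synthetic generator with known ground truth,
so the entire measurement chain is verifiable without any recordings.

## The synthetic generators

The generators are first-class, tested code: they define the conditions
under which the analyses are validated.

**Calcium trains.** Each beat adds `amplitude * g(t - t_k)` to the signal,
with `g(s) = exp(-s/tau_decay)` in instantaneous-upstroke mode and
`g(s) = (1 - exp(-s/tau_rise)) * exp(-s/tau_decay)` (rescaled to unit peak)
in exponential mode. The product-of-exponentials family was chosen because
its late decay is *exactly* mono-exponential with `tau_decay`, which makes
decay-constant recovery well-posed. Beats superpose: when the decay has not
finished at the next onset, the new transient rides on the remaining tail.
Two useful identities follow: every peak sits exactly `amplitude` above the
level immediately before its onset, and the decay limb of every beat is
exactly exponential (the carried tail only scales it). Traces begin with
200 ms of pure diastolic baseline.

**Presets.** The packaged presets pin the embryonic amplitude and decay
constant to the published group means (wild type: amplitude 99.8 on the
normalized-percent scale, tau 105.74 ms; R14del: 73.9 and 178.6 ms), with
per-field provenance (`published` vs `assumed`) recorded in the JSON file and
surfaced by `make_preset()`. Values the source does not print were fixed
once at physiologically sensible levels and marked `assumed`: a 2 Hz beat
rate (120 bpm, in the range of tricaine-anesthetized 3 dpf embryos; the
printed comparison found no genotype difference in frequency), a diastolic
level of 100 on the normalized scale, and additive Gaussian noise with sd
5% of the wild-type amplitude. Embryonic presets use the instantaneous
upstroke so the decay fit is exact; the adult Indo-1 presets (all values
assumed, since only figures are printed for the adult cells) use a 25 ms
exponential upstroke and nM units. The printed embryonic recovery time
(123.84 ms) is inconsistent with a mono-exponential of tau 105.74 ms under
any single fixed-percentage criterion, so the generator pins tau and lets
the recovery time emerge from whatever criterion is configured (default:
90% return).

**AP trains** are feature-controlled waveforms, not biophysical models: a
half-cosine upstroke (1 ms), a fast spike-to-plateau decay, a plateau at
`rmp + plateau_frac * apa`, and a cosine repolarization timed so the
90%-repolarization crossing falls exactly APD90 after the
maximal-upstroke-velocity instant — the same fiducial the analysis uses.
Even and odd beats can carry different APD90 values to create alternans,
and an optional Gaussian hump after the last beat emulates a delayed
afterdepolarization (DAD). APD20/50 emerge from the shape rather than
being controlled.

**Hemodynamics, movies, ECGs.** Doppler beat tables alternate
`mean_pv * (1 +/- variation/2)` so the variability statistic equals
`variation` exactly. Ellipse series interpolate sinusoidally between
end-diastolic and end-systolic axes and can be rendered as binary-mask
multi-page TIFF movies. ECG complexes are Gaussian P/Q/T waves plus a
narrow R spike, with the P centre placed so the P-onset to R-onset
interval equals the requested PR exactly under the 10%-crossing onset
convention.

What the generators do *not* emulate: photobleaching, motion artifacts,
optical blur, baseline drift, ionic-current kinetics, or real brightfield
texture. Passing tests therefore demonstrate the correctness of the
measurement chain, not robustness to every artifact of real recordings.

## Calcium transient measurement

`detect_transients()` finds peaks by topographic prominence (default 30%
of the trace range, 100 ms minimum separation) and brackets each peak with
its neighbouring minima; overlapping transients closer than the separation
merge into one segment by design. `transient_features()` reports, per
transient: diastolic level, amplitude (peak minus diastolic), upstroke
time (10%-rise to peak), recovery time (peak to the configurable
fractional return, default 90%), transient durations CaD20/50/80 (width at
20/50/80% *recovery level*, i.e. at `(1 - X) * amplitude` above diastolic
— the conventional reading of "duration at X%"), and the decay constant.
All crossings are linearly interpolated between samples.

**Diastolic baseline.** The default estimator fits a line through the 30 ms
window before the upstroke and evaluates it at the upstroke instant. A
plain window mean (available as `baseline_method = "mean"`) is biased high
by the decay slope whenever the previous transient's tail is still
falling — with the R14del decay constant at 2 Hz the decay is ~6%
incomplete at the next onset, and that slope term alone would distort
amplitudes by ~0.7% in a genotype-dependent direction. The linear
evaluation removes the slope term; on noiseless synthetic trains the
per-beat amplitude error is below 0.05% for both embryonic presets.

**Decay constant.** `fit_decay_tau()` is a closed-form weighted
least-squares fit of `log(signal - diastolic)` over the falling limb
between 90% and 10% of the amplitude. Three numerical choices matter:

* weights `(signal - diastolic)^2`, the first-order error-propagation
  weights for a log transform under additive noise — without them the
  noisy tail samples dominate with asymmetric log-noise and the estimator
  acquires a several-percent upward bias;
* the window is bounded by the first *crossing times* of the two levels
  rather than by per-sample amplitude, so whether a sample enters the fit
  never depends on its own noise;
* `asymptote = "fit"` optionally refines the reference level by a
  deterministic one-dimensional search. This matters for slow decays: the
  decay approaches the true diastolic asymptote, while the measurable
  pre-onset baseline sits above it by the carried-over tail, so the
  default fit underestimates tau on such beats (by ~14% for the mutant
  preset at 2 Hz). The refinement recovers tau exactly on noiseless
  superposed beats; the default remains the simple baseline-referenced
  fit, which is exact whenever a transient is preceded by a quiet
  baseline.

At 2% amplitude noise the default fit recovers tau with a residual bias
under 2% (Monte-Carlo, 200 seeds); single-transient estimates at 100 fps
have a sampling sd of roughly 8%, which is why the per-recording pipeline
follows the conventional practice of averaging ten consecutive transients
before feature extraction.

**Averaging.** `average_transients()` aligns on the rising half-amplitude
crossing by default rather than on the per-beat argmax: aligning on a
noisy single-sample maximum selects positive noise into the averaged peak,
and does so more strongly for slowly decaying (flatter-peaked) transients,
which would bias genotype comparisons. Peak alignment remains available.

**Normalization and calibration.** `normalize_amplitudes()` expresses every
value as a percentage of the whole reference-group mean (the reading
adopted for "normalized amplitude"; per-session normalization is not
attempted). Indo-1 ratios convert to [Ca^2+^] through the Grynkiewicz
ratio equation `Kd * beta * (R - Rmin) / (Rmax - R)`; the source gives no
calibration constants, so `indo1_calibration()` defaults
(Kd 250 nM, Rmin 0.3, Rmax 3, beta 3) are typical in-situ values flagged
`assumed` and must be replaced for quantitative work.

## Action potentials, currents, capacitance

APD20/50/90 are measured from the maximal-upstroke-velocity instant to the
interpolated crossing of `V_peak - x% * APA_max` — the fiducial and the
peak-referenced repolarization levels are stated conventions, since the
acquisition methods name the quantities without formulas. RMP is the mean
of the pre-upstroke window, APA_plat the amplitude 50 ms after the
upstroke, Phase-3 velocity the largest downward dV/dt between the 50% and
90% crossings, and derivatives are central differences at the recording
rate. The alternans statistic is the mean absolute APD90 difference over
*all* consecutive pairs in the analyzed record. DADs are suprathreshold
(> 1 mV) excursions above the post-burst diastolic baseline (median of the
500 ms preceding the search window; events merged within 50 ms); the
search window must be placed so that its preceding baseline lies in the
pause, because during fast pacing the membrane is depolarized for most of
each cycle. Steady-state K^+^ currents split at -30 mV with the boundary
row excluded from both partitions ("negative or positive to" excludes
equality); I~Ca,L~ is peak minus steady-state current of the P1 step
(steady state: mean of the last 10%); C~m~ is the capacitive-transient
time constant over the series resistance (ms/MOhm -> nF, reported in pF).

## Hemodynamics

Adult Doppler quantities use the printed formulas: outflow surface
`pi (d/2)^2`, stroke volume `VTI x area` (mm^3 = ul), cardiac output
`SV x HR` (ml/min). The beat-to-beat variability statistic is
`mean(|PV[i+1] - PV[i]|) / mean(PV)`: "corrected for the average" is read
as division (a dimensionless coefficient comparable across fish;
subtraction would keep units and fish-size dependence). All available
consecutive pairs are used, with a six-beat minimum enforced.

Embryo volumetrics use the ellipse model: area `pi a b / 4`, volume
`(pi/6) a b^2` with 1000 um^3 = 1 pL (the SI conversion; with ~100 um
axes this yields the 10^2-pL volumes expected for a 3 dpf ventricle).
End-diastolic and end-systolic volumes are the means of the three largest
per-cycle maxima and three smallest minima of a lightly smoothed volume
series (moving average of fs/10 frames), mirroring manual 3 + 3 frame
selection; EF = SV/EDV and CO = SV x HR follow. Contraction time runs
from a volume maximum to the next minimum and relaxation back to the
following maximum, averaged over three cycles when available. Mask-based
axis extraction uses second central moments (full axis =
`4 * sqrt(eigenvalue)` of the pixel-coordinate covariance, exact for a
filled ellipse) and serves synthetic renders and pre-segmented data only —
no attempt is made to segment real brightfield movies.

## ECG

Filtering is a zero-phase (forward-backward) Butterworth band-pass,
3-100 Hz by default, so intervals are not phase-shifted; the second-order
default keeps a 50 Hz component within 5% while attenuating 500 Hz by more
than 60 dB. Beat detection runs on a copy smoothed over 5 ms (matched to
the R-spike width) so noise spikes cannot masquerade as beats. Ensemble
averaging uses complete R-centred windows only (by default 45% of the
shortest RR on each side). On the averaged complex, onsets are the last
sub-10%-amplitude samples before each wave peak, searched backwards so
early noise crossings are ignored; PR is P onset to R onset and PQ is P
onset to the Q trough, which in this stylized complex makes PQ a few ms
shorter than PR — both are reported under these documented conventions. A
complex without a detectable P wave (below 5% of R) yields `NA` intervals
rather than an error. Note that the 3 Hz high-pass slightly reshapes the
slow P wave, shortening measured PR by a few ms relative to the unfiltered
complex; interval round-trip accuracy is therefore validated on the
unfiltered path, and the filter separately by its frequency response.

## Problem sizes and validation strategy

The test suite validates each stage twice: exactly on noiseless synthetic
data (closed forms such as CaD50 = tau ln 2, recovery = tau ln 10, sphere
volumes, the Indo-1 algebraic inverse, and generator round-trips for every
controlled parameter) and statistically under seeded noise (20-50 seeds
per property; means compared within three standard errors or the stated
conventional tolerances; ensemble averaging checked against the sqrt(N)
law). Cohort-scale checks simulate 10 wild-type and 12 mutant fish with
10-beat, 100 fps recordings — the published group sizes — and recover the
~26% amplitude reduction end to end; single-fish recordings use 1000
frames at 100 fps as in the imaging protocol. These sizes keep the whole
suite within a minute on one core while leaving every statistical check
with comfortable power.

## Known limitations

* The per-beat diastolic level is the *end-diastolic* level, not the decay
  asymptote; for strongly overlapping transients the two differ by the
  carried tail (that difference is physiological — the same elevation
  appears in real recordings of slowed reuptake).
* The default tau fit inherits that reference and underestimates tau on
  such beats unless `asymptote = "fit"` is used.
* The stylized AP and ECG waveforms control only the measured features;
  morphology-sensitive analyses beyond those features should not be
  validated against them.
* Indo-1 calibration defaults are placeholders, flagged `assumed`.
* Inferential statistics (t-tests, ANOVA families) are deliberately out of
  scope; the package emits tidy per-subject tables ready for standard
  routines.
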