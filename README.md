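# cardiotrace

Quantitative phenotyping of cardiac function in zebrafish models of
phospholamban (PLN) R14del cardiomyopathy.

PLN is the endogenous brake on SERCA2a, the pump that clears cytosolic
Ca²⁺ back into the sarcoplasmic reticulum after every beat. The R14del
variant tightens that brake, and its earliest measurable signatures are
cellular: a smaller Ca²⁺ transient with a slower mono-exponential decay
(larger τ), beat-to-beat alternation of action-potential duration (APD
alternans) at fast pacing, delayed afterdepolarizations, beat-to-beat
variation in ventricular outflow velocity, and impaired relaxation.
cardiotrace implements the full measurement stack for these phenotypes:

* **calcium** — transient detection, per-beat features (diastolic level,
  amplitude, upstroke/recovery times, CaD20/50/80), weighted log-linear
  fitting of the decay constant τ (with optional asymptote refinement),
  10-transient averaging, group normalization, and Grynkiewicz Indo-1
  ratio-to-[Ca²⁺] calibration;
* **electro** — AP segmentation and features (RMP, APA_max, APA_plat,
  APD20/50/90 from the dV/dt-max fiducial, upstroke and Phase-3
  velocities), the APD90 alternans statistic, DAD detection (> 1 mV rule),
  steady-state K⁺-current partition at −30 mV (I_K1 / I_Kr), I_Ca,L from
  a P1 step, and capacitance from the capacitive transient (C_m = τ/R_s);
* **hemo** — Doppler outflow surface π(d/2)², stroke volume VTI × area,
  cardiac output, the beat-to-beat peak-velocity variability coefficient
  mean(|ΔPV|)/mean(PV), and embryo ellipse-model volumetrics
  (V = (π/6)·a·b², EDV/ESV/SV/EF/CO) with contraction/relaxation timing
  and moment-based ellipse extraction from mask movies;
* **ecg** — zero-phase 3–100 Hz band-pass, R-peak detection,
  ensemble-averaged complexes, PR/PQ intervals and P/R amplitudes;
* **synth** — seeded generators for all of the above with known ground
  truth, including presets that encode the published wild-type and R14del
  group means (amplitudes 99.8 vs 73.9 %, τ 105.74 vs 178.6 ms), with
  per-field provenance;
* **report** — mean ± SEM summaries, percent change, 2^−ΔΔCt fold
  changes, paired baseline/treated tables, and CSV/TIFF round-trip I/O.

## Worked example

Simulate a wild-type embryonic GCaMP6f recording (10 beats, 100 fps, 5%
noise) and extract its features:

```r
library(cardiotrace)

wt <- make_preset("wt_embryo")
wt
#> generator_preset 'wt_embryo' (units: arb)
#>   diastolic_level  100            [assumed]
#>   amplitude        99.8           [published]
#>   tau_rise         0              [assumed]
#>   tau_decay        105.74         [published]
#>   beat_rate        2              [assumed]
#>   noise_sd         5              [assumed]
#>   upstroke_mode    instantaneous  [assumed]

tr  <- gen_calcium_train(wt, n_beats = 10, fs = 100, seed = 7, noise_sd = 5)
res <- analyze_calcium_trace(tr)
round(as.data.frame(res$features), 2)
#>   frequency diastolic amplitude upstroke_time recovery_time cad20 cad50  cad80    tau
#> 1         2    100.08     97.18          9.04        229.78 28.63 81.45 179.92 104.82
```

The chain detects the ten transients (frequency 2 Hz), averages them
aligned on the upstroke, and recovers the generating parameters: amplitude
97.2 (true 99.8, within the noise), diastolic 100.1 (true 100), and
τ = 104.8 ms against the generating 105.74 ms. The recovery time (229.8 ms)
is the 90%-return time, ≈ τ·ln 10 for a mono-exponential decay.

Comparing against a simulated mutant fish and quantifying alternans:

```r
mut    <- make_preset("r14del_embryo")
tr_mut <- gen_calcium_train(mut, n_beats = 10, fs = 100, seed = 8, noise_sd = 5)
amp    <- normalize_amplitudes(
  list(wt = res$features$amplitude,
       r14del = analyze_calcium_trace(tr_mut)$features$amplitude), "wt")
round(percent_change(amp$wt, amp$r14del), 1)
#> [1] 25

ap    <- gen_ap_train(apd90_even = 120, apd90_odd = 80, pacing = 4, n_aps = 8)
apd90 <- sapply(segment_aps(ap$trace, ap$stimuli),
                function(s) ap_features(ap$trace, s)$apd90)
apd_alternans(apd90)
#> APD90 alternans: mean |dAPD90| = 40 ms over 7 pairs
```

A single mutant fish shows a ~25% lower amplitude than this wild-type
fish, and the alternans statistic recovers exactly the programmed
|120 − 80| = 40 ms.

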