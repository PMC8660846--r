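{
  "wt_embryo": {
    "description": "3 dpf wild-type embryonic heart, cytosolic GCaMP6f fluorescence, 100 fps widefield imaging. Amplitude and decay constant pinned to the published wild-type group means (normalized % scale).",
    "units": "arb",
    "fields": {
      "diastolic_level": {"value": 100.0, "provenance": "assumed", "note": "normalized diastolic fluorescence; scale anchor for the normalized-percent units"},
      "amplitude": {"value": 99.8, "provenance": "published", "note": "wild-type group mean of the normalized Ca2+ transient amplitude (%)"},
      "tau_rise": {"value": 0.0, "provenance": "assumed", "note": "instantaneous upstroke so the decay limb is exactly mono-exponential"},
      "tau_decay": {"value": 105.74, "provenance": "published", "note": "wild-type group mean decay constant of mono-exponential fits (ms)"},
      "beat_rate": {"value": 2.0, "provenance": "assumed", "note": "120 bpm, within the physiological range of tricaine-anesthetized 3 dpf embryos"},
      "noise_sd": {"value": 5.0, "provenance": "assumed", "note": "additive Gaussian noise, 5% of the wild-type amplitude"},
      "upstroke_mode": {"value": "instantaneous", "provenance": "assumed", "note": "tied to tau_rise = 0"}
    }
  },
  "r14del_embryo": {
    "description": "3 dpf plna-R14del embryonic heart, GCaMP6f fluorescence. Amplitude and decay constant pinned to the published mutant group means.",
    "units": "arb",
    "fields": {
      "diastolic_level": {"value": 100.0, "provenance": "assumed", "note": "diastolic level not significantly different from wild type in embryos; same scale anchor"},
      "amplitude": {"value": 73.9, "provenance": "published", "note": "mutant group mean of the normalized Ca2+ transient amplitude (%)"},
      "tau_rise": {"value": 0.0, "provenance": "assumed", "note": "instantaneous upstroke"},
      "tau_decay": {"value": 178.6, "provenance": "published", "note": "mutant group mean decay constant of mono-exponential fits (ms)"},
      "beat_rate": {"value": 2.0, "provenance": "assumed", "note": "transient frequency did not differ between genotypes"},
      "noise_sd": {"value": 5.0, "provenance": "assumed", "note": "5% of the wild-type amplitude"},
      "upstroke_mode": {"value": "instantaneous", "provenance": "assumed", "note": "tied to tau_rise = 0"}
    }
  },
  "r14del_istaroxime": {
    "description": "plna-R14del embryo after 30 min incubation with 100 uM istaroxime: amplitude and decay restored towards wild-type levels, diastolic level unaffected.",
    "units": "arb",
    "fields": {
      "diastolic_level": {"value": 100.0, "provenance": "assumed", "note": "istaroxime left diastolic levels unaffected"},
      "amplitude": {"value": 96.0, "provenance": "assumed", "note": "restored towards the wild-type mean (no printed group mean)"},
      "tau_rise": {"value": 0.0, "provenance": "assumed", "note": "instantaneous upstroke"},
      "tau_decay": {"value": 115.0, "provenance": "assumed", "note": "decay restored towards the wild-type constant (no printed group mean)"},
      "beat_rate": {"value": 2.0, "provenance": "assumed", "note": "unchanged beat rate"},
      "noise_sd": {"value": 5.0, "provenance": "assumed", "note": "5% of the wild-type amplitude"},
      "upstroke_mode": {"value": "instantaneous", "provenance": "assumed", "note": "tied to tau_rise = 0"}
    }
  },
  "wt_adult": {
    "description": "Isolated adult wild-type ventricular cardiomyocyte, Indo-1 ratiometric [Ca2+] at 1 kHz, field-stimulated at 1 Hz, 25 C. All values assumed (figures only, no printed means).",
    "units": "nM",
    "fields": {
      "diastolic_level": {"value": 100.0, "provenance": "assumed", "note": "typical diastolic [Ca2+]i for quiescent ventricular myocytes"},
      "amplitude": {"value": 400.0, "provenance": "assumed", "note": "systolic-minus-diastolic [Ca2+]i"},
      "tau_rise": {"value": 25.0, "provenance": "assumed", "note": "finite upstroke of the Indo-1 transient"},
      "tau_decay": {"value": 300.0, "provenance": "assumed", "note": "slow reuptake at 25 C"},
      "beat_rate": {"value": 1.0, "provenance": "assumed", "note": "1 Hz field stimulation"},
      "noise_sd": {"value": 8.0, "provenance": "assumed", "note": "photomultiplier noise on the calibrated signal"},
      "upstroke_mode": {"value": "exponential", "provenance": "assumed", "note": "tied to tau_rise > 0"}
    }
  },
  "r14del_adult": {
    "description": "Isolated adult plna-R14del ventricular cardiomyocyte, Indo-1 at 1 kHz: raised diastolic [Ca2+], longer transients and slower decay than wild type. All values assumed (figures only).",
    "units": "nM",
    "fields": {
      "diastolic_level": {"value": 150.0, "provenance": "assumed", "note": "diastolic [Ca2+]i increased in mutant adult myocytes"},
      "amplitude": {"value": 360.0, "provenance": "assumed", "note": "systolic level comparable to wild type on a raised diastolic level"},
      "tau_rise": {"value": 25.0, "provenance": "assumed", "note": "finite upstroke"},
      "tau_decay": {"value": 480.0, "provenance": "assumed", "note": "slower decay, consistent with impaired SR reuptake"},
      "beat_rate": {"value": 1.0, "provenance": "assumed", "note": "1 Hz field stimulation"},
      "noise_sd": {"value": 8.0, "provenance": "assumed", "note": "photomultiplier noise"},
      "upstroke_mode": {"value": "exponential", "provenance": "assumed", "note": "tied to tau_rise > 0"}
    }
  }
}
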