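Package: cardiotrace
Title: Calcium Transient, Electrophysiology, Hemodynamic and ECG Analysis
    for Zebrafish Cardiac Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A measurement stack for quantifying cardiac function in zebrafish
    models of phospholamban-linked cardiomyopathy. Extracts per-beat features
    from GCaMP and Indo-1 calcium transients (amplitude, diastolic level,
    durations, mono-exponential decay constant), quantifies action potentials,
    APD alternans and delayed afterdepolarizations from patch-clamp traces,
    partitions steady-state potassium currents and L-type calcium current,
    computes Doppler-based hemodynamics (outflow-tract area, stroke volume,
    beat-to-beat peak-velocity variation) and ellipse-model ventricular
    volumetrics with contraction and relaxation timing, and filters,
    beat-detects and ensemble-averages electrocardiograms. A seeded
    synthetic-data module generates traces, beat tables, ellipse series,
    movies and ECGs with known ground truth, including presets encoding
    published wild-type and R14del group means, so every analysis stage is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
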