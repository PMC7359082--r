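Package: spinefus
Title: Transvertebral Focused-Ultrasound Blood-Spinal-Cord-Barrier Opening Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational pipeline for focused-ultrasound
    blood-spinal-cord-barrier opening through the intact vertebral column
    with microbubbles. Provides short-burst phase-keying (SBPK) transmit
    waveform synthesis with pulse-inversion pairing and intensity metrics,
    ramped-pressure exposure schedules with a subharmonic acoustic-emissions
    feedback controller, passive-cavitation-detection spectral analysis
    (narrowband receiver model, time- and frequency-domain baseline
    subtraction, 40 kHz band sums, threshold detection), a Pennes bioheat
    finite-difference thermal safety model with microbubble enhancement
    scaling, treatment outcome metrics (MRI enhancement criterion, outcome
    table aggregation, through-bone transmission and focal-shift metrics,
    CT density statistics, histology grading), and seeded synthetic-data
    generators for emissions, MRI image pairs and benchtop field scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
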