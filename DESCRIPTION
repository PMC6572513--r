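Package: esopcg
Title: Quantitative Analysis of Intraoperative Esophageal Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying drug-induced changes in intraoperative
    esophageal heart-sound recordings and synchronized arterial pressure
    waveforms. Extracts S1/S2 heart-sound amplitudes via the Hilbert
    envelope, total spectral power with a Hamming-window FFT, heart rate
    from S1 intervals, arterial dP/dtmax and systemic vascular resistance,
    and runs paired before/after drug-effect statistics with
    normality-gated test selection and correlation of percentage changes
    against hemodynamic covariates. Includes a parametric simulator of
    esophageal phonocardiogram and arterial-pressure episodes with known
    ground-truth drug effects, so every processing stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
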