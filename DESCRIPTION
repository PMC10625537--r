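Package: cloprhythm
Title: Quantification of Daily Chloride Rhythms from Ratiometric Biosensor
    Imaging, LFP Spectra and Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying day/night modulation of intracellular chloride
    in cortical pyramidal neurons and its functional consequences. Implements a
    forward spectral model of a dual chloride/pH ratiometric biosensor
    (ClopHensor-type) and its inversion to per-cell pH and [Cl-]i, Nernst
    equilibrium-potential conversion, automated soma detection and ROI ratio
    extraction from multi-wavelength two-channel image stacks, visually evoked
    gamma-band peak prominence over an aperiodic 1/f fit, z-score-spectrogram
    quantification of drug-induced epileptiform events and seizures with
    censored latencies and cumulative pathological activity, and circadian
    locomotor actogram metrics. Ships synthetic-data generators with known
    ground truth for every input modality so the full pipeline can be exercised
    and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
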