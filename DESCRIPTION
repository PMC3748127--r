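Package: myomri
Title: Noninvasive Muscle Phenotyping by Quantitative MRI, Dynamic 31P-MRS and
    Evoked-Force Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for noninvasive phenotyping of mouse hindlimb
    muscle. Provides a digital hindlimb phantom with known ground truth and
    simulators for every acquisition the pipeline analyzes (three-point Dixon
    gradient-echo imaging, multi-echo T2-weighted imaging, diffusion-weighted
    imaging, dynamic 31P spectroscopy and evoked-force recordings), together
    with the matching analyzers: three-point Dixon water/fat separation with
    fat-fraction quantification and muscle anatomy (cross-sectional area,
    hindlimb volume), pixel-wise log-linear T2 mapping, diffusion-tensor
    estimation with eigenvalue/ADC/FA metrics, prior-knowledge time-domain
    quantification of dynamic 31P spectra (PCr, Pi and ATP time courses,
    intracellular pH from the Pi chemical shift, PCr recovery time constant),
    and evoked-force analysis (tetanus kinetics, Hill force-frequency fit,
    fatigue binning, specific force). Cohort helpers assemble per-animal
    results into group summaries, percent differences, t-tests and Pearson
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
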