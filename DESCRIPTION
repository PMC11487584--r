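Package: diffuseQC
Title: Simulation, Fitting, and Quality Control for Hybrid Diffuse Optics (TRS + DCS)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models, inverse fitting, and rule-based quality control for
    hybrid diffuse optical neuromonitoring combining time-resolved near-infrared
    spectroscopy (TRS) and diffuse correlation spectroscopy (DCS). Simulates
    distributions of photon time-of-flight (DTOF) and intensity autocorrelation
    (g2) curves for homogeneous semi-infinite media and heterogeneity-mimicking
    mixtures, recovers absorption and reduced scattering coefficients, hemoglobin
    concentrations, tissue oxygen saturation, the blood-flow index and the
    coherence parameter, and computes figures of merit (FWHM ratios, SNR,
    dynamic range, count rate, tail plateau) feeding a configurable
    trustworthiness classifier. Includes a seeded generator of healthy and
    pathological case presets, a tissue-composition grammar, and long-format
    dataset tables with cohort summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'classes-optics.R'
    'classes-instrument.R'
    'classes-results.R'
    'diffusion.R'
    'forward-models.R'
    'instrument.R'
    'fit-trs.R'
    'hemodynamics.R'
    'fit-dcs.R'
    'qc-metrics.R'
    'qc-classify.R'
    'tissue.R'
    'dataset.R'
    'presets.R'
    'cohort.R'
    'curve-io.R'
    'pipeline.R'
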