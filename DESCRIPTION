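Package: receptorpharm
Title: Radioligand Binding and Receptor Pharmacology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of G-protein-coupled receptor
    pharmacology assays: three-parameter logistic fitting of
    concentration-response data with a fixed Hill slope, Schild regression
    for competitive antagonism (dose ratios, pA2), homologous and
    heterologous radioligand competition binding (IC50, Bmax, KD,
    Cheng-Prusoff Ki), one-phase association and dissociation kinetics with
    derived rate constants (kobs, kon, koff, kinetic KD) and delta-method
    error propagation, and BRET ratio quantification of arrestin
    recruitment. Includes a mass-action synthetic-assay generator that
    emulates plate-based cAMP accumulation, BRET, whole-cell competition
    binding and scintillation-proximity kinetic assays, so every analysis
    stage can be validated by parameter recovery against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
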