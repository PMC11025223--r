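Package: DNAclassify
Title: Compilation and Simulation of DNA Strand-Displacement Molecular
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to design, compile and simulate DNA-based molecular
    classifiers for gene-expression signatures. A linear classifier over
    miRNA biomarkers is compiled into a chemical reaction network of
    toehold-mediated strand-displacement modules: catalytic amplifiers with
    competitive inhibitors realize signed real-valued weights as
    concentration ratios, shared output strands implement summation, a
    cooperative-hybridization annihilator performs winner-take-all
    subtraction, and dual fluorescent reporters (HEX/ROX) read out the
    diagnostic call. The package includes a deterministic mass-action ODE
    simulator with conservation-law checking, a cycle-by-cycle model of
    reverse transcription plus asymmetric PCR that renders single-stranded
    DNA approximately linear in the logarithm of the initial miRNA
    concentration, a concentration-level model of associative
    strand-displacement signal conversion, an in-silico training pipeline
    (differential-expression screen, random-forest importance ranking,
    class-weighted linear support-vector machines, minimal-panel selection),
    and synthetic-data generators that emulate a two-class serum miRNA
    profiling study for end-to-end validation of hepatocellular carcinoma
    diagnosis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    randomForest,
    e1071,
    pROC,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'DNAclassify-package.R'
    'crn-core.R'
    'classifier-compiler.R'
    'classifier-io.R'
    'crn-io.R'
    'ml-training.R'
    'pcr-frontend.R'
    'signal-transformation.R'
    'pipeline.R'
    'synthetic-data.R'
    'utils.R'
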