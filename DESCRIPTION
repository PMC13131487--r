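Package: nociscreen
Title: Screening Analytics for GPCR Agonists That Silence CGRP+ Nociceptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based quantification pipeline for a Gi/o-coupled GPCR
    agonist screen in CGRP+ dorsal root ganglion (DRG) sensory neurons.
    Implements the KCl-pulse calcium-imaging excitability classifier
    (per-trial max dF/F, baseline QC, +/-15 percent drug-effect rule, soma
    diameter strata), a subtype-restricted GPCR expression screen over
    gene-by-subtype summaries, GloSensor cAMP assay normalization with
    dose-response and constitutive-activity indices, nocifensive behavior
    quantifiers (von Frey 50 percent threshold, dynamic-brush allodynia,
    pinprick validity and movement magnitude, paw-luminance ratios,
    temperature preference, annotated-event summaries), and optically
    evoked EPSC baseline normalization with recording-stability QC.
    Every input can be simulated with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
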