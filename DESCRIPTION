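Package: circuitDyn
Title: Dynamic Network Reconfiguration of Receptor-Defined Brain Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying static and dynamic functional connectivity of
    monoaminergic (serotonergic, dopaminergic, noradrenergic) brain circuits
    in relation to fatigue in multiple sclerosis. Delineates receptor- and
    transporter-defined circuits from normalized PET density vectors via
    elbow or top-fraction cut-offs, computes sliding-window functional
    connectivity from region-averaged BOLD time series, assigns each region a
    window-wise resting-state-network allegiance, derives reconfiguration
    metrics (flexibility, promiscuity, cohesion, disjointedness), classifies
    fatigue groups from FSMC scores, and compares groups with covariate-
    adjusted ANCOVA under family-wise Benjamini-Hochberg correction. Includes
    a synthetic-cohort generator with planted switching structure and group
    effects so the whole pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
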