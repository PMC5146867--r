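Package: mcemri
Title: Molecular Contrast-Enhanced MRI Quantification of Gene Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for molecular
    contrast-enhanced (MCE) MRI, in which sequence-targeted
    superparamagnetic iron oxide nanoparticle (SPION) probes report
    regional mRNA abundance as an elevation of the effective transverse
    relaxation rate R2*. Provides a synthetic multi-echo gradient-echo
    phantom generator with known ground truth, voxelwise R2* relaxometry,
    delta-R2* / CNR / subtraction-map statistics with baseline
    stratification, delta-delta-Ct qPCR quantification, antisense
    oligonucleotide design checks (reverse complement, amplicon length,
    in-silico duplex calls), photocell beam-break locomotor analysis, and
    an end-to-end calibration of delta-R2* against mRNA copy number.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    igraph,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
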