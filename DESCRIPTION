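Package: lipidmsi
Title: Reproducibility-Filtered MALDI-MSI Lipidomics of FFPE Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for MALDI mass spectrometry imaging (MSI)
    lipidomics of formalin-fixed paraffin-embedded tissue. Builds
    reproducibility-filtered master peak lists across technical and biological
    replicates (ppm-window mass merging, coefficient-of-variation gates,
    ROC-based matrix-peak removal, isotope filtering), computes whole-dataset,
    intraday and interday CV robustness metrics, tests tumor versus necrosis
    region differences with iterative pixel-subsampled linear mixed models,
    discovers treatment markers with Wilcoxon rank-sum tests, pixel-level ROC
    analysis and PCA, and annotates masses by accurate-mass lipid adduct
    matching. Includes imzML input/output and a ground-truthed synthetic MSI
    study generator emulating a treated-versus-control xenograft design, so
    that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils,
    tools,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
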