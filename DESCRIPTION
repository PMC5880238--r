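Package: mirdosage
Title: Dosage Sensitivity Inference from Conserved miRNA Targeting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs gene dosage sensitivities from the conservation of
    microRNA target sites in 3' UTRs. Scans untranslated regions for
    canonical seed-match sites (8mer, 7mer-m8, 7mer-A1), calls sites
    conserved with perfect identity across species pairs from per-gene
    multiple alignments, estimates per-gene background conservation with a
    shuffled-seed permutation null, segments UTRs into regions of
    homogeneous background conservation, and compares gene classes (X-Y
    pairs, X-inactivated, X escape; Z-W pairs, Z without W homolog;
    autosomal copy-number strata) with exact and asymptotic rank tests,
    gene resampling, and multinomial logistic regression with AIC-based
    predictor ablation. Includes a synthetic-data generator emulating every
    input dialect so the full pipeline is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nnet,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
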