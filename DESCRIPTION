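Package: tepwarehouse
Title: Tumour-Exclusive Peptide Discovery and HLA Peptide Warehouse Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of HLA immunopeptidomes for tumour vaccine
    design. Takes per-sample HLA-presented peptide identification tables and a
    benign reference ligandome, applies identification and spectral quality
    filters, annotates HLA class I binders with position-specific scoring
    motifs, calls HPV status from oncogene RNA read counts, computes
    tumour-exclusive peptides (TEP) with cohort prevalence and HPV
    stratification, estimates source-protein saturation and cohort statistics
    (allele enrichment, mass-yield correlation, population coverage), and
    builds an HLA-allotype-indexed peptide warehouse by multiobjective
    (size versus carrier coverage) optimisation, from which semi-personalised
    per-patient peptide compositions are assembled. Includes a synthetic
    cohort generator with planted ground truth so the whole pipeline is
    testable without access to measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
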