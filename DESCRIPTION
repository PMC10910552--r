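Package: bestvar
Title: Mutation Landscape, Conservation, and Prevalence Analysis for BEST1 Bestrophinopathies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Curates a catalogue of pathogenic BEST1 variants under explicit
    allele-frequency and evidence filters, maps variants onto the
    bestrophin-1 transmembrane topology model, computes sliding-window and
    per-site ortholog conservation, correlates conservation with inheritance
    pattern and disease type per protein region, and derives cohort
    prevalence bounds in 1-in-N and per-100,000 form. Ships a synthetic-data
    generator that produces variant catalogues, ortholog families, and
    stratified cohort counts with recorded ground truth so that every
    pipeline stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Biostrings, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
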