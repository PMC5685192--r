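Package: xciase
Title: X-Chromosome Inactivation Inference from Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-gene X-chromosome inactivation (XCI) status from
    allele-specific expression (ASE) read counts, in two complementary
    designs: bulk multi-tissue ASE from a donor with fully skewed XCI, and
    single-cell ASE with reference-free (or trio-based) haplotype phasing.
    Includes exact binomial and signed-rank machinery with an empirical
    allele-miscall error bound, Jeffreys binomial intervals, BH and Storey
    q-values, a label-permutation engine, harmonization of prior XCI-status
    catalogues, sex-bias category statistics with an X-Y homolog re-test,
    PAR1 X/Y dosage testing, chromatin-state enrichment with permutation
    calibration, and a synthetic-data generator that emulates every input
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
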