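Package: chdyn
Title: Clonal Hematopoiesis Dynamics from Serial Whole-Blood and Plasma Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of clonal hematopoiesis (CH) from serial error-corrected
    variant calls in whole blood and plasma cell-free DNA. Implements the
    variant-retention and classification cascade (somatic CH, germline, SNP
    exclusion, recurrent-hotspot rescue), hematopoietic versus tumor-shed
    origin attribution for paired cfDNA calls, rule-based pathogenic germline
    homologous-recombination-deficiency calling, closed-form clonal fitness
    estimation under a sigmoid clone-growth model with per-treatment-phase
    decomposition, single-cell DNA genotype clone inference with doublet-aware
    mutual-exclusivity testing, and cohort-level statistics (Fisher and
    Wilcoxon tests, mutation co-occurrence with FDR control, VAF concordance).
    A synthetic-cohort generator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
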