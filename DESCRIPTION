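Package: casevar
Title: Case-Exclusive Variant Discovery for Mendelian Traits in Small Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of the whole-genome
    rare-variant discovery strategy used for dominant Mendelian traits in
    companion animals: filtering a multi-sample VCF for variants shared by
    all affected individuals under a heterozygous (dominant) or homozygous
    (recessive) model and absent from a control-genome panel; transcript-aware
    SNV consequence annotation with HGVS c./p. nomenclature; cross-species
    residue conservation scoring from a protein multiple alignment;
    pedigree-aware dominant-segregation checks and cohort genotype-phenotype
    association tables; and a deterministic synthetic-cohort generator that
    emits complete desk-scale fixtures (reference, gene models, VCF, sample
    sheet, pedigree, alignment) with a ground-truth table so the entire
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
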