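Package: neoprior
Title: Neoantigen Candidate Prioritization and Vaccine Immunomonitoring
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate neoepitopes from annotated somatic missense
    variants using HLA binding percent-rank thresholds and an alignment-free
    k-mer kernel similarity between wild-type and mutant peptides, classifying
    candidates into strong-binder (A), dissimilar-both-binder (B) and
    negative-control groups, with a class II binding-core containment filter.
    Also implements the immunomonitoring statistics used in therapeutic
    cancer-vaccine trials: IFNg ELISPOT normalization and response scores,
    delayed-type hypersensitivity (DTH) grading and scores, DTH-ELISPOT
    correlation, calcein-release specific lysis, and tumor mutational burden.
    A synthetic-cohort generator with planted group structure, overdispersed
    censored spot counts and a latent DTH-ELISPOT correlation makes every
    pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
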