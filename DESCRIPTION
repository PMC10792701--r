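Package: hetpanel
Title: Tumor Heterogeneity Biomarker Panels from Somatic Variants and
    Copy Number
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-sample tumor heterogeneity biomarkers from
    whole-exome somatic variant calls and allele-specific copy-number
    segments: tumor mutational burden (total and subclonal), mutant-allele
    tumor heterogeneity (MATH), tumor-adjusted variant allele frequency
    (TVAF), binomial clonality classification, 96-channel mutational
    signature refitting, purity/ploidy estimation anchored on
    histopathological purity, whole-genome-doubling and HRD scar scores
    (LOH/LST/TAI), genome fractions and arm/gene-level copy-number events.
    Includes cohort-level group comparison with Benjamini-Hochberg
    correction, correlation pruning, per-marker ROC with DeLong intervals,
    a leave-one-out cross-validated logistic model, and a two-group
    synthetic cohort generator so the full pipeline runs without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    GenomeInfoDb,
    SummarizedExperiment,
    methods,
    generics,
    ggplot2,
    pracma,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    VariantAnnotation,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
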