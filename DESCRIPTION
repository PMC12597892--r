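Package: gwash
Title: Harmonization, Validation and Meta-Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates, repairs and harmonizes genome-wide association study
    (GWAS) summary statistics against a curated dbSNP-style variant reference.
    Infers the genome build (GRCh37/GRCh38), restores or updates rsIDs
    (including retired, merged identifiers), drops variants incompatible with
    the reference alleles, imputes missing statistics columns (Z, B, SE, P, N)
    from closed-form identities, and writes chromosome-partitioned Parquet
    datasets that can be queried lazily with 'arrow'. A fixed-effects
    inverse-variance meta-analysis with Cochran's Q and I-squared heterogeneity
    statistics runs directly on the partitioned output. Deterministic synthetic
    fixture generators for reference panels and raw summary statistics make the
    whole pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
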