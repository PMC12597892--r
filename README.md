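# gwash

Harmonization, validation and meta-analysis of GWAS summary statistics.

## The problem

Genome-wide association studies are shared as per-variant summary tables
(effect size, standard error, P value, allele frequency, sample size), but
there is no agreed format: column names, chromosome labels, variant
identifiers and the set of reported statistics differ between every study.
Before any downstream analysis — polygenic scores, heritability estimation,
meta-analysis, fine-mapping — each file has to be "munged" into shape.

`gwash` separates that munging into *validation* and *harmonization*, and
deliberately leaves quality control (strand-ambiguous SNP removal, INFO or
MAF thresholds) to downstream filters, so a file is cleaned **once** and
reused everywhere. Given a raw summary-statistics table and a curated
dbSNP-style variant reference, the pipeline:

1. parses the file (tab/comma/semicolon/whitespace, optionally gzipped) and
   guesses the mapping of its headers onto canonical columns;
2. removes rows missing critical values, deduplicates on variant identity,
   detects indels, and validates every column (chromosome labels `chr1`,
   `ch1`, `23` are harmonized; `P` outside (0, 1], negative `SE`, malformed
   alleles remove the row);
3. infers the genome build by matching up to 10,000 rows against GRCh37 and
   GRCh38 positions, then merges with the reference by `CHR:POS` (or by rsID,
   updating retired/merged identifiers), restoring the rsID and positions on
   **both** builds and dropping variants absent from the reference or with
   incompatible alleles;
4. imputes missing statistics columns from closed-form identities
   (`Z = B/SE`; `Z = sign(B) * sqrt(qchisq(P, 1, lower = FALSE))`;
   `B = Z / sqrt(2 EAF (1-EAF) (N + Z^2))` and its SE twin;
   `P = 2 * pnorm(-|Z|)`; `N = 4 / (2 MAF (1-MAF) SE^2)`), never overwriting
   observed values;
5. optionally compares allele frequencies against a reference
   superpopulation (flagging differences > 0.2);
6. writes chromosome-partitioned Parquet (hive-style `CHR=<label>/`), which
   `arrow` queries lazily — many cleaned studies behave as one dataset.

On top of that format, `meta_analyse()` runs a fixed-effects
inverse-variance meta-analysis with
`w_i = 1/SE_i^2`, `B = Σ w_i B_i / Σ w_i`, `SE = 1/sqrt(Σ w_i)`, Cochran's
`Q = Σ w_i (B_i - B)^2`, heterogeneity P from the upper χ²(k−1) tail, and
`I² = max(0, (Q-(k-1))/Q) × 100`, with per-study allele alignment and
METAL-style direction strings.

Everything is testable offline: the `fixture_spec()` / `make_reference()` /
`make_sumstats()` generators build seeded synthetic panels and raw files
with known ground truth, including planted defects whose per-filter removal
counts are recovered exactly.

## A worked example

```r
library(gwash)

spec  <- fixture_spec(seed = 7, n_variants = 300,
                      corruption = list(duplicate_rows = 4, invalid_p = 2))
panel <- make_reference(spec, file.path(tempdir(), "panel"))
sim   <- make_sumstats(spec, panel, build = 38)

res <- harmonise_sumstats(sim$raw, panel)
res
#> <gwash_result>
#> <build_call> GRCh38 (0 GRCh37 vs 298 GRCh38 matches over 298 rows)
#> <cleaning_report> 304 rows in, 298 rows out
#> # A tibble: 6 x 2
#>   step                removed
#>   <chr>                 <int>
#> 1 missing_critical          0
#> 2 duplicates                4
#> 3 validation                2
#> 4 no_dbsnp_match            0
#> 5 allele_incompatible       0
#> 6 indel_dropped             0
```

The raw file carried 304 rows (300 variants plus 4 planted duplicates); the
pipeline called the build GRCh38 (298 of 298 sampled rows matched GRCh38
coordinates, none GRCh37), removed the 4 duplicates and the 2 rows with an
out-of-range P value, and harmonized the remaining 298. `tidy(res)` returns
the harmonized tibble with both-build positions restored from the panel:

```r
head(tidy(res)[, c("RSID", "CHR", "POS_37", "POS_38", "EffectAllele",
                   "OtherAllele", "B", "SE", "P")], 3)
#>   RSID   CHR    POS_37  POS_38 EffectAllele OtherAllele        B      SE        P
#> 1 rs6245 3     5166116 5169116 T            C           -0.0242  0.00448 7.02e- 8
#> 2 rs3449 2     3937022 3939022 TTGC         T           -0.0367  0.00515 1.03e-12
#> 3 rs4680 2     8980684 8982684 G            C           -0.00429 0.00452 3.42e- 1
```

`glance(res)` gives a one-row run summary; `autoplot(res)` draws the
removals bar chart. Writing with `output = <dir>` produces the partitioned
dataset, after which:

```r
query_region(list("study1", "study2"), chr = "2", start = 1.7e6, end = 2.3e6,
             build = 38, p_max = 5e-8)   # significant hits across studies
meta <- meta_analyse(list("study1", "study2"))
glance(meta)
```

A thin command-line wrapper (`inst/cli/gwash.R`) exposes the same pipeline
as `gwash clean | meta | query | make-fixtures | curate-ref`.

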