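---
title: "Harmonizing GWAS summary statistics with gwash: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing GWAS summary statistics with gwash}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwash)
```

## Scope and philosophy

`gwash` validates and harmonizes GWAS summary statistics; it does not do
quality control. The distinction matters operationally: QC choices
(strand-ambiguous SNP removal, imputation-quality or frequency thresholds)
depend on the downstream application, while validation (a P value must lie
in (0, 1]) and harmonization (a variant's identity is its dbSNP record)
do not. The pipeline therefore applies only filters every application
agrees on, and returns enough information — both-build positions, flags for
indels, multiallelics, strand flips, frequency outliers — for any
downstream filter to be applied afterwards without re-cleaning.

## The reference panel and its curation

Variant identity is anchored in a curated dbSNP-style panel: per variant an
integer rsID number, a chromosome, 1-based positions on **both** GRCh37 and
GRCh38, a reference allele and one or more alternate alleles (multiallelic
sites are one record with comma-joined alternates). Indels live in a
separate partition with left-aligned, trimmed allele representations.

`curate_reference()` makes the panel internally consistent with four
filters, applied in this order (order affects the counts, so the counts are
reported per filter):

1. an rsID observed at more than one genomic position is removed entirely —
   both records are untrustworthy;
2. where several rsIDs share one chromosome:position, the smallest rsID
   number survives ("smallest" is numeric: rs45 < rs123 — lexicographic
   order would invert it);
3. records whose chromosome differs between the builds are removed;
4. only records with positions on both builds are kept.

After these, chromosome:position is a key on each build, which is what
makes position-based matching well-defined. Curation is idempotent;
re-curating survivors removes nothing (asserted in tests).

Retired rsIDs are handled through a merged-identifier map. Merges chain
across dbSNP releases, so the map is resolved transitively to each chain's
terminal identifier at load time; a cycle in the map is a data error and
fatal. On disk the panel is hive-partitioned Parquet (`CHR=<label>/`), and
the loader pins the partition column to a string type so chromosome labels
like `X` and `1` behave identically.

## Column mapping

The header dictionary maps common dialects (PLINK, GWAS catalog, METAL,
SAIGE/BOLT-style) case-insensitively onto a canonical vocabulary of
fourteen columns. Two deliberate choices: two headers mapping to one
canonical column is fatal rather than first-wins, because it almost always
indicates a mis-specified file; and `MAF` is accepted as `EAF` only when no
EAF-proper column exists, with a logged notice, because the minor-allele
frequency equals the effect-allele frequency only when the effect allele
happens to be minor. An explicit user mapping bypasses guessing entirely.

## Row-level validation

Missing-value handling distinguishes three cases. Alleles are always
required. Variant identity requires either an rsID or a complete
chromosome + position; when *all three* are present the rsID column is
dropped and restored from the reference, because study-supplied rsIDs are
the least reliable of the three. Deduplication keys on
chromosome:position:{allele pair} (or rsID:{allele pair}), with the allele
pair treated as an unordered set so `(A,G)` and `(G,A)` at one site
collapse; the first occurrence survives, which makes the step deterministic
and order-auditable.

The per-column domains: P in (0, 1] with P = 0 rescued to the smallest
positive normal double and flagged `p_zero` (underflowed genome-wide hits
are an encoding artifact, not bad data); EAF strictly inside (0, 1);
SE > 0; INFO in [0, 1.1] because common imputation dialects slightly exceed
1; N, CaseN, ControlN positive, with N < CaseN + ControlN logged but kept;
positions in [1, 3e8]; B and Z finite; chromosome labels normalized
(`chr1`/`ch1`/`CHR1` to `1`, PLINK's 23/24/25 to X/Y/MT) and restricted to
1–22, X, Y, MT; allele strings over A/C/G/T or the legacy indel codes
D/I/R. A value that fails its domain removes the row; a genuinely missing
value never does. If more than half of a column's non-missing cells fail
numeric coercion the run aborts naming the column — that is a mapping
error, not a data error.

## Genome-build inference and identity repair

The build is called by matching up to 10,000 rows against the panel's
GRCh37 and GRCh38 positions and taking the build with more matches. The
sample is the *first* 10,000 cleaned rows, not a random draw: determinism
is worth more here than unbiasedness, since any genuine overlap dominates
the comparison. A tie resolves to GRCh38 (the newer build) with a warning;
zero matches on both builds is fatal.

Compound identifiers (`chr1:12345`, `1:12345:A:G`) in the rsID column are
split into chromosome and position before inference, with embedded alleles
ignored in favor of the allele columns. Splitting runs before build
inference because an rsID-only file whose identifiers are all compound has
usable positions only after the split; for files matched purely by rsID no
build call is needed at all (the panel supplies both builds).

Matching attaches the panel rsID, both positions and the panel reference
allele. The study allele pair {EffectAllele, OtherAllele} is compatible
with a panel record when it is a subset of {ref} ∪ alts with at least one
member equal to ref — either as observed or after base complementation.
Complemented matches are kept and flagged `strand_flipped` rather than
dropped: accepting them matches community practice, and the flag preserves
auditability. Palindromic pairs (A/T, C/G) match trivially in both
orientations and are *not* removed — that is a QC decision left
downstream. A row compatible with several alternates of a multiallelic
record is kept once, and rows sharing a restored rsID are all flagged
`multi_allelic`. Indel rows are normalized with the same
left-align-and-trim procedure as the panel before matching against the
indel partition; legacy D/I/R codes carry no sequence and cannot match a
sequence-resolved reference, so under the `qc` strategy they are dropped
(with the `keep` strategy they pass through unmatched).

## Statistics imputation

Missing statistics columns are filled from these identities, in this
order, never overwriting an observed value:

| filled | from | identity |
|---|---|---|
| Z | B, SE | `Z = B/SE` |
| Z | B, P (SE absent) | `Z = sign(B) * sqrt(qchisq(P, 1, lower = FALSE))` |
| B, SE | Z, N, EAF | `B = Z/d`, `SE = 1/d`, `d = sqrt(2 EAF (1-EAF) (N + Z^2))` |
| P | Z | `P = 2 * pnorm(-|Z|)` |
| N | SE, EAF | `N = 4 / (2 MAF (1-MAF) SE^2)`, `MAF = min(EAF, 1-EAF)` |

Two passes are run so an early fill can feed a later one; two passes are
the fixpoint of this dependency graph. P from Z is computed in log space so
the tail survives to |Z| ≈ 37 before the two-sided double underflows. Rows
where a formula degenerates (EAF of exactly 0 or 1, non-positive N) skip
that imputation and are flagged `repair_skipped`.

The N identity carries a factor 4 — the effective-sample-size convention
for case-control designs (`N_eff = 4 / (1/Ncases + 1/Ncontrols)`). Note
that it is *not* the algebraic inverse of the SE identity: inverting
`SE = 1/sqrt(2 EAF (1-EAF) (N + Z^2))` at Z = 0 gives a factor 1, not 4.
The two conventions cannot hold simultaneously, so a dataset in which
B, SE, Z, P and EAF are mutually consistent will round-trip every column
*except* N through deletion-and-repair. The printed convention is
implemented as stated; the synthetic generator makes the Z/P/B/SE
identities exact and the test suite checks the N formula against direct
arithmetic instead of a round trip.

## Storage and queries

Cleaned output is hive-partitioned Parquet by chromosome (or a single
gzipped TSV), with the cleaning report and run metadata as
underscore-prefixed JSON sidecars in the dataset root — the underscore
keeps them invisible to arrow's dataset discovery while keeping the
partition directories at the root as the layout's contract requires.
Missing values are native Parquet nulls, never sentinel numbers, which is
what makes the write/read round trip bit-exact. Region queries are 1-based
closed intervals, consistent with dbSNP/VCF coordinates, on either build's
position column; only the requested chromosome partition is scanned.

## Meta-analysis

Pooling is inverse-variance fixed-effects on (B, SE) — the canonical
reading of "fixed-effects meta-analysis" when effects and standard errors
are available — rather than sample-size-weighted Z pooling. Variants are
grouped by rsID *plus* unordered allele set, so multiallelic sites pool
per allele pair. Within a group the first contributing study's allele
orientation is canonical; a study reporting the pair swapped contributes
−B (and 1−EAF), and a study reporting a different allele set at the same
rsID forms its own group, appearing as `?` in the other group's direction
string. Heterogeneity uses Cochran's Q with k−1 degrees of freedom;
k = 1 leaves Q, its P value and I² missing (df = 0 is undefined), and
single-study variants are only emitted when `min_k = 1` is requested
(default 2), to avoid presenting unpooled rows as meta-analyzed.
Processing is per chromosome partition, so memory is bounded by one
chromosome of all studies, not by the union of datasets.

## The synthetic generators

`make_reference()` emulates the curated panel: positions uniform within
each chromosome, per-chromosome build offsets (so the builds disagree at
every site, which is what makes build inference testable), a configurable
indel fraction stored left-aligned in the indel partition, multiallelic
sites, and a merged-rsID map containing short chains. `make_sumstats()`
draws variants from the panel and simulates EAF ~ U(0.05, 0.95), a true
effect β ~ N(0, 0.02²) observed with sampling noise at
SE₀ = 1/sqrt(2 EAF (1−EAF) N) with N = 100,000 by default (a typical
modern biobank-scale GWAS), then derives the reported B and SE through the
Z/N/EAF identities so the statistics columns are mutually consistent and
individually recoverable. Corruptions — missing alleles, duplicates,
invalid P/EAF/SE, off-panel positions, incompatible alleles, compound
identifiers, `chr`-prefixed labels, swapped alleles — are planted on
*disjoint* row sets (and only on SNV rows), so every cleaning-report entry
has one unambiguous expected count; headers are renamed to randomly chosen
dialect aliases and rows shuffled. A single integer seed drives all
randomness through locally scoped RNG state, so generators are pure
functions of their spec and never disturb the caller's stream.

What the generators do **not** emulate: linkage disequilibrium between
variants, realistic allele-frequency spectra, population stratification, or
correlated noise across studies. Passing tests therefore demonstrate the
*mechanics* — exact filter attribution, identity restoration, formula
algebra, pooling arithmetic — not robustness to the statistical structure
of real GWAS data.

## Problem sizes and numerical choices

The test suite and the acceptance script run on panels of 400–1,000
variants over three chromosomes, 100 repeated build calls at 40% panel
overlap, meta-analysis oracles at 1,000 variants × 10 studies, and a
calibration study at 10,000 variants — sizes chosen so the full suite
completes in about a minute on one core while every code path (including
per-chromosome partition iteration) is exercised. Floating-point
tolerances mirror what the algebra supports: 1e−12 relative for the B/SE/Z
identity (pure arithmetic), 1e−6 for the Z→P→Z round trip (quantile
functions at extreme tails), 1e−10 against the meta-analysis oracle, and
exact (`identical()`) for Parquet round trips and end-to-end determinism.

## Known limitations

- Liftover is never computed: both-build positions come from the panel, so
  variants absent from it cannot be mapped across builds.
- D/I/R indel codes cannot be matched to a sequence-resolved reference and
  are effectively dropped under the `qc` strategy.
- The frequency reference covers SNVs only, one alternate allele per
  variant.
- Remote inputs (URLs, repository accessions) are accepted by the CLI as a
  convenience but are outside the tested surface.
- Meta-analysis assumes independent studies; overlapping samples inflate
  precision and are not corrected for.
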