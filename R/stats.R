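# Imputation of missing statistics columns from closed-form identities, and
# allele-frequency comparison against a reference population.

#' Impute missing statistics columns
#'
#' Fills missing columns from the ones present, using these identities in
#' this order, never overwriting an observed value:
#'
#' 1. `Z = B / SE` (B, SE present)
#' 2. `Z = sign(B) * sqrt(qchisq(P, 1, lower = FALSE))` (B, P present, SE absent)
#' 3. `B = Z / sqrt(2 * EAF * (1 - EAF) * (N + Z^2))` and
#'    `SE = 1 / sqrt(2 * EAF * (1 - EAF) * (N + Z^2))` (Z, N, EAF present)
#' 4. `P = 2 * pnorm(-|Z|)` (Z present)
#' 5. `N = 4 / ((2 * MAF * (1 - MAF)) * SE^2)` with `MAF = min(EAF, 1 - EAF)`
#'    (SE, EAF present, N absent; effective-N convention for case-control
#'    designs)
#'
#' Two passes are run, so a value imputed by an earlier identity can feed a
#' later one (this is the fixpoint for this dependency graph). Rows where a
#' formula would divide by zero (`EAF` of exactly 0 or 1, `N <= 0`) are
#' skipped for that imputation and flagged `repair_skipped`.
#'
#' @param tbl Harmonized tibble with numeric statistics columns (any subset
#'   of `B`, `SE`, `Z`, `P`, `EAF`, `N`).
#' @return The tibble with missing statistics filled where possible.
#' @export
repair_stats <- function(tbl) {
  for (col in c("B", "SE", "Z", "P", "EAF", "N")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
  }
  if (!"repair_skipped" %in% names(tbl)) tbl$repair_skipped <- FALSE
  n <- nrow(tbl)
  if (n == 0L) return(tbl)

  for (pass in 1:2) {
    # Z from B and SE
    i <- is.na(tbl$Z) & !is.na(tbl$B) & !is.na(tbl$SE)
    tbl$Z[i] <- tbl$B[i] / tbl$SE[i]

    # Z from B and P (only when SE is unavailable)
    i <- is.na(tbl$Z) & !is.na(tbl$B) & !is.na(tbl$P) & is.na(tbl$SE)
    tbl$Z[i] <- sign(tbl$B[i]) * sqrt(qchisq(tbl$P[i], df = 1, lower.tail = FALSE))

    # B and SE from Z, N, EAF
    usable <- !is.na(tbl$Z) & !is.na(tbl$N) & !is.na(tbl$EAF)
    degen <- usable & (tbl$EAF <= 0 | tbl$EAF >= 1 | tbl$N <= 0)
    tbl$repair_skipped <- tbl$repair_skipped |
      (degen & (is.na(tbl$B) | is.na(tbl$SE)))
    ok <- usable & !degen
    denom <- sqrt(2 * tbl$EAF * (1 - tbl$EAF) * (tbl$N + tbl$Z^2))
    i <- is.na(tbl$B) & ok
    tbl$B[i] <- tbl$Z[i] / denom[i]
    i <- is.na(tbl$SE) & ok
    tbl$SE[i] <- 1 / denom[i]

    # P from Z (log-space tail so |Z| > 8 does not underflow prematurely)
    i <- is.na(tbl$P) & !is.na(tbl$Z)
    tbl$P[i] <- 2 * exp(pnorm(-abs(tbl$Z[i]), log.p = TRUE))

    # N from SE and MAF (effective N, factor 4 by convention)
    usable <- is.na(tbl$N) & !is.na(tbl$SE) & !is.na(tbl$EAF)
    degen <- usable & (tbl$EAF <= 0 | tbl$EAF >= 1)
    tbl$repair_skipped <- tbl$repair_skipped | degen
    i <- usable & !degen
    maf <- pmin(tbl$EAF[i], 1 - tbl$EAF[i])
    tbl$N[i] <- 4 / ((2 * maf * (1 - maf)) * tbl$SE[i]^2)
  }
  tbl
}

#' Append reference allele frequencies for a chosen population
#'
#' Attaches a per-variant `EAF_ref` column from a frequency reference table:
#' the reference alternate-allele frequency when the study effect allele is
#' the panel alternate allele, and its complement when the effect allele is
#' the panel reference allele. When the study's own `EAF` is missing it is
#' filled from `EAF_ref` and flagged `eaf_imputed`.
#'
#' @param tbl Repaired tibble with `RSID`, `EffectAllele`, `OtherAllele`.
#' @param freq_ref Frequency reference: data frame with columns `RSID`
#'   (integer rs number), `POP`, `ALT` (the allele the frequency refers to)
#'   and `ALT_FREQ` in \[0, 1\], one row per (variant, population).
#' @param population Population label present in `freq_ref$POP`
#'   (e.g. one of AFR, AMR, EAS, EUR, SAS).
#' @return The tibble with `EAF_ref` (and possibly updated `EAF`,
#'   `eaf_imputed`).
#' @export
append_reference_freq <- function(tbl, freq_ref, population) {
  freq_ref <- tibble::as_tibble(freq_ref)
  if (!population %in% unique(freq_ref$POP)) {
    abort(paste0("population '", population, "' not present in frequency reference"))
  }
  fr <- freq_ref |>
    dplyr::filter(.data$POP == .env$population) |>
    dplyr::transmute(RSID = paste0("rs", .data$RSID),
                     ref_alt = .data$ALT, ref_alt_freq = .data$ALT_FREQ)
  out <- dplyr::left_join(tbl, fr, by = "RSID")
  out$EAF_ref <- dplyr::case_when(
    is.na(out$ref_alt) ~ NA_real_,
    out$EffectAllele == out$ref_alt ~ out$ref_alt_freq,
    out$OtherAllele == out$ref_alt ~ 1 - out$ref_alt_freq,
    .default = NA_real_
  )
  out$eaf_imputed <- is.na(out$EAF) & !is.na(out$EAF_ref)
  out$EAF[out$eaf_imputed] <- out$EAF_ref[out$eaf_imputed]
  dplyr::select(out, -"ref_alt", -"ref_alt_freq")
}

#' Flag allele-frequency mismatches against the reference
#'
#' Marks `freq_diff = TRUE` where the study effect-allele frequency differs
#' from the reference-population frequency by more than the threshold
#' (default 0.2). Rows lacking either value get `NA`, not `FALSE`; no rows
#' are removed.
#'
#' @param tbl Tibble with `EAF` and `EAF_ref` (see [append_reference_freq()]).
#' @param threshold Absolute difference above which a variant is flagged.
#' @return The tibble with a logical `freq_diff` column.
#' @export
add_freq_diff_flag <- function(tbl, threshold = 0.2) {
  if (!"EAF_ref" %in% names(tbl)) {
    abort("EAF_ref column missing: call append_reference_freq() first")
  }
  tbl$freq_diff <- abs(tbl$EAF - tbl$EAF_ref) > threshold
  tbl
}
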