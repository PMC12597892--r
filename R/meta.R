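# Fixed-effects inverse-variance meta-analysis over cleaned datasets, with
# Cochran's Q, I-squared and METAL-style direction strings.

#' Align per-study effects for one variant
#'
#' The first contributing study's (EffectAllele, OtherAllele) orientation is
#' canonical. A study reporting the same pair swapped contributes its effect
#' negated (and `1 - EAF`); a study whose allele set does not match the
#' canonical set is excluded from pooling and contributes `?` to the
#' direction string.
#'
#' @param rows Tibble of per-study records for one variant: columns `study`,
#'   `EffectAllele`, `OtherAllele`, `B`, `SE`, and optionally `EAF`, `N`.
#' @return The tibble with aligned `B` (and `EAF`), plus logical `aligned`
#'   (usable for pooling) and the canonical alleles in every row.
#' @export
align_effects <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  ea0 <- rows$EffectAllele[1]
  oa0 <- rows$OtherAllele[1]
  same <- rows$EffectAllele == ea0 & rows$OtherAllele == oa0
  swapped <- rows$EffectAllele == oa0 & rows$OtherAllele == ea0
  rows$B <- dplyr::if_else(swapped, -rows$B, rows$B)
  if ("EAF" %in% names(rows)) {
    rows$EAF <- dplyr::if_else(swapped, 1 - rows$EAF, rows$EAF)
  }
  rows$aligned <- same | swapped
  rows$EffectAllele <- ea0
  rows$OtherAllele <- oa0
  rows
}

#' Pool per-study effects with inverse-variance weights
#'
#' Lower-level engine behind [meta_analyse()]: takes a long per-study table
#' already in memory and returns the pooled per-variant results. `study`
#' should be a factor whose level order is the study input order (it drives
#' the direction string); a character column is converted in order of first
#' appearance.
#'
#' @param long Tibble with columns `study`, `RSID`, `EffectAllele`,
#'   `OtherAllele`, `B`, `SE` and optionally `EAF`, `N`, `CHR`, `POS_37`,
#'   `POS_38`.
#' @param min_k Minimum contributing studies per reported variant.
#' @return A tibble of per-variant pooled results (see [meta_analyse()]).
#' @export
pool_fixed_effects <- function(long, min_k = 2L) {
  stopifnot(all(c("study", "RSID", "EffectAllele", "OtherAllele", "B", "SE")
                %in% names(long)))
  if (!is.factor(long$study)) long$study <- factor(long$study, levels = unique(long$study))
  studies <- levels(long$study)
  if (!"EAF" %in% names(long)) long$EAF <- NA_real_
  if (!"N" %in% names(long)) long$N <- NA_real_
  for (col in c("CHR", "POS_37", "POS_38")) {
    if (!col %in% names(long)) long[[col]] <- NA
  }

  long <- long |>
    dplyr::mutate(.key = paste(.data$RSID,
                               pmin(.data$EffectAllele, .data$OtherAllele),
                               pmax(.data$EffectAllele, .data$OtherAllele),
                               sep = ":")) |>
    dplyr::arrange(.data$.key, as.integer(.data$study))

  # vectorized equivalent of align_effects() applied per .key group
  aligned <- long |>
    dplyr::group_by(.data$.key) |>
    dplyr::mutate(.ea0 = dplyr::first(.data$EffectAllele),
                  .oa0 = dplyr::first(.data$OtherAllele)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      .same = .data$EffectAllele == .data$.ea0 & .data$OtherAllele == .data$.oa0,
      .swap = .data$EffectAllele == .data$.oa0 & .data$OtherAllele == .data$.ea0,
      B = dplyr::if_else(.data$.swap, -.data$B, .data$B),
      EAF = dplyr::if_else(.data$.swap, 1 - .data$EAF, .data$EAF),
      aligned = .data$.same | .data$.swap,
      EffectAllele = .data$.ea0,
      OtherAllele = .data$.oa0
    ) |>
    dplyr::select(-".ea0", -".oa0", -".same", -".swap")

  usable <- aligned$aligned & !is.na(aligned$B) & !is.na(aligned$SE) & aligned$SE > 0

  direction_of <- function(study, b, use) {
    d <- rep("?", length(studies))
    idx <- as.integer(study)[use]
    d[idx] <- dplyr::case_when(b[use] > 0 ~ "+", b[use] < 0 ~ "-", .default = "0")
    paste(d, collapse = "")
  }

  res <- aligned |>
    dplyr::mutate(.use = usable, w = dplyr::if_else(usable, 1 / .data$SE^2, NA_real_)) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      RSID = .data$RSID[1],
      CHR = .data$CHR[1],
      POS_37 = .data$POS_37[1],
      POS_38 = .data$POS_38[1],
      EffectAllele = .data$EffectAllele[1],
      OtherAllele = .data$OtherAllele[1],
      k = sum(.data$.use),
      B_meta = sum(.data$w[.data$.use] * .data$B[.data$.use]) / sum(.data$w[.data$.use]),
      SE_meta = 1 / sqrt(sum(.data$w[.data$.use])),
      Q = sum(.data$w[.data$.use] * (.data$B[.data$.use] - B_meta)^2),
      N_total = if (all(is.na(.data$N[.data$.use]))) NA_real_
                else sum(.data$N[.data$.use], na.rm = TRUE),
      direction = direction_of(.data$study, .data$B, .data$.use),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k >= min_k) |>
    dplyr::mutate(
      Z_meta = .data$B_meta / .data$SE_meta,
      P_meta = 2 * exp(pnorm(-abs(.data$Z_meta), log.p = TRUE)),
      Q = dplyr::if_else(.data$k > 1L, .data$Q, NA_real_),
      P_het = dplyr::if_else(.data$k > 1L,
                             pchisq(.data$Q, df = .data$k - 1L, lower.tail = FALSE),
                             NA_real_),
      I2 = dplyr::if_else(.data$k > 1L & .data$Q > 0,
                          pmax(0, (.data$Q - (.data$k - 1L)) / .data$Q) * 100,
                          dplyr::if_else(.data$k > 1L, 0, NA_real_))
    ) |>
    dplyr::select("RSID", "CHR", "POS_37", "POS_38", "EffectAllele", "OtherAllele",
                  "k", "B_meta", "SE_meta", "Z_meta", "P_meta",
                  "Q", "P_het", "I2", "N_total", "direction")
  res
}

#' Fixed-effects meta-analysis across cleaned datasets
#'
#' Pools per-variant effects across two or more cleaned datasets with
#' inverse-variance weights \eqn{w_i = 1/SE_i^2}:
#' \eqn{B = \sum w_i B_i / \sum w_i}, \eqn{SE = 1/\sqrt{\sum w_i}},
#' plus Cochran's Q, its chi-squared heterogeneity P (df = k - 1) and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100}. Variants are grouped by
#' rsID and canonical allele set, effects are allele-aligned to the first
#' contributing study ([align_effects()]), and processing is per chromosome
#' partition, so memory stays bounded by one chromosome.
#'
#' @param datasets List of `cleaned_dataset` handles or paths (>= 2),
#'   hive-style format.
#' @param min_k Minimum number of contributing studies for a variant to be
#'   reported (default 2).
#' @return A `meta_result` tibble (one row per variant) with the pooled
#'   effect, heterogeneity statistics and a METAL-style direction string in
#'   dataset input order.
#' @export
meta_analyse <- function(datasets, min_k = 2L) {
  if (inherits(datasets, "cleaned_dataset")) datasets <- list(datasets)
  if (length(datasets) < 2L) abort("meta-analysis requires at least 2 datasets")
  datasets <- lapply(datasets, function(d) if (is.character(d)) open_cleaned(d) else d)
  for (ds in datasets) {
    if (!identical(ds$format, "hivestyle")) {
      abort(paste0("dataset '", ds$id, "' is not in hivestyle format; ",
                   "meta-analysis requires partitioned output"))
    }
  }
  ids <- vapply(datasets, `[[`, character(1), "id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  chroms <- sort(unique(unlist(lapply(datasets, function(d) d$metadata$chromosomes))))

  res <- purrr::map(chroms, function(chr) {
    long <- purrr::map2(datasets, ids, function(ds, id) {
      part <- read_cleaned(ds, chr = chr)
      part$study <- id
      part
    })
    long <- dplyr::bind_rows(long)
    long$study <- factor(long$study, levels = ids)
    if (nrow(long) == 0L) return(NULL)
    pool_fixed_effects(long, min_k = min_k)
  })
  res <- dplyr::bind_rows(res)
  structure(res, class = c("meta_result", class(res)), studies = ids)
}

#' Write a meta-analysis result
#'
#' `"hivestyle"` writes a chromosome-partitioned Parquet dataset whose schema
#' is compatible with cleaned datasets (pooled `B`, `SE`, `Z`, `P`, total
#' `N`); `"metal"` writes a METAL-like TSV with columns `MarkerName`,
#' `Allele1`, `Allele2`, `Effect`, `StdErr`, `P-value`, `Direction`,
#' `HetISq`, `HetChiSq`, `HetDf`, `HetPVal`.
#'
#' @param result A `meta_result` from [meta_analyse()].
#' @param path Output directory (hivestyle) or file path (metal).
#' @param format `"hivestyle"` or `"metal"`.
#' @param overwrite Replace existing output.
#' @return `path`, invisibly.
#' @export
write_meta <- function(result, path, format = c("hivestyle", "metal"),
                       overwrite = FALSE) {
  format <- match.arg(format)
  if (format == "hivestyle") {
    tbl <- result |>
      tibble::as_tibble() |>
      dplyr::transmute(.data$RSID, .data$CHR, .data$POS_37, .data$POS_38,
                       .data$EffectAllele, .data$OtherAllele,
                       B = .data$B_meta, SE = .data$SE_meta, Z = .data$Z_meta,
                       P = .data$P_meta, N = .data$N_total)
    write_output(tbl, path, output_format = "hivestyle",
                 metadata = list(kind = "meta_analysis",
                                 studies = attr(result, "studies")),
                 overwrite = overwrite)
  } else {
    if (file.exists(path) && !overwrite) {
      abort(paste0("output file exists: ", path, " (use overwrite = TRUE)"))
    }
    out <- result |>
      tibble::as_tibble() |>
      dplyr::transmute(
        MarkerName = .data$RSID,
        Allele1 = .data$EffectAllele, Allele2 = .data$OtherAllele,
        Effect = .data$B_meta, StdErr = .data$SE_meta,
        `P-value` = .data$P_meta, Direction = .data$direction,
        HetISq = .data$I2, HetChiSq = .data$Q, HetDf = .data$k - 1L,
        HetPVal = .data$P_het)
    readr::write_tsv(out, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    n_studies = length(attr(x, "studies")),
    mean_k = mean(x$k),
    n_significant = sum(x$P_meta <= 5e-8, na.rm = TRUE),
    median_I2 = stats::median(x$I2, na.rm = TRUE)
  )
}

#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$B_meta,
                                   y = -log10(pmax(.data$P_meta, 1e-300)),
                                   colour = .data$I2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(5e-8), linetype = "dashed") +
    ggplot2::labs(x = "pooled effect (B)", y = expression(-log[10](P)),
                  colour = expression(I^2)) +
    ggplot2::theme_minimal()
}
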