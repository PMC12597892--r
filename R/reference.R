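# Curated dual-build variant reference: curation filters, on-disk layout,
# lazy loading, indel normalization, merged-rsID resolution.
#
# On disk a panel is a directory:
#   _panel.json             metadata (chromosomes, counts, has_indels)
#   _merged_rsids.parquet   columns OLD_RSID, NEW_RSID (raw, unresolved)
#   variants/CHR=<label>/   hive-partitioned Parquet, columns
#                           RSID (int), POS_37, POS_38, REF, ALT
#   indels/CHR=<label>/     optional, same schema, left-aligned/trimmed
# ALT holds comma-joined alternate alleles for multiallelic sites.

#' Apply the reference curation filters
#'
#' Takes uncurated variant records carrying per-build chromosome and position
#' and applies, in order: (1) remove rsIDs that map to more than one genomic
#' position; (2) among records sharing a chromosome and position, keep only
#' the smallest rsID number; (3) remove records whose chromosome differs
#' between GRCh37 and GRCh38; (4) keep only records with positions on both
#' builds. Records sharing an rsID at one site are then collapsed to a single
#' row with comma-joined alternate alleles.
#'
#' @param raw A data frame with columns `RSID` (integer rs number), `CHR_37`,
#'   `POS_37`, `CHR_38`, `POS_38`, `REF`, `ALT`.
#' @return A list with `variants` (curated tibble: `RSID`, `CHR`, `POS_37`,
#'   `POS_38`, `REF`, `ALT`) and `removed` (tibble of per-filter removal
#'   counts, in filter order).
#' @export
curate_reference <- function(raw) {
  raw <- tibble::as_tibble(raw)
  need <- c("RSID", "CHR_37", "POS_37", "CHR_38", "POS_38", "REF", "ALT")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste0("uncurated reference lacks columns: ",
                                 paste(miss, collapse = ", ")))
  n0 <- nrow(raw)

  # (1) an rsID observed at more than one position (on either build) is
  # untrustworthy: remove every record of that rsID
  site <- paste(raw$CHR_37, raw$POS_37, raw$CHR_38, raw$POS_38, sep = ":")
  multi_pos <- dplyr::group_by(tibble::tibble(RSID = raw$RSID, site = site), .data$RSID)
  multi_pos <- dplyr::filter(multi_pos, dplyr::n_distinct(.data$site) > 1L)
  bad_rsid <- unique(multi_pos$RSID)
  keep <- !(raw$RSID %in% bad_rsid)
  n_multi_position <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]

  # (2) one rsID per site: at a shared chr:pos (per build) keep the smallest
  # rs number
  for (build in c("37", "38")) {
    chr <- raw[[paste0("CHR_", build)]]
    pos <- raw[[paste0("POS_", build)]]
    ok <- !is.na(chr) & !is.na(pos)
    min_at_site <- stats::ave(ifelse(ok, raw$RSID, NA_integer_),
                              paste(chr, pos),
                              FUN = function(x) suppressWarnings(min(x, na.rm = TRUE)))
    keep <- !ok | raw$RSID == min_at_site
    raw <- raw[keep, , drop = FALSE]
    if (build == "37") n_dup_site_37 <- sum(!keep) else n_dup_site_38 <- sum(!keep)
  }
  n_duplicate_site <- n_dup_site_37 + n_dup_site_38

  # (3) chromosome must agree between builds
  keep <- is.na(raw$CHR_37) | is.na(raw$CHR_38) | raw$CHR_37 == raw$CHR_38
  n_chr_mismatch <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]

  # (4) both-build positions required
  keep <- !is.na(raw$POS_37) & !is.na(raw$POS_38) &
    !is.na(raw$CHR_37) & !is.na(raw$CHR_38)
  n_single_build <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]

  variants <- raw |>
    dplyr::mutate(CHR = .data$CHR_37) |>
    dplyr::group_by(.data$RSID, .data$CHR, .data$POS_37, .data$POS_38, .data$REF) |>
    dplyr::summarise(
      ALT = paste(sort(unique(unlist(strsplit(.data$ALT, ",", fixed = TRUE)))),
                  collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$CHR, .data$POS_37, .data$RSID) |>
    dplyr::select("RSID", "CHR", "POS_37", "POS_38", "REF", "ALT")

  if (nrow(variants) == 0L) inform("curation produced an empty reference panel")

  removed <- tibble::tibble(
    filter = c("multi_position_rsid", "duplicate_site", "chr_mismatch", "single_build"),
    removed = c(n_multi_position, n_duplicate_site, n_chr_mismatch, n_single_build)
  )
  stopifnot(sum(removed$removed) + nrow(raw) == n0)
  list(variants = variants, removed = removed)
}

#' Write a reference panel to disk
#'
#' @param variants Curated variant tibble (`RSID`, `CHR`, `POS_37`, `POS_38`,
#'   `REF`, `ALT`).
#' @param path Output directory (created; must not already hold a panel unless
#'   `overwrite = TRUE`).
#' @param merged Optional merged-rsID map: tibble with `OLD_RSID`, `NEW_RSID`.
#' @param indels Optional indel tibble, same schema as `variants`, already
#'   left-aligned and trimmed (see [left_align_trim()]).
#' @param overwrite Replace an existing panel.
#' @return `path`, invisibly.
#' @export
write_reference <- function(variants, path, merged = NULL, indels = NULL,
                            overwrite = FALSE) {
  if (file.exists(file.path(path, "_panel.json")) && !overwrite) {
    abort(paste0("a reference panel already exists at ", path,
                 " (use overwrite = TRUE)"))
  }
  if (dir.exists(path) && overwrite) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  variants <- dplyr::arrange(tibble::as_tibble(variants),
                             .data$CHR, .data$POS_37, .data$RSID)
  arrow::write_dataset(variants, file.path(path, "variants"),
                       partitioning = "CHR", format = "parquet")
  chroms <- sort(unique(variants$CHR))
  indel_chroms <- character(0)
  if (!is.null(indels) && nrow(indels) > 0L) {
    indels <- dplyr::arrange(tibble::as_tibble(indels),
                             .data$CHR, .data$POS_37, .data$RSID)
    arrow::write_dataset(indels, file.path(path, "indels"),
                         partitioning = "CHR", format = "parquet")
    indel_chroms <- sort(unique(indels$CHR))
  }
  if (is.null(merged)) {
    merged <- tibble::tibble(OLD_RSID = integer(0), NEW_RSID = integer(0))
  }
  arrow::write_parquet(tibble::as_tibble(merged), file.path(path, "_merged_rsids.parquet"))

  meta <- list(
    format_version = 1L,
    n_variants = nrow(variants),
    chromosomes = as.list(chroms),
    has_indels = length(indel_chroms) > 0,
    indel_chromosomes = as.list(indel_chroms),
    n_merged_rsids = nrow(merged)
  )
  jsonlite::write_json(meta, file.path(path, "_panel.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a reference panel as a lazy handle
#'
#' Opens the chromosome-partitioned Parquet panel lazily (per-chromosome scans
#' only; the panel is never materialized whole) and resolves merged-rsID
#' chains transitively to their terminal identifier.
#'
#' @param path Panel directory written by [write_reference()] or
#'   [make_reference()].
#' @return A `reference_panel` handle.
#' @export
load_reference <- function(path) {
  meta_path <- file.path(path, "_panel.json")
  if (!file.exists(meta_path)) {
    abort(paste0("not a reference panel (no _panel.json): ", path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (chr in meta$chromosomes) {
    part <- file.path(path, "variants", paste0("CHR=", chr))
    if (!dir.exists(part) || !length(list.files(part, pattern = "\\.parquet$"))) {
      abort(paste0("reference panel partition missing or empty: ", part))
    }
  }
  if (isTRUE(meta$has_indels)) {
    for (chr in meta$indel_chromosomes) {
      part <- file.path(path, "indels", paste0("CHR=", chr))
      if (!dir.exists(part) || !length(list.files(part, pattern = "\\.parquet$"))) {
        abort(paste0("reference panel indel partition missing or empty: ", part))
      }
    }
  }
  merged <- tibble::as_tibble(arrow::read_parquet(file.path(path, "_merged_rsids.parquet")))
  merged <- resolve_merged_chains(merged)
  structure(list(path = path, meta = meta, merged = merged), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel> ", x$path, "\n",
      "  variants: ", x$meta$n_variants,
      " across chromosomes {", paste(unlist(x$meta$chromosomes), collapse = ", "), "}\n",
      "  indel partition: ", if (isTRUE(x$meta$has_indels)) "yes" else "no", "\n",
      "  merged rsIDs: ", nrow(x$merged), "\n", sep = "")
  invisible(x)
}

# Resolve old -> new rsID chains to their terminal id. dbSNP merges chain
# across releases; a single hop can land on another retired id.
resolve_merged_chains <- function(merged) {
  if (nrow(merged) == 0L) return(merged)
  if (any(merged$OLD_RSID == merged$NEW_RSID)) {
    abort("merged-rsID map contains self-mapping entries")
  }
  new <- merged$NEW_RSID
  for (i in seq_len(64L)) {
    idx <- match(new, merged$OLD_RSID)
    hit <- !is.na(idx)
    if (!any(hit)) break
    new[hit] <- merged$NEW_RSID[idx[hit]]
    if (i == 64L) abort("merged-rsID map contains a cycle")
  }
  tibble::tibble(OLD_RSID = merged$OLD_RSID, NEW_RSID = new)
}

# Materialize one chromosome (or all) of the panel, SNVs or indels.
ref_scan <- function(panel, chr = NULL, indels = FALSE) {
  stopifnot(inherits(panel, "reference_panel"))
  sub <- if (indels) "indels" else "variants"
  if (indels && !isTRUE(panel$meta$has_indels)) {
    return(tibble::tibble(RSID = integer(0), CHR = character(0),
                          POS_37 = integer(0), POS_38 = integer(0),
                          REF = character(0), ALT = character(0)))
  }
  ds <- open_hive_dataset(file.path(panel$path, sub))
  if (!is.null(chr)) ds <- dplyr::filter(ds, .data$CHR %in% !!as.character(chr))
  out <- dplyr::collect(ds)
  out$CHR <- as.character(out$CHR)
  dplyr::arrange(tibble::as_tibble(out), .data$CHR, .data$POS_37, .data$RSID)
}

#' Left-align and trim an indel allele pair
#'
#' Reduces a ref/alt allele pair to its minimal representation: the shared
#' suffix is removed first, then the shared prefix with the position advanced
#' accordingly, always keeping at least one base in each allele. This is the
#' standard variant-normalization step for indels.
#'
#' @param ref,alt Allele strings over `A`, `C`, `G`, `T` (vectorized).
#' @param pos 1-based positions.
#' @return A tibble with columns `ref`, `alt`, `pos`.
#' @examples
#' left_align_trim("CAG", "CAGAG", 100)   # -> C, CAG, 100
#' @export
left_align_trim <- function(ref, alt, pos) {
  stopifnot(length(ref) == length(alt), length(ref) == length(pos))
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    abort("alleles must be non-empty strings over {A,C,G,T}")
  }
  if (any(ref == alt)) abort("ref and alt are identical: not a variant")
  out <- purrr::pmap(list(ref, alt, pos), function(r, a, p) {
    rs <- strsplit(r, "")[[1]]
    as <- strsplit(a, "")[[1]]
    while (length(rs) > 1L && length(as) > 1L && rs[length(rs)] == as[length(as)]) {
      rs <- rs[-length(rs)]
      as <- as[-length(as)]
    }
    while (length(rs) > 1L && length(as) > 1L && rs[1] == as[1]) {
      rs <- rs[-1]
      as <- as[-1]
      p <- p + 1L
    }
    list(ref = paste(rs, collapse = ""), alt = paste(as, collapse = ""), pos = p)
  })
  tibble::tibble(
    ref = vapply(out, `[[`, character(1), "ref"),
    alt = vapply(out, `[[`, character(1), "alt"),
    pos = vapply(out, function(x) as.integer(x$pos), integer(1))
  )
}
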