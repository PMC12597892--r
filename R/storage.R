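# Persisting cleaned summary statistics as chromosome-partitioned Parquet
# (hive-style, CHR=<label>/) or TSV, with JSON sidecars, and lazy multi-
# dataset region queries.

OUTPUT_COLUMNS <- c(
  "RSID", "CHR", "POS_37", "POS_38", "EffectAllele", "OtherAllele",
  "EAF", "EAF_ref", "B", "SE", "Z", "P", "N", "CaseN", "ControlN", "INFO",
  "indel", "multi_allelic", "freq_diff", "strand_flipped", "eaf_imputed"
)

canonicalize_output <- function(tbl) {
  for (col in OUTPUT_COLUMNS) {
    if (!col %in% names(tbl)) {
      tbl[[col]] <- switch(col,
        RSID = , CHR = , EffectAllele = , OtherAllele = NA_character_,
        POS_37 = , POS_38 = NA_integer_,
        indel = , multi_allelic = , freq_diff = , strand_flipped = ,
        eaf_imputed = NA,
        NA_real_
      )
    }
  }
  for (col in c("indel", "multi_allelic", "freq_diff", "strand_flipped", "eaf_imputed")) {
    tbl[[col]] <- as.logical(tbl[[col]])
  }
  tbl <- tbl[, OUTPUT_COLUMNS, drop = FALSE]
  # drop provenance attributes so they are not serialized as file metadata
  for (a in setdiff(names(attributes(tbl)), c("names", "row.names", "class"))) {
    attr(tbl, a) <- NULL
  }
  dplyr::arrange(tbl, .data$CHR, .data$POS_38, .data$RSID,
                 .data$EffectAllele, .data$OtherAllele)
}

#' Write a cleaned summary-statistics dataset
#'
#' `"hivestyle"` writes one Parquet partition per chromosome
#' (`CHR=<label>/part-0.parquet`) under `path`, plus underscore-prefixed JSON
#' sidecars (`_cleaning_report.json`, `_metadata.json`) that arrow's dataset
#' discovery ignores. `"tsv"` writes a single gzip-compressed tab-separated
#' file with the same sidecars. Missing values are native Parquet nulls
#' (`NA` in the TSV).
#'
#' @param tbl Repaired tibble.
#' @param path Output directory.
#' @param output_format `"hivestyle"` or `"tsv"`.
#' @param report Optional `cleaning_report` to store as a sidecar.
#' @param metadata Optional named list stored in `_metadata.json`.
#' @param overwrite Replace an existing dataset.
#' @return A `cleaned_dataset` handle (see [open_cleaned()]).
#' @export
write_output <- function(tbl, path, output_format = c("hivestyle", "tsv"),
                         report = NULL, metadata = NULL, overwrite = FALSE) {
  output_format <- match.arg(output_format)
  if (dir.exists(path) && length(list.files(path, all.files = TRUE, no.. = TRUE))) {
    if (!overwrite) abort(paste0("output path exists and is non-empty: ", path,
                                 " (use overwrite = TRUE)"))
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  tbl <- canonicalize_output(tibble::as_tibble(tbl))
  if (output_format == "hivestyle") {
    arrow::write_dataset(tbl, path, partitioning = "CHR", format = "parquet")
  } else {
    readr::write_tsv(tbl, file.path(path, "sumstats.tsv.gz"), na = "NA",
                     progress = FALSE)
  }
  if (!is.null(report)) {
    jsonlite::write_json(
      list(n_input = attr(report, "n_input"), n_output = attr(report, "n_output"),
           steps = tibble::as_tibble(report)),
      file.path(path, "_cleaning_report.json"), auto_unbox = TRUE, digits = NA)
  }
  meta <- c(list(format = output_format, n_rows = nrow(tbl),
                 chromosomes = sort(unique(tbl$CHR)),
                 tool = "gwash", tool_version = as.character(utils::packageVersion("gwash"))),
            metadata %||% list())
  jsonlite::write_json(meta, file.path(path, "_metadata.json"), auto_unbox = TRUE,
                       digits = NA)
  open_cleaned(path)
}

#' Open a cleaned dataset lazily
#'
#' @param path Directory written by [write_output()].
#' @param id Dataset identifier used in multi-dataset queries; defaults to the
#'   directory name.
#' @return A `cleaned_dataset` handle with fields `path`, `id`, `format`,
#'   `metadata`.
#' @export
open_cleaned <- function(path, id = basename(normalizePath(path))) {
  meta_path <- file.path(path, "_metadata.json")
  if (!file.exists(meta_path)) {
    abort(paste0("not a cleaned dataset (no _metadata.json): ", path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(list(path = path, id = id, format = meta$format, metadata = meta),
            class = "cleaned_dataset")
}

#' @export
print.cleaned_dataset <- function(x, ...) {
  cat("<cleaned_dataset> ", x$id, " (", x$format, ", ", x$metadata$n_rows,
      " rows) at ", x$path, "\n", sep = "")
  invisible(x)
}

# Lazy arrow handle (hivestyle) or materialized tibble (tsv).
dataset_query <- function(ds) {
  stopifnot(inherits(ds, "cleaned_dataset"))
  if (ds$format == "hivestyle") {
    open_hive_dataset(ds$path)
  } else {
    readr::read_tsv(file.path(ds$path, "sumstats.tsv.gz"),
                    col_types = cleaned_col_types(), na = "NA", progress = FALSE)
  }
}

cleaned_col_types <- function() {
  readr::cols(
    RSID = "c", CHR = "c", POS_37 = "i", POS_38 = "i",
    EffectAllele = "c", OtherAllele = "c",
    EAF = "d", EAF_ref = "d", B = "d", SE = "d", Z = "d", P = "d",
    N = "d", CaseN = "d", ControlN = "d", INFO = "d",
    indel = "l", multi_allelic = "l", freq_diff = "l",
    strand_flipped = "l", eaf_imputed = "l"
  )
}

#' Materialize a cleaned dataset as a tibble
#'
#' @param ds A `cleaned_dataset` (or path).
#' @param chr Optional chromosome subset (only those partitions are scanned).
#' @return A tibble in canonical column order.
#' @export
read_cleaned <- function(ds, chr = NULL) {
  if (is.character(ds)) ds <- open_cleaned(ds)
  q <- dataset_query(ds)
  if (!is.null(chr)) q <- dplyr::filter(q, .data$CHR %in% !!as.character(chr))
  out <- tibble::as_tibble(dplyr::collect(q))
  out$CHR <- as.character(out$CHR)
  dplyr::arrange(out[, OUTPUT_COLUMNS, drop = FALSE],
                 .data$CHR, .data$POS_38, .data$RSID,
                 .data$EffectAllele, .data$OtherAllele)
}

#' Query a genomic region across one or more cleaned datasets
#'
#' Returns all variants with `CHR == chr` and `start <= POS_<build> <= end`
#' (1-based, closed interval), optionally restricted to `P <= p_max`, across
#' every supplied dataset, with a `dataset` identifier column prepended.
#' Only the relevant chromosome partitions are scanned.
#'
#' @param datasets A `cleaned_dataset`, a path, or a list of either.
#' @param chr Chromosome label.
#' @param start,end 1-based closed interval bounds.
#' @param build Genome build of the interval: `37` or `38`.
#' @param p_max Optional significance threshold (`P <= p_max`).
#' @return A tibble with `dataset` plus the canonical output columns.
#' @export
query_region <- function(datasets, chr, start, end, build = 38, p_max = NULL) {
  if (!build %in% c(37, 38, "37", "38", "GRCh37", "GRCh38")) {
    abort(paste0("unknown build: ", build, " (use 37 or 38)"))
  }
  if (start > end) abort("region start exceeds end")
  pos_col <- if (build %in% c(37, "37", "GRCh37")) "POS_37" else "POS_38"
  if (inherits(datasets, "cleaned_dataset") || is.character(datasets)) {
    datasets <- list(datasets)
  }
  datasets <- lapply(datasets, function(d) if (is.character(d)) open_cleaned(d) else d)

  out <- purrr::map(datasets, function(ds) {
    q <- dataset_query(ds) |>
      dplyr::filter(.data$CHR == !!as.character(chr),
                    .data[[pos_col]] >= !!as.integer(start),
                    .data[[pos_col]] <= !!as.integer(end))
    if (!is.null(p_max)) q <- dplyr::filter(q, !is.na(.data$P), .data$P <= !!p_max)
    res <- tibble::as_tibble(dplyr::collect(q))
    if (nrow(res)) res$CHR <- as.character(res$CHR)
    dplyr::bind_cols(tibble::tibble(dataset = rep(ds$id, nrow(res))),
                     res[, OUTPUT_COLUMNS[OUTPUT_COLUMNS %in% names(res)], drop = FALSE])
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- dplyr::bind_cols(
      tibble::tibble(dataset = character(0)),
      canonicalize_output(tibble::tibble(RSID = character(0)))
    )
  }
  dplyr::arrange(out, .data[[pos_col]], .data$dataset)
}

# Open a CHR=<label>/ partitioned Parquet directory with the partition column
# pinned to utf8, so chromosome labels never degrade to integers.
open_hive_dataset <- function(path) {
  arrow::open_dataset(path, format = "parquet",
                      partitioning = arrow::hive_partition(CHR = arrow::utf8()))
}
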