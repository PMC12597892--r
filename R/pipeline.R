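# The end-to-end harmonization pipeline: parse -> map -> clean -> identity
# repair -> statistics repair -> (optional) frequency comparison -> write.

#' Harmonize a GWAS summary-statistics table against a variant reference
#'
#' Runs the full pipeline: parse the raw source, guess the column-name
#' mapping, remove rows missing critical values, deduplicate, detect indels,
#' validate and coerce every column, split compound `chr:pos` identifiers,
#' infer the genome build, repair variant identity against the reference
#' panel (restoring rsIDs and both-build positions, dropping variants with no
#' reference entry or incompatible alleles), flag multiallelics, impute
#' missing statistics columns, optionally compare allele frequencies with a
#' reference population, and (if `output` is given) write the cleaned
#' dataset.
#'
#' @param tbl A file path or data frame of raw summary statistics.
#' @param dbsnp_path Path to the reference panel directory (see
#'   [make_reference()] / [write_reference()]).
#' @param output Optional output directory; when given, the cleaned dataset
#'   is written there in `output_format`.
#' @param output_format `"hivestyle"` (chromosome-partitioned Parquet,
#'   default) or `"tsv"`.
#' @param column_names Optional explicit mapping `c(raw = "Canonical", ...)`
#'   overriding name guessing.
#' @param indel_strategy `"qc"` (match indels to the reference indel
#'   partition, default), `"keep"` or `"drop"`.
#' @param freq_ref Optional frequency reference (see
#'   [append_reference_freq()]).
#' @param population Population label in `freq_ref` to compare against.
#' @param overwrite Replace an existing output directory.
#' @return A `gwash_result`: list with `tbl` (harmonized tibble), `report`
#'   (a `cleaning_report`), `build` (a `build_call` or `NULL`), `mapping`
#'   (the `column_mapping` used) and `dataset` (a `cleaned_dataset` handle
#'   when `output` was given).
#' @examples
#' \donttest{
#' spec <- fixture_spec(seed = 7, n_variants = 300)
#' panel <- make_reference(spec, file.path(tempdir(), "panel"), overwrite = TRUE)
#' sim <- make_sumstats(spec, panel, build = 38)
#' res <- harmonise_sumstats(sim$raw, panel)
#' glance(res)
#' }
#' @export
harmonise_sumstats <- function(tbl, dbsnp_path,
                               output = NULL,
                               output_format = c("hivestyle", "tsv"),
                               column_names = NULL,
                               indel_strategy = c("qc", "keep", "drop"),
                               freq_ref = NULL, population = NULL,
                               overwrite = FALSE) {
  output_format <- match.arg(output_format)
  indel_strategy <- match.arg(indel_strategy)
  panel <- if (inherits(dbsnp_path, "reference_panel")) dbsnp_path
           else load_reference(dbsnp_path)

  raw <- parse_input(tbl)
  mapping <- guess_names(names(raw), mapping = column_names)
  x <- select_correct_columns(raw, mapping)
  n_input <- nrow(x)
  entries <- list()

  s <- remove_rows_with_na(x)
  x <- s$tbl; entries <- c(entries, list(s$entry))
  s <- remove_duplicates(x)
  x <- s$tbl; entries <- c(entries, list(s$entry))
  s <- detect_indels(x, indel_strategy)
  x <- s$tbl; entries <- c(entries, list(s$entry))
  s <- validate_columns(x)
  x <- s$tbl; entries <- c(entries, list(s$entry))

  x <- split_compound_ids(x)
  build <- NULL
  if (all(c("CHR", "POS") %in% names(x)) && any(!is.na(x$CHR) & !is.na(x$POS))) {
    build <- infer_build(x, panel)
  }
  s <- repair_ids(x, panel, build = build, indel_strategy = indel_strategy)
  x <- s$tbl; entries <- c(entries, s$entries)
  x <- flag_multiallelic(x)
  x <- repair_stats(x)

  if (!is.null(freq_ref)) {
    if (is.null(population)) abort("`population` must be given with `freq_ref`")
    x <- append_reference_freq(x, freq_ref, population)
    x <- add_freq_diff_flag(x)
  }

  report <- cleaning_report(entries, n_input = n_input, n_output = nrow(x))
  dataset <- NULL
  if (!is.null(output)) {
    meta <- list(source = as.character(attr(raw, "source") %||% "in-memory"),
                 build = if (!is.null(build)) build$build else "from-rsID",
                 build_matches_37 = if (!is.null(build)) build$matches_37,
                 build_matches_38 = if (!is.null(build)) build$matches_38,
                 indel_strategy = indel_strategy)
    dataset <- write_output(x, output, output_format = output_format,
                            report = report, metadata = meta,
                            overwrite = overwrite)
  }
  structure(list(tbl = tibble::as_tibble(x), report = report, build = build,
                 mapping = mapping, dataset = dataset),
            class = "gwash_result")
}

#' @export
print.gwash_result <- function(x, ...) {
  cat("<gwash_result>\n")
  if (!is.null(x$build)) print(x$build)
  print(x$report)
  invisible(x)
}

#' @describeIn harmonise_sumstats Harmonized variants as a tibble.
#' @param x,object A `gwash_result`.
#' @param ... Unused.
#' @method tidy gwash_result
#' @export
tidy.gwash_result <- function(x, ...) {
  x$tbl
}

#' @describeIn harmonise_sumstats One-row run summary: rows in/out, per-step
#'   removals, inferred build and match counts.
#' @method glance gwash_result
#' @export
glance.gwash_result <- function(x, ...) {
  rem <- setNames(as.list(x$report$removed), paste0("removed_", x$report$step))
  tibble::as_tibble(c(
    list(n_input = attr(x$report, "n_input"),
         n_output = attr(x$report, "n_output")),
    rem,
    list(build = if (!is.null(x$build)) x$build$build else NA_character_,
         build_matches_37 = if (!is.null(x$build)) x$build$matches_37 else NA_integer_,
         build_matches_38 = if (!is.null(x$build)) x$build$matches_38 else NA_integer_)
  ))
}

#' @describeIn harmonise_sumstats Bar chart of rows removed per cleaning step.
#' @method autoplot gwash_result
#' @export
autoplot.gwash_result <- function(object, ...) {
  autoplot(object$report)
}

#' @method autoplot cleaning_report
#' @export
autoplot.cleaning_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$step <- factor(df$step, levels = rev(REPORT_STEPS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$removed, y = .data$step)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "rows removed", y = NULL,
                  title = "Rows removed per cleaning step") +
    ggplot2::theme_minimal()
}

#' @method tidy cleaning_report
#' @export
tidy.cleaning_report <- function(x, ...) {
  tibble::as_tibble(x)
}
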