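# Ingestion: delimited-text parsing and column-name mapping.

# Alias dictionary. Matching is case-insensitive; the canonical spelling of a
# canonical name is always an alias of itself. MAF is handled specially in
# guess_names(): it maps to EAF only when no EAF-proper alias is present.
COLUMN_ALIASES <- list(
  RSID         = c("RSID", "SNP", "rs_id", "MarkerName", "variant_id", "ID", "snpid", "rsids"),
  CHR          = c("CHR", "chromosome", "CHROM", "#CHROM", "chrom"),
  POS          = c("POS", "bp", "position", "base_pair_location", "BP", "pos_b37", "bpos"),
  EffectAllele = c("EffectAllele", "A1", "effect_allele", "EA", "ALT", "allele1"),
  OtherAllele  = c("OtherAllele", "A2", "other_allele", "OA", "REF", "NEA", "allele2", "allele0"),
  B            = c("B", "beta", "effect", "Effect"),
  SE           = c("SE", "standard_error", "StdErr", "se_beta"),
  Z            = c("Z", "zscore", "z_score", "Zscore"),
  P            = c("P", "pval", "p_value", "P.value", "PVAL", "p_val"),
  EAF          = c("EAF", "af", "effect_allele_frequency", "FRQ", "freq", "A1FREQ"),
  N            = c("N", "sample_size", "NMISS", "n_total"),
  CaseN        = c("CaseN", "n_cases", "Ncas", "N_CASE"),
  ControlN     = c("ControlN", "n_controls", "Ncon", "N_CONTROL"),
  INFO         = c("INFO", "imputation_quality", "R2", "info_score")
)

MAF_ALIASES <- c("MAF", "minor_allele_frequency", "minor_AF")

#' Parse a raw summary-statistics source
#'
#' Reads a delimited text file (tab, comma, semicolon or whitespace separated,
#' optionally gzip-compressed) or accepts an in-memory data frame. All cells
#' are kept as character: numeric coercion happens later, in
#' [validate_columns()], so that malformed values can be counted rather than
#' silently dropped by the reader.
#'
#' @param source A file path or a data frame.
#' @return A tibble of character columns with attribute `"source"`
#'   describing provenance.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tA1\tA2\tP", "rs1\tA\tG\t0.5"), tf)
#' parse_input(tf)
#' @export
parse_input <- function(source) {
  if (is.data.frame(source)) {
    tbl <- dplyr::mutate(tibble::as_tibble(source),
                         dplyr::across(dplyr::everything(), as.character))
    if (nrow(tbl) == 0L) abort("in-memory table has zero data rows")
    attr(tbl, "source") <- "in-memory"
    return(tbl)
  }
  if (!is.character(source) || length(source) != 1L) {
    abort("`source` must be a file path or a data frame")
  }
  if (!file.exists(source)) {
    abort(paste0("cannot read summary statistics file: ", source))
  }
  delim <- detect_delimiter(source)
  tbl <- if (identical(delim, "whitespace")) {
    readr::read_table(source, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
  } else {
    readr::read_delim(source, delim = delim,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE, trim_ws = TRUE)
  }
  if (nrow(tbl) == 0L) abort(paste0("file has a header but zero data rows: ", source))
  names(tbl) <- trimws(names(tbl))
  if (anyDuplicated(names(tbl))) {
    abort(paste0("duplicate column headers after whitespace normalization: ",
                 paste(names(tbl)[duplicated(names(tbl))], collapse = ", ")))
  }
  attr(tbl, "source") <- source
  tbl
}

# Pick the delimiter that yields a constant field count > 1 over the first
# lines of the file. gzfile() reads plain files transparently.
detect_delimiter <- function(path, n_probe = 50L) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, n = n_probe)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(paste0("file has fewer than 2 non-empty lines: ", path))
  candidates <- c("\t", ",", ";")
  widths <- function(split) {
    vapply(strsplit(lines, split, fixed = FALSE), length, integer(1))
  }
  for (d in candidates) {
    w <- vapply(strsplit(lines, d, fixed = TRUE), length, integer(1))
    if (w[1] > 1L && all(w == w[1])) return(d)
  }
  w <- widths("[ \t]+")
  if (w[1] > 1L && all(w == w[1])) return("whitespace")
  abort(paste0("could not detect a delimiter with constant field count > 1: ", path))
}

#' Guess the mapping from raw headers to canonical column names
#'
#' Performs a case-insensitive lookup of each header against a built-in alias
#' dictionary covering common summary-statistics dialects. Headers that match
#' no alias are reported as dropped. A `MAF`-style header is used for `EAF`
#' only when no proper `EAF` alias is present, and that fallback is flagged
#' in the mapping (MAF is not the effect-allele frequency in general).
#'
#' @param headers Character vector of raw column names.
#' @param mapping Optional named character vector `c(raw = "Canonical", ...)`
#'   supplied by the user; if given, it overrides guessing entirely.
#' @return A `column_mapping` object: list with `pairs` (named character
#'   vector raw -> canonical), `dropped` (character) and `maf_as_eaf` (logical).
#' @examples
#' guess_names(c("SNP", "A1", "A2", "BETA", "SE", "P"))
#' @export
guess_names <- function(headers, mapping = NULL) {
  if (length(headers) == 0L) abort("empty header list")
  headers <- trimws(headers)

  if (!is.null(mapping)) {
    bad <- setdiff(unname(mapping), CANONICAL_COLUMNS)
    if (length(bad)) abort(paste0("unknown canonical names in explicit mapping: ",
                                  paste(bad, collapse = ", ")))
    missing_raw <- setdiff(names(mapping), headers)
    if (length(missing_raw)) abort(paste0("explicit mapping names absent from headers: ",
                                          paste(missing_raw, collapse = ", ")))
    pairs <- mapping[names(mapping) %in% headers]
    check_mapping_collisions(pairs)
    return(new_column_mapping(pairs, dropped = setdiff(headers, names(pairs)),
                              maf_as_eaf = FALSE))
  }

  lookup <- unlist(lapply(names(COLUMN_ALIASES), function(canon) {
    setNames(rep(canon, length(COLUMN_ALIASES[[canon]])),
             tolower(COLUMN_ALIASES[[canon]]))
  }))
  canon_of <- unname(lookup[tolower(headers)])
  names(canon_of) <- headers

  maf_as_eaf <- FALSE
  maf_hits <- tolower(headers) %in% tolower(MAF_ALIASES)
  if (any(maf_hits) && !("EAF" %in% canon_of)) {
    first_maf <- which(maf_hits)[1]
    canon_of[first_maf] <- "EAF"
    maf_as_eaf <- TRUE
    inform(paste0("header '", headers[first_maf],
                  "' used as EAF (no EAF column present); note MAF != EAF in general"))
  }

  mapped <- !is.na(canon_of)
  pairs <- setNames(unname(canon_of[mapped]), headers[mapped])
  check_mapping_collisions(pairs)
  new_column_mapping(pairs, dropped = headers[!mapped], maf_as_eaf = maf_as_eaf)
}

check_mapping_collisions <- function(pairs) {
  dup <- unique(pairs[duplicated(pairs)])
  if (length(dup)) {
    offenders <- vapply(dup, function(d) {
      paste0(d, " <- {", paste(names(pairs)[pairs == d], collapse = ", "), "}")
    }, character(1))
    abort(paste0("multiple headers map to the same canonical column: ",
                 paste(offenders, collapse = "; ")))
  }
  invisible(pairs)
}

new_column_mapping <- function(pairs, dropped, maf_as_eaf) {
  structure(list(pairs = pairs, dropped = dropped, maf_as_eaf = maf_as_eaf),
            class = "column_mapping")
}

#' @export
print.column_mapping <- function(x, ...) {
  cat("<column_mapping>\n")
  if (length(x$pairs)) {
    cat(paste0("  ", names(x$pairs), " -> ", x$pairs, collapse = "\n"), "\n")
  }
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Keep and rename the mapped columns of a raw table
#'
#' Retains only the columns named by the mapping, renames them to the
#' canonical vocabulary, normalizes missing-value tokens (`""`, `"NA"`,
#' `"NaN"`, `"."`, ...) to `NA`, and drops any column whose values are then
#' entirely missing. Dropping is recorded on the result, never fatal.
#'
#' @param tbl A raw tibble from [parse_input()].
#' @param mapping A `column_mapping` from [guess_names()], or `NULL` to guess
#'   from `names(tbl)`.
#' @return A tibble with canonical column names, ordered canonically, with
#'   attributes `"dropped_unmapped"` and `"dropped_all_missing"`.
#' @export
select_correct_columns <- function(tbl, mapping = NULL) {
  if (is.null(mapping)) mapping <- guess_names(names(tbl))
  stopifnot(inherits(mapping, "column_mapping"))
  missing_hdr <- setdiff(names(mapping$pairs), names(tbl))
  if (length(missing_hdr)) {
    abort(paste0("mapping refers to headers absent from the table: ",
                 paste(missing_hdr, collapse = ", ")))
  }
  out <- tbl[, names(mapping$pairs), drop = FALSE]
  names(out) <- unname(mapping$pairs)
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(),
    ~ dplyr::if_else(is.na(.x) | trimws(.x) %in% MISSING_TOKENS, NA_character_, trimws(.x))
  ))
  all_missing <- names(out)[vapply(out, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    inform(paste0("dropping all-missing column(s): ", paste(all_missing, collapse = ", ")))
    out <- out[, setdiff(names(out), all_missing), drop = FALSE]
  }
  out <- out[, intersect(CANONICAL_COLUMNS, names(out)), drop = FALSE]
  attr(out, "dropped_unmapped") <- mapping$dropped
  attr(out, "dropped_all_missing") <- all_missing
  attr(out, "source") <- attr(tbl, "source")
  out
}
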