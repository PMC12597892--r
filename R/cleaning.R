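# Row-level validation and harmonization before reference matching.
# Each step returns its input minus failing rows plus a cleaning-report entry;
# removed + kept always equals the input row count.

REPORT_STEPS <- c("missing_critical", "duplicates", "validation",
                  "no_dbsnp_match", "allele_incompatible", "indel_dropped")

new_report_entry <- function(step, removed) {
  stopifnot(step %in% REPORT_STEPS)
  tibble::tibble(step = step, removed = as.integer(removed))
}

#' Assemble a cleaning report
#'
#' @param entries A list of per-step entries (tibbles with `step`, `removed`).
#' @param n_input,n_output Row counts before and after cleaning.
#' @return A `cleaning_report` tibble with one row per step in pipeline order.
#' @export
cleaning_report <- function(entries, n_input, n_output) {
  tbl <- dplyr::bind_rows(c(list(tibble::tibble(step = character(0),
                                                removed = integer(0))),
                            entries))
  tbl <- dplyr::left_join(tibble::tibble(step = REPORT_STEPS), tbl, by = "step")
  tbl$removed <- dplyr::coalesce(tbl$removed, 0L)
  out <- structure(tbl, class = c("cleaning_report", class(tbl)))
  attr(out, "n_input") <- as.integer(n_input)
  attr(out, "n_output") <- as.integer(n_output)
  stopifnot(sum(out$removed) + n_output == n_input)
  out
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report> ", attr(x, "n_input"), " rows in, ",
      attr(x, "n_output"), " rows out\n", sep = "")
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Remove rows with missing values in critical columns
#'
#' Effect and other allele are always required. Variant identity additionally
#' requires either an rsID or a complete chromosome + position pair. When all
#' of `CHR`, `POS` and `RSID` are present, the `RSID` column is dropped
#' entirely — it is restored from the reference during identity repair, which
#' is more reliable than trusting study-supplied identifiers.
#'
#' @param tbl Canonical-column tibble (character or typed).
#' @return A list with `tbl` and `entry` (report entry `missing_critical`).
#' @export
remove_rows_with_na <- function(tbl) {
  has <- function(col) col %in% names(tbl)
  if (!has("EffectAllele") || !has("OtherAllele")) {
    abort("EffectAllele and OtherAllele columns are required")
  }
  if (!has("RSID") && !(has("CHR") && has("POS"))) {
    abort("variant identity requires either an RSID column or both CHR and POS")
  }
  n0 <- nrow(tbl)
  if (has("RSID") && has("CHR") && has("POS")) {
    inform("CHR, POS and RSID all present: dropping RSID (restored from reference)")
    tbl <- dplyr::select(tbl, -"RSID")
  }
  keep <- !is.na(tbl$EffectAllele) & !is.na(tbl$OtherAllele)
  id_ok <- rep(FALSE, nrow(tbl))
  if (has("RSID")) id_ok <- id_ok | !is.na(tbl$RSID)
  if (has("CHR") && has("POS")) id_ok <- id_ok | (!is.na(tbl$CHR) & !is.na(tbl$POS))
  keep <- keep & id_ok
  list(tbl = tbl[keep, , drop = FALSE],
       entry = new_report_entry("missing_critical", n0 - sum(keep)))
}

#' Remove rows with duplicated variant identity
#'
#' The identity key is `CHR:POS:{alleles}` when both `CHR` and `POS` columns
#' are present, otherwise `RSID:{alleles}`; the allele pair is treated as an
#' unordered set, so `(A,G)` and `(G,A)` at one site are duplicates. The first
#' occurrence in input order survives.
#'
#' @param tbl Post-[remove_rows_with_na()] tibble.
#' @return A list with `tbl` and `entry` (report entry `duplicates`).
#' @export
remove_duplicates <- function(tbl) {
  n0 <- nrow(tbl)
  a1 <- pmin(tbl$EffectAllele, tbl$OtherAllele)
  a2 <- pmax(tbl$EffectAllele, tbl$OtherAllele)
  key <- if (all(c("CHR", "POS") %in% names(tbl))) {
    paste(tbl$CHR, tbl$POS, a1, a2, sep = ":")
  } else {
    paste(tbl$RSID, a1, a2, sep = ":")
  }
  keep <- !duplicated(key)
  list(tbl = tbl[keep, , drop = FALSE],
       entry = new_report_entry("duplicates", n0 - sum(keep)))
}

#' Detect insertion/deletion variants
#'
#' A row is flagged `indel = TRUE` when either allele is longer than one
#' character or uses a legacy deletion/insertion code (`D`, `I`, `R`).
#' With `indel_strategy = "qc"` flagged rows are later matched against the
#' panel's dedicated left-aligned indel partition; `"keep"` passes them
#' through identity repair unmatched; `"drop"` removes them (logged in the
#' report as `indel_dropped`).
#'
#' @param tbl Tibble with allele columns.
#' @param indel_strategy One of `"qc"`, `"keep"`, `"drop"`.
#' @return A list with `tbl` (flag column `indel` added) and `entry`
#'   (report entry `indel_dropped`; zero unless dropping).
#' @export
detect_indels <- function(tbl, indel_strategy = c("qc", "keep", "drop")) {
  indel_strategy <- match.arg(indel_strategy)
  ea <- toupper(tbl$EffectAllele)
  oa <- toupper(tbl$OtherAllele)
  indel <- nchar(ea) > 1L | nchar(oa) > 1L | ea %in% c("D", "I", "R") |
    oa %in% c("D", "I", "R")
  tbl$indel <- indel
  removed <- 0L
  if (indel_strategy == "drop") {
    removed <- sum(indel)
    tbl <- tbl[!indel, , drop = FALSE]
  }
  list(tbl = tbl, entry = new_report_entry("indel_dropped", removed))
}

# Per-column validation rules. Values failing their domain remove the row;
# genuinely missing values (NA) never do. P = 0 is rescued, not removed:
# it is an encoding artifact of underflowed genome-wide hits.
validate_numeric <- function(x, ok_fun) {
  v <- suppressWarnings(as.numeric(x))
  parse_fail <- !is.na(x) & is.na(v)
  bad <- parse_fail | (!is.na(v) & !ok_fun(v))
  list(value = v, bad = bad, parse_fail = parse_fail)
}

normalize_chr <- function(chr) {
  chr <- toupper(trimws(chr))
  chr <- sub("^CHR", "", chr)
  chr <- sub("^CH", "", chr)
  chr[chr == "23"] <- "X"
  chr[chr == "24"] <- "Y"
  chr[chr %in% c("25", "M")] <- "MT"
  chr
}

#' Validate and coerce the canonical columns
#'
#' Coerces every column to its proper type and applies domain checks:
#' chromosome labels are harmonized (`chr1`, `ch1`, `CHR1`, `1` all become
#' `1`; PLINK codes 23/24/25 become X/Y/MT) and must fall in 1–22, X, Y, MT;
#' positions are positive integers; alleles are uppercased and must use
#' `A`,`C`,`G`,`T` (or indel codes `D`,`I`,`R`); `P` must lie in (0, 1] with
#' `P = 0` replaced by the smallest positive normal double and flagged
#' `p_zero`; `EAF` in (0, 1) exclusive; `SE > 0`; `INFO` in [0, 1.1];
#' `N`, `CaseN`, `ControlN` positive; `B` and `Z` finite. Rows failing any
#' check are removed and counted. A column failing numeric coercion for more
#' than half its non-missing rows aborts — it is almost certainly mis-mapped.
#'
#' @param tbl Canonical-column tibble (cells may still be character).
#' @return A list with `tbl` (typed, harmonized) and `entry` (report entry
#'   `validation`).
#' @export
validate_columns <- function(tbl) {
  n0 <- nrow(tbl)
  bad <- rep(FALSE, n0)
  fatal_coercion <- function(col, parse_fail) {
    n_nonmiss <- sum(!is.na(tbl[[col]]))
    if (n_nonmiss > 0L && sum(parse_fail) > 0.5 * n_nonmiss) {
      abort(paste0("column ", col, " fails numeric coercion for >50% of rows; ",
                   "it is probably mis-mapped"))
    }
  }

  if ("CHR" %in% names(tbl)) {
    chr <- normalize_chr(tbl$CHR)
    bad <- bad | (!is.na(chr) & !(chr %in% VALID_CHR))
    tbl$CHR <- chr
  }
  if ("POS" %in% names(tbl)) {
    v <- validate_numeric(tbl$POS, function(x) x >= 1 & x <= 3e8 & x == floor(x))
    fatal_coercion("POS", v$parse_fail)
    bad <- bad | v$bad
    tbl$POS <- as.integer(v$value)
  }
  if ("RSID" %in% names(tbl)) tbl$RSID <- trimws(tbl$RSID)

  for (col in c("EffectAllele", "OtherAllele")) {
    al <- toupper(trimws(tbl[[col]]))
    bad <- bad | (!is.na(al) & !grepl("^([ACGT]+|[DIR])$", al))
    tbl[[col]] <- al
  }
  bad <- bad | (!is.na(tbl$EffectAllele) & !is.na(tbl$OtherAllele) &
                  tbl$EffectAllele == tbl$OtherAllele)

  p_zero <- rep(FALSE, n0)
  if ("P" %in% names(tbl)) {
    v <- validate_numeric(tbl$P, function(x) x >= 0 & x <= 1)
    fatal_coercion("P", v$parse_fail)
    bad <- bad | v$bad
    p_zero <- !is.na(v$value) & v$value == 0 & !v$bad
    v$value[p_zero] <- .Machine$double.xmin
    tbl$P <- v$value
  }
  numeric_rules <- list(
    EAF      = function(x) x > 0 & x < 1,
    SE       = function(x) x > 0 & is.finite(x),
    INFO     = function(x) x >= 0 & x <= 1.1,
    N        = function(x) x > 0 & is.finite(x),
    CaseN    = function(x) x > 0 & is.finite(x),
    ControlN = function(x) x > 0 & is.finite(x),
    B        = function(x) is.finite(x),
    Z        = function(x) is.finite(x)
  )
  for (col in intersect(names(numeric_rules), names(tbl))) {
    v <- validate_numeric(tbl[[col]], numeric_rules[[col]])
    fatal_coercion(col, v$parse_fail)
    bad <- bad | v$bad
    tbl[[col]] <- v$value
  }
  if (all(c("N", "CaseN", "ControlN") %in% names(tbl))) {
    viol <- sum(tbl$N < tbl$CaseN + tbl$ControlN, na.rm = TRUE)
    if (viol > 0L) inform(paste0(viol, " row(s) have N < CaseN + ControlN (kept)"))
  }

  tbl$p_zero <- p_zero
  tbl <- tbl[!bad, , drop = FALSE]
  list(tbl = tbl, entry = new_report_entry("validation", sum(bad)))
}
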