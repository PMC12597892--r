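# Identity repair: genome-build inference, compound-id splitting, merging
# with the reference panel on CHR:POS or RSID, allele-compatibility checks,
# multiallelic flagging.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  out <- vapply(strsplit(a, ""), function(ch) {
    paste(rev(unname(COMPLEMENT[ch])), collapse = "")
  }, character(1))
  out[is.na(a)] <- NA_character_
  out
}

#' Infer the genome build of a summary-statistics table
#'
#' Matches up to 10,000 rows (the first rows, for determinism) against the
#' panel positions of both GRCh37 and GRCh38 and calls the build with more
#' chromosome:position matches. A tie is resolved to GRCh38 with a warning.
#'
#' @param tbl Validated tibble with `CHR` and `POS`.
#' @param panel A `reference_panel` handle.
#' @param n_max Maximum rows sampled (default 10,000).
#' @return A `build_call` object: list with `build` (`"GRCh37"`/`"GRCh38"`),
#'   `n_sampled`, `matches_37`, `matches_38`.
#' @export
infer_build <- function(tbl, panel, n_max = 10000L) {
  if (!all(c("CHR", "POS") %in% names(tbl))) {
    abort("build inference requires CHR and POS columns")
  }
  smp <- tbl |>
    dplyr::filter(!is.na(.data$CHR), !is.na(.data$POS)) |>
    head(n_max) |>
    dplyr::distinct(.data$CHR, .data$POS)
  if (nrow(smp) == 0L) abort("no rows with CHR and POS available for build inference")

  ref <- ref_scan(panel, chr = unique(smp$CHR))
  if (isTRUE(panel$meta$has_indels)) {
    ref <- dplyr::bind_rows(ref, ref_scan(panel, chr = unique(smp$CHR), indels = TRUE))
  }
  m37 <- nrow(dplyr::semi_join(smp, ref, by = c(CHR = "CHR", POS = "POS_37")))
  m38 <- nrow(dplyr::semi_join(smp, ref, by = c(CHR = "CHR", POS = "POS_38")))
  if (m37 == 0L && m38 == 0L) {
    abort("no overlap with reference on either build: cannot infer genome build")
  }
  if (m37 == m38) {
    warn(paste0("build inference tie (", m37, " matches on both builds); using GRCh38"))
  }
  structure(list(build = if (m37 > m38) "GRCh37" else "GRCh38",
                 n_sampled = nrow(smp), matches_37 = m37, matches_38 = m38),
            class = "build_call")
}

#' @export
print.build_call <- function(x, ...) {
  cat("<build_call> ", x$build, " (", x$matches_37, " GRCh37 vs ",
      x$matches_38, " GRCh38 matches over ", x$n_sampled, " rows)\n", sep = "")
  invisible(x)
}

#' Split compound CHR:POS identifiers found in the rsID column
#'
#' Values of the form `chr<chr>:<pos>[:<ref>:<alt>]` (case-insensitive
#' `chr`/`ch` prefix optional) in the `RSID` column are split into `CHR` and
#' `POS`; any alleles embedded in the identifier are ignored in favor of the
#' allele columns, and the rsID cell is cleared so the true rsID can be
#' restored from the reference.
#'
#' @param tbl Tibble with an `RSID` column.
#' @return The tibble with `CHR`/`POS` filled for compound-id rows.
#' @export
split_compound_ids <- function(tbl) {
  if (!"RSID" %in% names(tbl)) return(tbl)
  pat <- "^(?:chr|ch)?([0-9]{1,2}|[XYM]|MT):([0-9]+)(?::[ACGTDIR]+:[ACGTDIR]+)?$"
  hit <- !is.na(tbl$RSID) & grepl(pat, tbl$RSID, ignore.case = TRUE, perl = TRUE)
  if (!any(hit)) return(tbl)
  if (!"CHR" %in% names(tbl)) tbl$CHR <- NA_character_
  if (!"POS" %in% names(tbl)) tbl$POS <- NA_integer_
  chr <- normalize_chr(sub(pat, "\\1", tbl$RSID[hit], ignore.case = TRUE, perl = TRUE))
  pos <- as.integer(sub(pat, "\\2", tbl$RSID[hit], ignore.case = TRUE, perl = TRUE))
  tbl$CHR[hit] <- chr
  tbl$POS[hit] <- pos
  tbl$RSID[hit] <- NA_character_
  tbl
}

# Allele compatibility of the unordered study pair {EA, OA} against the panel
# {REF} + alts: the pair must be a subset with one member equal to REF, either
# as observed or after base complementation (strand flip, flagged).
allele_compatibility <- function(ea, oa, ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)
  direct <- purrr::pmap_lgl(list(ea, oa, ref, alts), function(e, o, r, a) {
    ok <- c(r, a)
    (e %in% ok && o %in% ok) && (e == r || o == r)
  })
  ea_c <- complement_allele(ea)
  oa_c <- complement_allele(oa)
  flipped <- purrr::pmap_lgl(list(ea_c, oa_c, ref, alts), function(e, o, r, a) {
    ok <- c(r, a)
    (e %in% ok && o %in% ok) && (e == r || o == r)
  })
  # palindromic pairs (A/T, C/G) match both ways; count them as direct
  tibble::tibble(compatible = direct | flipped, strand_flipped = !direct & flipped)
}

#' Repair variant identity against the reference panel
#'
#' Merges the table with the panel by `CHR`:`POS` on the inferred build when
#' chromosome and position are available, and by rsID (after updating retired
#' identifiers through the merged-rsID map) otherwise; a table mixing the two
#' is handled row-wise. Every matched row gains the panel rsID, positions on
#' both builds and the panel reference allele. Rows with no panel entry are
#' dropped (`no_dbsnp_match`), as are rows whose allele pair is incompatible
#' with the panel reference + alternate alleles (`allele_incompatible`);
#' strand-complement matches are kept and flagged `strand_flipped`.
#'
#' Indel rows (flag `indel`) are matched against the panel's left-aligned
#' indel partition when `indel_strategy = "qc"`, after normalizing the study
#' alleles with [left_align_trim()]; with `"keep"` they pass through
#' unmatched (identity columns stay as supplied).
#'
#' @param tbl Validated tibble (post [detect_indels()]).
#' @param panel A `reference_panel`.
#' @param build A `build_call` from [infer_build()], or `NULL` when the table
#'   has no CHR/POS rows (pure rsID path).
#' @param indel_strategy `"qc"`, `"keep"` or `"drop"` (as given to
#'   [detect_indels()]).
#' @return A list with `tbl` (repaired: columns `RSID`, `CHR`, `POS_37`,
#'   `POS_38`, `REF`, `strand_flipped`, ...) and `entries` (report entries
#'   `no_dbsnp_match` and `allele_incompatible`).
#' @export
repair_ids <- function(tbl, panel, build = NULL,
                       indel_strategy = c("qc", "keep", "drop")) {
  indel_strategy <- match.arg(indel_strategy)
  n0 <- nrow(tbl)
  if (!"indel" %in% names(tbl)) tbl$indel <- FALSE
  tbl$.row_id <- seq_len(max(n0, 1L))[seq_len(n0)]

  has_pos <- if (all(c("CHR", "POS") %in% names(tbl))) {
    !is.na(tbl$CHR) & !is.na(tbl$POS)
  } else rep(FALSE, n0)
  has_rsid <- if ("RSID" %in% names(tbl)) !is.na(tbl$RSID) & !has_pos else rep(FALSE, n0)

  passthrough <- tbl$indel & indel_strategy == "keep"
  matchable <- (has_pos | has_rsid) & !passthrough

  pos_build <- if (!is.null(build)) build$build else "GRCh38"
  pos_col <- if (pos_build == "GRCh37") "POS_37" else "POS_38"

  empty_match <- function() {
    tibble::tibble(.row_id = integer(0), RSID_panel = integer(0),
                   CHR_panel = character(0), POS_37 = integer(0),
                   POS_38 = integer(0), REF = character(0), ALT = character(0))
  }

  match_by_rsid <- function(sub, indels) {
    if (nrow(sub) == 0L) return(empty_match())
    sub$rsid_num <- suppressWarnings(as.integer(sub("^rs", "", sub$RSID,
                                                    ignore.case = TRUE)))
    if (nrow(panel$merged) > 0L) {
      upd <- match(sub$rsid_num, panel$merged$OLD_RSID)
      sub$rsid_num[!is.na(upd)] <- panel$merged$NEW_RSID[upd[!is.na(upd)]]
    }
    ref <- ref_scan(panel, indels = indels)
    ref <- dplyr::rename(ref, RSID_panel = "RSID", CHR_panel = "CHR")
    joined <- dplyr::inner_join(sub, ref, by = c(rsid_num = "RSID_panel"),
                                relationship = "many-to-many")
    joined$RSID_panel <- joined$rsid_num
    joined$rsid_num <- NULL
    joined
  }

  match_by_pos <- function(sub, indels) {
    if (nrow(sub) == 0L) return(empty_match())
    if (indels) {
      norm <- left_align_trim_safe(sub$EffectAllele, sub$OtherAllele, sub$POS)
      sub$EffectAllele <- norm$ea
      sub$OtherAllele <- norm$oa
      sub$POS <- norm$pos
    }
    chroms <- unique(sub$CHR)
    ref <- ref_scan(panel, chr = chroms, indels = indels)
    ref <- dplyr::rename(ref, RSID_panel = "RSID", CHR_panel = "CHR")
    # join on copies so CHR_panel / POS_37 / POS_38 survive the merge
    ref$.chr_join <- ref$CHR_panel
    ref$.pos_join <- ref[[pos_col]]
    joined <- dplyr::inner_join(sub, ref,
                                by = c(CHR = ".chr_join", POS = ".pos_join"),
                                relationship = "many-to-many")
    joined
  }

  snv <- tbl[matchable & !tbl$indel, , drop = FALSE]
  ind <- tbl[matchable & tbl$indel, , drop = FALSE]

  joined <- dplyr::bind_rows(
    match_by_pos(snv[has_pos[snv$.row_id], , drop = FALSE], indels = FALSE),
    match_by_rsid(snv[has_rsid[snv$.row_id], , drop = FALSE], indels = FALSE),
    if (indel_strategy == "qc" && nrow(ind)) dplyr::bind_rows(
      match_by_pos(ind[has_pos[ind$.row_id], , drop = FALSE], indels = TRUE),
      match_by_rsid(ind[has_rsid[ind$.row_id], , drop = FALSE], indels = TRUE)
    ) else empty_match()
  )

  n_matchable <- sum(matchable)
  matched_ids <- unique(joined$.row_id)
  n_no_match <- n_matchable - length(matched_ids)

  if (nrow(joined)) {
    comp <- allele_compatibility(joined$EffectAllele, joined$OtherAllele,
                                 joined$REF, joined$ALT)
    joined$strand_flipped <- comp$strand_flipped
    joined <- joined[comp$compatible, , drop = FALSE]
    # a row compatible with several panel alts is kept once
    joined <- joined[!duplicated(joined$.row_id), , drop = FALSE]
  } else {
    joined$strand_flipped <- logical(0)
  }
  n_incompatible <- length(matched_ids) - nrow(joined)

  out <- joined |>
    dplyr::mutate(RSID = paste0("rs", .data$RSID_panel),
                  CHR = .data$CHR_panel) |>
    dplyr::select(-"RSID_panel", -"CHR_panel", -"ALT", -dplyr::any_of("POS"))

  if (any(passthrough)) {
    pass <- tbl[passthrough, , drop = FALSE]
    pass$strand_flipped <- FALSE
    pass$REF <- NA_character_
    if (!"POS_37" %in% names(pass)) pass$POS_37 <- NA_integer_
    if (!"POS_38" %in% names(pass)) pass$POS_38 <- NA_integer_
    if ("POS" %in% names(pass) && !is.null(build)) {
      if (pos_build == "GRCh37") pass$POS_37 <- pass$POS else pass$POS_38 <- pass$POS
    }
    pass <- dplyr::select(pass, -dplyr::any_of("POS"))
    out <- dplyr::bind_rows(out, pass)
  }

  out <- dplyr::arrange(out, .data$.row_id)
  out$.row_id <- NULL
  list(tbl = tibble::as_tibble(out),
       entries = list(new_report_entry("no_dbsnp_match", n_no_match),
                      new_report_entry("allele_incompatible", n_incompatible)))
}

# left_align_trim() for study allele pairs whose orientation is unknown and
# which may use D/I/R codes (left untouched: they cannot be normalized).
left_align_trim_safe <- function(ea, oa, pos) {
  can <- grepl("^[ACGT]+$", ea) & grepl("^[ACGT]+$", oa) & ea != oa
  out <- list(ea = ea, oa = oa, pos = pos)
  if (any(can)) {
    trimmed <- left_align_trim(ea[can], oa[can], pos[can])
    out$ea[can] <- trimmed$ref
    out$oa[can] <- trimmed$alt
    out$pos[can] <- trimmed$pos
  }
  out
}

#' Flag multiallelic variants
#'
#' After identity repair a site that carries more than one allele pair
#' appears as multiple rows sharing one rsID; all such rows are flagged
#' `multi_allelic = TRUE`. No rows are removed.
#'
#' @param tbl Post-[repair_ids()] tibble with `RSID`.
#' @return The tibble with a logical `multi_allelic` column.
#' @export
flag_multiallelic <- function(tbl) {
  if (nrow(tbl) == 0L) {
    tbl$multi_allelic <- logical(0)
    return(tbl)
  }
  tbl |>
    dplyr::group_by(.data$RSID) |>
    dplyr::mutate(multi_allelic = dplyr::n() > 1L & !is.na(.data$RSID)) |>
    dplyr::ungroup()
}
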