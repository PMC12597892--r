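# Deterministic synthetic fixtures: reference panels, frequency references
# and raw summary-statistics files with known ground truth. Everything is a
# pure function of (spec, seed), so the whole pipeline is testable without
# any download.

BASES <- c("A", "C", "G", "T")

# run code with a locally seeded RNG, restoring global RNG state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic fixture
#'
#' Bundles every knob of the fixture generators: panel size and layout, the
#' per-chromosome position shift between builds, indel/multiallelic
#' fractions, merged-rsID count, the GWAS sample size, and a corruption plan
#' of planted defects. Corruptions are applied to disjoint row sets so each
#' cleaning-report entry has an unambiguous expected count. A single integer
#' seed governs all randomness.
#'
#' @param seed Integer seed.
#' @param n_variants Panel size (SNVs + indels).
#' @param chromosomes Chromosome labels to use.
#' @param build_offset Named integer vector, per-chromosome shift such that
#'   `POS_38 = POS_37 + offset`; defaults to distinct non-zero shifts so the
#'   builds disagree at every site.
#' @param fraction_indels,fraction_multiallelic Fractions of panel variants
#'   that are indels / carry a second alternate allele.
#' @param merged_rsid_count Entries in the merged (retired) rsID map.
#' @param n_samples GWAS sample size used when simulating statistics.
#' @param corruption Named list of planted defect counts: `na_rows`,
#'   `duplicate_rows`, `invalid_p`, `invalid_eaf`, `invalid_se`, `off_panel`,
#'   `allele_incompatible`, `compound_ids`, `chr_prefix`, `swapped_alleles`.
#' @param reference_violations Named list of planted curation violations:
#'   `multi_position` (rsIDs placed at two positions; two records each),
#'   `duplicate_site` (extra larger rsIDs at an existing site),
#'   `chr_mismatch`, `single_build`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_variants = 1000L,
                         chromosomes = c("1", "2", "3"),
                         build_offset = NULL,
                         fraction_indels = 0.1,
                         fraction_multiallelic = 0.05,
                         merged_rsid_count = 20L,
                         n_samples = 1e5,
                         corruption = list(),
                         reference_violations = list()) {
  if (is.null(build_offset)) {
    build_offset <- setNames(1000L * seq_along(chromosomes), chromosomes)
  }
  stopifnot(all(chromosomes %in% VALID_CHR),
            all(chromosomes %in% names(build_offset)),
            fraction_indels >= 0, fraction_indels <= 1,
            fraction_multiallelic >= 0, fraction_multiallelic <= 1)
  corr_default <- list(na_rows = 0L, duplicate_rows = 0L, invalid_p = 0L,
                       invalid_eaf = 0L, invalid_se = 0L, off_panel = 0L,
                       allele_incompatible = 0L, compound_ids = 0L,
                       chr_prefix = 0L, swapped_alleles = 0L)
  bad <- setdiff(names(corruption), names(corr_default))
  if (length(bad)) abort(paste0("unknown corruption plan entries: ",
                                paste(bad, collapse = ", ")))
  viol_default <- list(multi_position = 0L, duplicate_site = 0L,
                       chr_mismatch = 0L, single_build = 0L)
  bad <- setdiff(names(reference_violations), names(viol_default))
  if (length(bad)) abort(paste0("unknown reference violations: ",
                                paste(bad, collapse = ", ")))
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 chromosomes = chromosomes, build_offset = build_offset,
                 fraction_indels = fraction_indels,
                 fraction_multiallelic = fraction_multiallelic,
                 merged_rsid_count = as.integer(merged_rsid_count),
                 n_samples = n_samples,
                 corruption = modifyList(corr_default, corruption),
                 reference_violations = modifyList(viol_default,
                                                   reference_violations)),
            class = "fixture_spec")
}

# Clean curated panel variants as a tibble (SNVs and indels marked).
generate_panel_variants <- function(spec) {
  with_local_seed(spec$seed, {
    n <- spec$n_variants
    chr <- sort(sample(spec$chromosomes, n, replace = TRUE))
    pos37 <- unlist(lapply(split(seq_len(n), chr), function(idx) {
      sort(sample.int(10e6, length(idx)))
    }))
    ord <- order(chr)
    chr <- chr[ord]
    pos38 <- pos37 + spec$build_offset[chr]
    rsid <- cumsum(sample.int(50L, n, replace = TRUE)) + 10L

    ref <- sample(BASES, n, replace = TRUE)
    alt <- unname(vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1)))
    is_indel <- runif(n) < spec$fraction_indels
    # indels are minimal by construction: single-base ref vs ref+suffix
    ins <- vapply(seq_len(sum(is_indel)), function(i) {
      paste(sample(BASES, sample(1:3, 1L), replace = TRUE), collapse = "")
    }, character(1))
    alt[is_indel] <- paste0(ref[is_indel], ins)
    is_multi <- !is_indel & runif(n) < spec$fraction_multiallelic
    alt2 <- vapply(which(is_multi), function(i) {
      sample(setdiff(BASES, c(ref[i], alt[i])), 1L)
    }, character(1))
    alt[is_multi] <- paste(pmin(alt[is_multi], alt2), pmax(alt[is_multi], alt2),
                           sep = ",")
    tibble::tibble(RSID = as.integer(rsid), CHR = as.character(chr),
                   POS_37 = as.integer(pos37), POS_38 = as.integer(pos38),
                   REF = ref, ALT = alt, indel = is_indel)
  })
}

generate_merged_map <- function(spec, panel_rsids) {
  if (spec$merged_rsid_count == 0L) {
    return(tibble::tibble(OLD_RSID = integer(0), NEW_RSID = integer(0)))
  }
  with_local_seed(spec$seed + 1L, {
    n <- spec$merged_rsid_count
    old <- max(panel_rsids) + sample.int(10000L, n)
    new <- sample(panel_rsids, n, replace = TRUE)
    map <- tibble::tibble(OLD_RSID = as.integer(old), NEW_RSID = as.integer(new))
    # turn a few entries into two-hop chains (old2 -> old1 -> panel)
    n_chain <- min(3L, n %/% 4L)
    if (n_chain > 0L) {
      map$NEW_RSID[seq_len(n_chain)] <- map$OLD_RSID[n_chain + seq_len(n_chain)]
    }
    map
  })
}

#' Generate and write a synthetic reference panel
#'
#' Emulates a curated dbSNP-style product: dual-build positions shifted by a
#' per-chromosome offset, a fraction of indel records stored in a separate
#' left-aligned partition, multiallelic sites with comma-joined alternates,
#' and a merged-rsID map containing short chains.
#'
#' @param spec A [fixture_spec()].
#' @param path Output directory.
#' @param overwrite Replace an existing panel.
#' @return A `reference_panel` handle (see [load_reference()]).
#' @export
make_reference <- function(spec, path, overwrite = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  v <- generate_panel_variants(spec)
  merged <- generate_merged_map(spec, v$RSID)
  write_reference(v[!v$indel, setdiff(names(v), "indel")], path,
                  merged = merged,
                  indels = if (any(v$indel)) v[v$indel, setdiff(names(v), "indel")],
                  overwrite = overwrite)
  load_reference(path)
}

#' Generate uncurated reference records with planted curation violations
#'
#' Produces the raw dual-build records that [curate_reference()] consumes: a
#' clean core (which survives curation) plus the planted violations counted
#' in `spec$reference_violations`. Planted sets are disjoint, so each filter's
#' expected removal count is exact: every multi-position rsID contributes two
#' removed records; the other violation types contribute one each.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `raw` (uncurated tibble), `expected_removed` (tibble
#'   per filter) and `clean` (the records that survive).
#' @export
make_raw_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  v <- generate_panel_variants(spec)
  clean <- tibble::tibble(RSID = v$RSID, CHR_37 = v$CHR, POS_37 = v$POS_37,
                          CHR_38 = v$CHR, POS_38 = v$POS_38,
                          REF = v$REF, ALT = v$ALT)
  viol <- spec$reference_violations
  with_local_seed(spec$seed + 2L, {
    next_rsid <- max(clean$RSID)
    new_rsid <- function(k) {
      out <- next_rsid + seq_len(k)
      next_rsid <<- next_rsid + k
      as.integer(out)
    }
    free_pos <- function(k, base) {
      # positions guaranteed off every clean site on either build, and in
      # a range disjoint from other planted violation types
      as.integer(base + sample.int(1e6, k))
    }
    planted <- list()
    if (viol$multi_position > 0L) {
      ids <- new_rsid(viol$multi_position)
      p1 <- free_pos(viol$multi_position, 20e6)
      p2 <- p1 + 2e6
      chrs <- rep(sample(spec$chromosomes, viol$multi_position, replace = TRUE),
                  each = 2L)
      pos <- as.vector(rbind(p1, p2))
      planted$multi <- tibble::tibble(
        RSID = rep(ids, each = 2L), CHR_37 = chrs, POS_37 = pos,
        CHR_38 = chrs, POS_38 = pos + 1L, REF = "A", ALT = "G")
    }
    if (viol$duplicate_site > 0L) {
      take <- clean[sample.int(nrow(clean), viol$duplicate_site), ]
      planted$dup <- dplyr::mutate(take, RSID = new_rsid(viol$duplicate_site))
    }
    if (viol$chr_mismatch > 0L) {
      chrs <- sample(spec$chromosomes, viol$chr_mismatch, replace = TRUE)
      other <- vapply(chrs, function(c) sample(setdiff(spec$chromosomes, c), 1L),
                      character(1))
      planted$chr <- tibble::tibble(
        RSID = new_rsid(viol$chr_mismatch), CHR_37 = chrs,
        POS_37 = free_pos(viol$chr_mismatch, 24e6),
        CHR_38 = other, POS_38 = free_pos(viol$chr_mismatch, 24e6),
        REF = "C", ALT = "T")
    }
    if (viol$single_build > 0L) {
      chrs <- sample(spec$chromosomes, viol$single_build, replace = TRUE)
      planted$single <- tibble::tibble(
        RSID = new_rsid(viol$single_build), CHR_37 = chrs,
        POS_37 = free_pos(viol$single_build, 27e6),
        CHR_38 = chrs, POS_38 = NA_integer_, REF = "G", ALT = "A")
    }
    raw <- dplyr::bind_rows(c(list(clean = clean), planted))
    raw <- raw[sample.int(nrow(raw)), ]
    expected <- tibble::tibble(
      filter = c("multi_position_rsid", "duplicate_site", "chr_mismatch",
                 "single_build"),
      removed = c(2L * viol$multi_position, viol$duplicate_site,
                  viol$chr_mismatch, viol$single_build))
    list(raw = raw, expected_removed = expected, clean = clean)
  })
}

#' Generate a raw summary-statistics file with known ground truth
#'
#' Draws variants from the panel at the chosen build's positions and
#' simulates association statistics: `EAF ~ U(0.05, 0.95)`, a true effect
#' `beta ~ N(0, 0.02^2)` observed with sampling noise at `SE0 =
#' 1/sqrt(2 EAF (1-EAF) N)`, `Z` as the Wald ratio, and final `B`, `SE`
#' defined through the Z/N/EAF identities so that the statistics columns are
#' mutually consistent and individually recoverable. The corruption plan is
#' then applied to disjoint row sets, headers are renamed to randomly chosen
#' aliases, and rows are shuffled.
#'
#' @param spec A [fixture_spec()].
#' @param panel A `reference_panel` from [make_reference()].
#' @param build Which build's coordinates the raw file uses: 37 or 38.
#' @param path Optional file path (`.tsv` or `.tsv.gz`) to write the messy
#'   file to.
#' @param id_cols Variant-identity columns in the raw file: `"chr_pos"`,
#'   `"rsid"`, or `"both"`.
#' @param n_rows Number of panel variants to draw (default: all).
#' @param alias_headers Rename columns to random dialect aliases.
#' @return A list with `raw` (messy tibble as written), `truth` (expected
#'   harmonized survivors), `plan` (realized corruption counts) and `path`.
#' @export
make_sumstats <- function(spec, panel, build = 38, path = NULL,
                          id_cols = c("chr_pos", "rsid", "both"),
                          n_rows = NULL, alias_headers = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(panel, "reference_panel"))
  id_cols <- match.arg(id_cols)
  build <- as.character(build)
  stopifnot(build %in% c("37", "38"))
  pos_col <- paste0("POS_", build)

  snv <- ref_scan(panel)
  ind <- ref_scan(panel, indels = TRUE)
  snv$indel <- rep(FALSE, nrow(snv))
  ind$indel <- rep(TRUE, nrow(ind))
  pool <- dplyr::bind_rows(snv, ind)

  with_local_seed(spec$seed + 3L, {
    n <- min(n_rows %||% nrow(pool), nrow(pool))
    pool <- pool[sort(sample.int(nrow(pool), n)), ]

    eaf <- runif(n, 0.05, 0.95)
    nn <- rep(spec$n_samples, n)
    beta_true <- rnorm(n, 0, 0.02)
    se0 <- 1 / sqrt(2 * eaf * (1 - eaf) * nn)
    bhat <- beta_true + rnorm(n) * se0
    z <- bhat / se0
    denom <- sqrt(2 * eaf * (1 - eaf) * (nn + z^2))
    b <- z / denom
    se <- 1 / denom
    p <- 2 * exp(pnorm(-abs(z), log.p = TRUE))
    alt1 <- vapply(strsplit(pool$ALT, ",", fixed = TRUE), `[[`, character(1), 1L)

    tbl <- tibble::tibble(
      RSID = paste0("rs", pool$RSID),
      CHR = pool$CHR,
      POS = pool[[pos_col]],
      EffectAllele = alt1,
      OtherAllele = pool$REF,
      B = b, SE = se, Z = z, P = p, EAF = eaf, N = nn,
      POS_37 = pool$POS_37, POS_38 = pool$POS_38,
      REF = pool$REF, indel = pool$indel
    )

    # --- corruption plan, disjoint row sets -------------------------------
    plan <- spec$corruption
    n_corrupt <- sum(unlist(plan[setdiff(names(plan), "duplicate_rows")]))
    # corruptions target SNV rows only, so indel routing never confounds the
    # per-filter attribution
    candidates <- which(!tbl$indel)
    if (n_corrupt > length(candidates)) abort("corruption plan exceeds available rows")
    # compound ids only make sense when the raw file carries an RSID column
    if (id_cols == "chr_pos") plan$compound_ids <- 0L
    pools <- split_corruption_rows(candidates, plan)
    removed <- rep(FALSE, n)
    # pristine identity for the ground truth: the pipeline restores these
    # from the reference even where the raw file carries a corrupted form
    rsid_clean <- tbl$RSID
    chr_clean <- tbl$CHR

    if (length(pools$na_rows)) {
      tbl$EffectAllele[pools$na_rows] <- NA_character_
      removed[pools$na_rows] <- TRUE
    }
    if (length(pools$invalid_p)) {
      tbl$P[pools$invalid_p] <- 1.3
      removed[pools$invalid_p] <- TRUE
    }
    if (length(pools$invalid_eaf)) {
      tbl$EAF[pools$invalid_eaf] <- 1.5
      removed[pools$invalid_eaf] <- TRUE
    }
    if (length(pools$invalid_se)) {
      tbl$SE[pools$invalid_se] <- -0.1
      removed[pools$invalid_se] <- TRUE
    }
    if (length(pools$off_panel)) {
      i <- pools$off_panel
      tbl$POS[i] <- 25e6 + sample.int(1e6, length(i))  # beyond any panel site
      tbl$RSID[i] <- paste0("rs", max(pool$RSID) + 20000L + seq_along(i))
      removed[i] <- TRUE
    }
    if (length(pools$allele_incompatible)) {
      i <- pools$allele_incompatible
      # neither allele nor its complement matches the panel reference allele
      pairs <- t(vapply(tbl$REF[i], function(r) {
        setdiff(BASES, c(r, unname(COMPLEMENT[r])))
      }, character(2)))
      tbl$EffectAllele[i] <- unname(pairs[, 1])
      tbl$OtherAllele[i] <- unname(pairs[, 2])
      tbl$indel[i] <- FALSE
      removed[i] <- TRUE
    }
    if (length(pools$compound_ids)) {
      i <- pools$compound_ids
      tbl$RSID[i] <- paste0(tbl$CHR[i], ":", tbl$POS[i])
    }
    if (length(pools$chr_prefix)) {
      i <- pools$chr_prefix
      tbl$CHR[i] <- paste0("chr", tbl$CHR[i])
    }
    if (length(pools$swapped_alleles)) {
      i <- pools$swapped_alleles
      ea <- tbl$EffectAllele[i]
      tbl$EffectAllele[i] <- tbl$OtherAllele[i]
      tbl$OtherAllele[i] <- ea
      tbl$B[i] <- -tbl$B[i]
      tbl$Z[i] <- -tbl$Z[i]
      tbl$EAF[i] <- 1 - tbl$EAF[i]
    }

    truth <- tbl
    truth$RSID <- rsid_clean
    truth$CHR <- chr_clean
    truth <- truth[!removed, c("RSID", "CHR", "POS_37", "POS_38", "EffectAllele",
                               "OtherAllele", "B", "SE", "Z", "P", "EAF", "N",
                               "indel")]

    raw <- tbl[, c("RSID", "CHR", "POS", "EffectAllele", "OtherAllele",
                   "B", "SE", "Z", "P", "EAF", "N")]
    raw <- switch(id_cols,
      chr_pos = dplyr::select(raw, -"RSID"),
      rsid = dplyr::select(raw, -"CHR", -"POS"),
      both = raw
    )
    if (plan$duplicate_rows > 0L) {
      dup_src <- which(!removed)
      if (plan$duplicate_rows > length(dup_src)) {
        abort("duplicate_rows exceeds surviving rows")
      }
      raw <- dplyr::bind_rows(raw, raw[sample(dup_src, plan$duplicate_rows), ])
    }
    raw <- raw[sample.int(nrow(raw)), ]

    if (alias_headers) {
      names(raw) <- vapply(names(raw), function(canon) {
        sample(COLUMN_ALIASES[[canon]], 1L)
      }, character(1))
    }
    if (!is.null(path)) {
      readr::write_tsv(raw, path, na = "NA", progress = FALSE)
    }
    list(raw = raw, truth = truth,
         plan = plan[c("na_rows", "duplicate_rows", "invalid_p", "invalid_eaf",
                       "invalid_se", "off_panel", "allele_incompatible",
                       "compound_ids", "chr_prefix", "swapped_alleles")],
         path = path)
  })
}

# deterministic disjoint index pools for the corruption plan
split_corruption_rows <- function(candidates, plan) {
  keys <- c("na_rows", "invalid_p", "invalid_eaf", "invalid_se", "off_panel",
            "allele_incompatible", "compound_ids", "chr_prefix",
            "swapped_alleles")
  idx <- sample(candidates)
  out <- list()
  at <- 1L
  for (k in keys) {
    cnt <- plan[[k]]
    out[[k]] <- if (cnt > 0L) idx[at:(at + cnt - 1L)] else integer(0)
    at <- at + cnt
  }
  out
}

#' Generate a synthetic per-population frequency reference
#'
#' One alternate-allele frequency per (variant, superpopulation) for the
#' panel's first alternate allele, emulating 1000 Genomes-style precomputed
#' estimates.
#'
#' @param spec A [fixture_spec()].
#' @param panel A `reference_panel`.
#' @param populations Population labels (default the five superpopulations).
#' @return A tibble with `RSID`, `POP`, `ALT`, `ALT_FREQ`.
#' @export
make_freq_reference <- function(spec, panel,
                                populations = c("AFR", "AMR", "EAS", "EUR", "SAS")) {
  snv <- ref_scan(panel)
  with_local_seed(spec$seed + 4L, {
    alt1 <- vapply(strsplit(snv$ALT, ",", fixed = TRUE), `[[`, character(1), 1L)
    tidyr::crossing(tibble::tibble(RSID = snv$RSID, ALT = alt1),
                    POP = populations) |>
      dplyr::mutate(ALT_FREQ = round(runif(dplyr::n(), 0.05, 0.95), 4)) |>
      dplyr::select("RSID", "POP", "ALT", "ALT_FREQ")
  })
}
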