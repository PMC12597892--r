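# Reference curation filters, panel I/O, indel normalization, merged rsIDs.

raw_ref_row <- function(rsid, chr, pos, chr38 = chr, pos38 = pos + 1000L,
                        ref = "A", alt = "G") {
  tibble::tibble(RSID = as.integer(rsid), CHR_37 = as.character(chr),
                 POS_37 = as.integer(pos), CHR_38 = as.character(chr38),
                 POS_38 = as.integer(pos38), REF = ref, ALT = alt)
}

test_that("an rsID mapping to multiple positions is removed entirely", {
  raw <- dplyr::bind_rows(
    raw_ref_row(100, "1", 500), raw_ref_row(100, "1", 900),  # violator
    raw_ref_row(7, "1", 100))
  cur <- curate_reference(raw)
  expect_equal(cur$removed$removed[cur$removed$filter == "multi_position_rsid"], 2L)
  expect_equal(cur$variants$RSID, 7L)
})

test_that("at a shared site the smallest rsID survives", {
  raw <- dplyr::bind_rows(raw_ref_row(123, "1", 500), raw_ref_row(45, "1", 500),
                          raw_ref_row(9, "2", 200))
  cur <- curate_reference(raw)
  expect_setequal(cur$variants$RSID, c(45L, 9L))
  expect_equal(cur$removed$removed[cur$removed$filter == "duplicate_site"], 1L)
})

test_that("chromosome disagreement between builds removes the record", {
  raw <- dplyr::bind_rows(raw_ref_row(11, "1", 500, chr38 = "2"),
                          raw_ref_row(12, "1", 600))
  cur <- curate_reference(raw)
  expect_equal(cur$variants$RSID, 12L)
  expect_equal(cur$removed$removed[cur$removed$filter == "chr_mismatch"], 1L)
})

test_that("records lacking a position on either build are removed", {
  raw <- dplyr::bind_rows(raw_ref_row(21, "1", 500),
                          raw_ref_row(22, "1", 600, pos38 = NA))
  cur <- curate_reference(raw)
  expect_equal(cur$variants$RSID, 21L)
  expect_equal(cur$removed$removed[cur$removed$filter == "single_build"], 1L)
})

test_that("curation recovers exact planted per-filter counts and is idempotent", {
  spec <- test_spec(reference_violations = list(multi_position = 5L,
                                                duplicate_site = 4L,
                                                chr_mismatch = 3L,
                                                single_build = 2L))
  rr <- make_raw_reference(spec)
  cur <- curate_reference(rr$raw)
  expect_equal(cur$removed, rr$expected_removed)

  # idempotence: re-curating the survivors removes nothing
  again <- curate_reference(
    dplyr::transmute(cur$variants, RSID = .data$RSID, CHR_37 = .data$CHR,
                     POS_37 = .data$POS_37, CHR_38 = .data$CHR,
                     POS_38 = .data$POS_38, REF = .data$REF, ALT = .data$ALT))
  expect_equal(sum(again$removed$removed), 0L)
  expect_equal(again$variants, cur$variants)
})

test_that("after curation (chr, pos) is a key on both builds", {
  spec <- test_spec(reference_violations = list(multi_position = 3L,
                                                duplicate_site = 5L))
  cur <- curate_reference(make_raw_reference(spec)$raw)
  expect_false(any(duplicated(paste(cur$variants$CHR, cur$variants$POS_37))))
  expect_false(any(duplicated(paste(cur$variants$CHR, cur$variants$POS_38))))
})

test_that("a panel round-trips through disk and scans per chromosome", {
  panel <- test_panel()
  all_v <- gwash:::ref_scan(panel)
  chr2 <- gwash:::ref_scan(panel, chr = "2")
  expect_gt(nrow(chr2), 0)
  expect_true(all(chr2$CHR == "2"))
  expect_equal(chr2, dplyr::filter(all_v, .data$CHR == "2"))

  # write the scanned variants again and reload: identical variant set
  dir2 <- withr::local_tempdir()
  write_reference(all_v, dir2, overwrite = TRUE)
  expect_equal(gwash:::ref_scan(load_reference(dir2)), all_v)
})

test_that("load_reference fails on non-panels and missing partitions", {
  empty <- withr::local_tempdir()
  expect_error(load_reference(empty), "_panel.json")

  spec <- test_spec()
  dir <- withr::local_tempdir()
  make_reference(spec, dir, overwrite = TRUE)
  unlink(file.path(dir, "variants", "CHR=2"), recursive = TRUE)
  expect_error(load_reference(dir), "CHR=2")
})

test_that("merged-rsID chains resolve transitively and cycles are fatal", {
  m <- tibble::tibble(OLD_RSID = c(1L, 2L, 3L), NEW_RSID = c(2L, 3L, 10L))
  r <- gwash:::resolve_merged_chains(m)
  expect_equal(r$NEW_RSID, c(10L, 10L, 10L))
  expect_error(gwash:::resolve_merged_chains(
    tibble::tibble(OLD_RSID = c(1L, 2L), NEW_RSID = c(2L, 1L))), "cycle")
  expect_error(gwash:::resolve_merged_chains(
    tibble::tibble(OLD_RSID = 5L, NEW_RSID = 5L)), "self-mapping")
})

test_that("left_align_trim matches its worked examples", {
  expect_equal(left_align_trim("CAG", "CAGAG", 100),
               tibble::tibble(ref = "C", alt = "CAG", pos = 100L))
  expect_equal(left_align_trim("A", "G", 100),
               tibble::tibble(ref = "A", alt = "G", pos = 100L))
  expect_equal(left_align_trim("TTC", "TC", 100),
               tibble::tibble(ref = "TT", alt = "T", pos = 100L))
  expect_error(left_align_trim("AC", "AC", 5), "identical")
  expect_error(left_align_trim("A-", "A", 5), "A,C,G,T")
})

test_that("left_align_trim agrees with a brute-force minimal-representation oracle", {
  # oracle: repeatedly strip one shared trailing base, then one shared
  # leading base, each only while both alleles keep >= 1 base afterwards
  oracle <- function(r, a, p) {
    repeat {
      rn <- nchar(r); an <- nchar(a)
      if (rn > 1 && an > 1 && substr(r, rn, rn) == substr(a, an, an)) {
        r <- substr(r, 1, rn - 1); a <- substr(a, 1, an - 1)
      } else break
    }
    repeat {
      if (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
        r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a)); p <- p + 1L
      } else break
    }
    list(r, a, p)
  }
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    r <- paste0(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    a <- paste0(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    if (r == a) next
    p <- sample.int(1000L, 1)
    got <- left_align_trim(r, a, p)
    want <- oracle(r, a, p)
    expect_identical(unname(as.list(got)), want,
                     label = paste0("pair ", r, "/", a))
  }
})
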