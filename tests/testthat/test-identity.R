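# Build inference, compound-id splitting, reference matching, multiallelics.

# typed sumstats rows drawn straight from the panel (skipping earlier stages)
panel_rows <- function(panel, build = "38", n = NULL, indels = FALSE) {
  v <- gwash:::ref_scan(panel, indels = indels)
  if (!is.null(n)) v <- v[seq_len(n), ]
  alt1 <- vapply(strsplit(v$ALT, ",", fixed = TRUE), `[[`, character(1), 1L)
  tibble::tibble(CHR = v$CHR, POS = v[[paste0("POS_", build)]],
                 EffectAllele = unname(alt1), OtherAllele = v$REF,
                 B = 0.1, SE = 0.05, indel = indels)
}

test_that("infer_build recovers the generating build with exhaustive-match counts", {
  panel <- test_panel()
  tbl <- panel_rows(panel, "38")
  bc <- infer_build(tbl, panel)
  expect_s3_class(bc, "build_call")
  expect_equal(bc$build, "GRCh38")
  expect_equal(bc$n_sampled, nrow(tbl))

  # oracle: exhaustive match counts against the materialized panel
  v <- dplyr::bind_rows(gwash:::ref_scan(panel), gwash:::ref_scan(panel, indels = TRUE))
  m38 <- sum(paste(tbl$CHR, tbl$POS) %in% paste(v$CHR, v$POS_38))
  m37 <- sum(paste(tbl$CHR, tbl$POS) %in% paste(v$CHR, v$POS_37))
  expect_equal(bc$matches_38, m38)
  expect_equal(bc$matches_37, m37)

  expect_equal(infer_build(panel_rows(panel, "37"), panel)$build, "GRCh37")
})

test_that("build sampling is bounded by the table and by 10,000 rows", {
  panel <- test_panel()
  tbl <- panel_rows(panel, "38", n = 17)
  expect_equal(infer_build(tbl, panel)$n_sampled, 17L)
  expect_equal(infer_build(panel_rows(panel, "38"), panel, n_max = 50L)$n_sampled, 50L)
})

test_that("a build tie resolves to GRCh38 with a warning; no overlap is fatal", {
  panel <- test_panel()
  t37 <- panel_rows(panel, "37", n = 10)
  t38 <- panel_rows(panel, "38", n = 10)
  expect_warning(bc <- infer_build(dplyr::bind_rows(t37, t38), panel), "tie")
  expect_equal(bc$build, "GRCh38")

  none <- tibble::tibble(CHR = "1", POS = c(99e6, 99e6 + 1),
                         EffectAllele = "A", OtherAllele = "G")
  expect_error(infer_build(none, panel), "no overlap")
})

test_that("compound chr:pos identifiers are split and cleared", {
  tbl <- tibble::tibble(RSID = c("1:12345:A:G", "rs789", "chr2:555", "CH3:9:AT:A"),
                        EffectAllele = "A", OtherAllele = "G")
  out <- split_compound_ids(tbl)
  expect_equal(out$CHR, c("1", NA, "2", "3"))
  expect_equal(out$POS, c(12345L, NA, 555L, 9L))
  expect_equal(out$RSID, c(NA, "rs789", NA, NA))

  # regex oracle over generated ids
  set.seed(12)
  ids <- paste0(sample(c("", "chr", "CH"), 50, TRUE), sample(c(1:22, "X"), 50, TRUE),
                ":", sample.int(1e6, 50),
                sample(c("", ":A:G", ":AT:A"), 50, TRUE))
  out2 <- split_compound_ids(tibble::tibble(RSID = ids))
  expect_true(all(is.na(out2$RSID)))
  expect_equal(out2$POS,
               as.integer(sub("^[^:]+:([0-9]+).*$", "\\1", ids)))
})

test_that("repair_ids restores rsID and both-build positions from chr:pos", {
  panel <- test_panel()
  tbl <- panel_rows(panel, "38", n = 25)
  r <- repair_ids(tbl, panel, build = infer_build(tbl, panel))
  expect_equal(nrow(r$tbl), 25L)
  expect_true(all(grepl("^rs[0-9]+$", r$tbl$RSID)))
  expect_true(all(!is.na(r$tbl$POS_37) & !is.na(r$tbl$POS_38)))
  expect_equal(r$tbl$POS_38 - r$tbl$POS_37,
               unname(test_spec()$build_offset[r$tbl$CHR]))
  expect_equal(r$entries[[1]]$removed, 0L)
  expect_equal(r$entries[[2]]$removed, 0L)
})

test_that("unmatched and allele-incompatible rows are dropped with separate counts", {
  panel <- test_panel()
  tbl <- panel_rows(panel, "38", n = 20)
  tbl$POS[1:3] <- 90e6 + 1:3                      # off panel
  # incompatible: neither allele nor complement equals the panel ref
  v <- gwash:::ref_scan(panel)[4:5, ]
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(v$REF[1], gwash:::complement_allele(v$REF[1])))
  tbl$EffectAllele[4] <- bad[1]; tbl$OtherAllele[4] <- bad[2]
  bad2 <- setdiff(c("A", "C", "G", "T"),
                  c(v$REF[2], gwash:::complement_allele(v$REF[2])))
  tbl$EffectAllele[5] <- bad2[1]; tbl$OtherAllele[5] <- bad2[2]
  r <- repair_ids(tbl, panel, build = infer_build(tbl, panel))
  expect_equal(r$entries[[1]]$removed, 3L)  # no_dbsnp_match
  expect_equal(r$entries[[2]]$removed, 2L)  # allele_incompatible
  expect_equal(nrow(r$tbl), 15L)
})

test_that("strand-complemented allele pairs are matched and flagged", {
  panel <- test_panel()
  v <- gwash:::ref_scan(panel)
  # pick non-palindromic biallelic SNVs and complement both alleles
  alt1 <- vapply(strsplit(v$ALT, ",", fixed = TRUE), `[[`, character(1), 1L)
  ok <- nchar(alt1) == 1 & gwash:::complement_allele(v$REF) != alt1
  v <- v[ok, ][1:10, ]
  alt1 <- unname(vapply(strsplit(v$ALT, ",", fixed = TRUE), `[[`, character(1), 1L))
  tbl <- tibble::tibble(CHR = v$CHR, POS = v$POS_38,
                        EffectAllele = gwash:::complement_allele(alt1),
                        OtherAllele = gwash:::complement_allele(v$REF),
                        B = 0.1, SE = 0.05)
  r <- repair_ids(tbl, panel, build = list(build = "GRCh38"))
  expect_equal(nrow(r$tbl), 10L)
  expect_true(all(r$tbl$strand_flipped))
})

test_that("retired rsIDs are matched through the merged map", {
  panel <- test_panel()
  merged <- panel$merged
  skip_if(nrow(merged) == 0)
  v <- gwash:::ref_scan(panel)
  hit <- merged[merged$NEW_RSID %in% v$RSID, ][1:5, ]
  cur <- v[match(hit$NEW_RSID, v$RSID), ]
  alt1 <- unname(vapply(strsplit(cur$ALT, ",", fixed = TRUE), `[[`, character(1), 1L))
  tbl <- tibble::tibble(RSID = paste0("rs", hit$OLD_RSID),
                        EffectAllele = alt1, OtherAllele = cur$REF,
                        B = 0.1, SE = 0.05)
  r <- repair_ids(tbl, panel, build = NULL)
  expect_equal(nrow(r$tbl), 5L)
  expect_equal(sort(r$tbl$RSID), sort(paste0("rs", hit$NEW_RSID)))
})

test_that("matching by chr:pos and by rsID yields identical surviving variants", {
  spec <- test_spec()
  panel <- test_panel()
  by_pos <- make_sumstats(spec, panel, build = 38, id_cols = "chr_pos")
  by_rsid <- make_sumstats(spec, panel, build = 38, id_cols = "rsid")
  r1 <- suppressMessages(harmonise_sumstats(by_pos$raw, panel))
  r2 <- suppressMessages(harmonise_sumstats(by_rsid$raw, panel))
  key <- function(t) paste(t$RSID, t$EffectAllele, t$OtherAllele)
  expect_setequal(key(r1$tbl), key(r2$tbl))
  expect_equal(nrow(r1$tbl), nrow(r2$tbl))
})

test_that("rows sharing an rsID are all flagged multiallelic", {
  tbl <- tibble::tibble(RSID = c("rs10", "rs10", "rs11"),
                        EffectAllele = c("A", "A", "C"),
                        OtherAllele = c("G", "C", "T"))
  out <- flag_multiallelic(tbl)
  expect_equal(out$multi_allelic, c(TRUE, TRUE, FALSE))
  empty <- flag_multiallelic(tbl[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true("multi_allelic" %in% names(empty))
})

test_that("removed-row counts equal brute-force set differences on fixtures", {
  spec <- test_spec(corruption = list(off_panel = 6L, allele_incompatible = 3L))
  panel <- test_panel()
  sim <- make_sumstats(spec, panel, build = 38)
  res <- suppressMessages(harmonise_sumstats(sim$raw, panel))
  rep <- res$report
  expect_equal(rep$removed[rep$step == "no_dbsnp_match"], 6L)
  expect_equal(rep$removed[rep$step == "allele_incompatible"], 3L)
  expect_equal(nrow(res$tbl), nrow(sim$raw) - 9L)
})
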