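# Inverse-variance fixed-effects pooling, heterogeneity, allele alignment.

# explicit-loop oracle for one variant: plain arithmetic, no dplyr
ivw_oracle <- function(b, se) {
  w <- 1 / se^2
  bm <- sum(w * b) / sum(w)
  sem <- 1 / sqrt(sum(w))
  q <- sum(w * (b - bm)^2)
  k <- length(b)
  list(B_meta = bm, SE_meta = sem, Z_meta = bm / sem,
       P_meta = 2 * pnorm(-abs(bm / sem)), Q = q,
       P_het = pchisq(q, k - 1, lower.tail = FALSE),
       I2 = if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0)
}

# long table of k studies per variant with random effects
simulate_long <- function(n_variants, k, seed = 1, swap_some = FALSE) {
  set.seed(seed)
  tidyr::crossing(RSID = paste0("rs", seq_len(n_variants)),
                  study = paste0("s", seq_len(k))) |>
    dplyr::mutate(EffectAllele = "A", OtherAllele = "G",
                  SE = runif(dplyr::n(), 0.02, 0.2),
                  B = rnorm(dplyr::n(), 0, 0.05),
                  study = factor(.data$study, levels = paste0("s", seq_len(k))))
}

test_that("two- and three-study worked examples match closed forms", {
  two <- tibble::tibble(study = c("a", "b"), RSID = "rs1", EffectAllele = "A",
                        OtherAllele = "G", B = c(0.1, 0.3), SE = 0.1)
  r <- pool_fixed_effects(two)
  expect_equal(r$B_meta, 0.2)
  expect_equal(r$SE_meta, 0.070711, tolerance = 1e-5)
  expect_equal(r$Q, 2)
  expect_equal(r$I2, 50)
  expect_equal(r$direction, "++")

  three <- tibble::tibble(study = c("a", "b", "c"), RSID = "rs1",
                          EffectAllele = "A", OtherAllele = "G",
                          B = -0.2, SE = 0.1)
  r3 <- pool_fixed_effects(three)
  expect_equal(r3$B_meta, -0.2)
  expect_equal(r3$SE_meta, 0.1 / sqrt(3))
  expect_equal(r3$Q, 0)
  expect_equal(r3$I2, 0)
  expect_equal(r3$direction, "---")
})

test_that("a single study passes through when min_k = 1", {
  one <- tibble::tibble(study = "a", RSID = "rs1", EffectAllele = "A",
                        OtherAllele = "G", B = 0.17, SE = 0.04)
  r <- pool_fixed_effects(one, min_k = 1)
  expect_equal(r$B_meta, 0.17)
  expect_equal(r$SE_meta, 0.04)
  expect_true(is.na(r$Q) && is.na(r$P_het) && is.na(r$I2))
  expect_equal(nrow(pool_fixed_effects(one, min_k = 2)), 0L)
})

test_that("pooled fields agree with the explicit-loop oracle on 1,000 variants", {
  long <- simulate_long(1000, 10, seed = 31)
  res <- pool_fixed_effects(long, min_k = 2)
  expect_equal(nrow(res), 1000L)
  # every pooled field, checked per variant against plain-arithmetic loops
  set.seed(99)
  for (i in sample.int(1000, 300)) {
    rs <- paste0("rs", i)
    sub <- long[long$RSID == rs, ]
    want <- ivw_oracle(sub$B, sub$SE)
    got <- res[res$RSID == rs, ]
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10, label = paste(rs, f))
    }
  }
})

test_that("pooling matches an established fixed-effects implementation", {
  skip_if_not_installed("metafor")
  set.seed(4)
  b <- rnorm(8, 0.1, 0.2); se <- runif(8, 0.05, 0.3)
  long <- tibble::tibble(study = paste0("s", 1:8), RSID = "rs1",
                         EffectAllele = "A", OtherAllele = "G", B = b, SE = se)
  got <- pool_fixed_effects(long)
  fit <- metafor::rma(yi = b, sei = se, method = "FE")
  expect_equal(got$B_meta, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(got$SE_meta, fit$se, tolerance = 1e-10)
  expect_equal(got$Q, fit$QE, tolerance = 1e-10)
  expect_equal(got$P_meta, fit$pval, tolerance = 1e-10)
})

test_that("allele alignment is an involution and excludes mismatched sets", {
  rows <- tibble::tibble(study = c("a", "b", "c"), RSID = "rs1",
                         EffectAllele = c("A", "G", "A"),
                         OtherAllele = c("G", "A", "C"),
                         B = c(0.2, -0.2, 0.9), SE = 0.1, EAF = c(0.3, 0.7, 0.5))
  out <- align_effects(rows)
  expect_equal(out$B[1:2], c(0.2, 0.2))       # swapped study recovers study 1
  expect_equal(out$EAF[1:2], c(0.3, 0.3))
  expect_equal(out$aligned, c(TRUE, TRUE, FALSE))

  # two studies reporting disjoint allele sets at one rsID: each becomes its
  # own variant row, with "?" marking the study that did not contribute
  long <- tibble::tibble(study = factor(c("a", "b"), c("a", "b")), RSID = "rs1",
                         EffectAllele = c("A", "C"), OtherAllele = c("G", "T"),
                         B = 0.1, SE = 0.1)
  r <- pool_fixed_effects(long, min_k = 1)
  expect_equal(r$k, c(1L, 1L))
  expect_setequal(r$direction, c("+?", "?+"))
})

test_that("study order affects only the direction string, never pooled values", {
  long <- simulate_long(50, 5, seed = 7)
  base <- pool_fixed_effects(long)
  perm <- long[sample.int(nrow(long)), ]
  # same factor levels -> same study order; row order must not matter
  again <- pool_fixed_effects(perm)
  expect_equal(dplyr::arrange(again, .data$RSID), dplyr::arrange(base, .data$RSID))
})

test_that("precision-weighted pooling is associative on fixtures", {
  long <- simulate_long(100, 6, seed = 13)
  direct <- pool_fixed_effects(long)
  # pool studies 1-3 into a pseudo-study, then pool with 4-6
  first <- pool_fixed_effects(dplyr::filter(long, .data$study %in% paste0("s", 1:3)))
  rest <- dplyr::filter(long, .data$study %in% paste0("s", 4:6))
  merged <- dplyr::bind_rows(
    dplyr::transmute(first, study = "pool", RSID = .data$RSID,
                     EffectAllele = .data$EffectAllele,
                     OtherAllele = .data$OtherAllele,
                     B = .data$B_meta, SE = .data$SE_meta),
    dplyr::select(rest, "study", "RSID", "EffectAllele", "OtherAllele", "B", "SE"))
  merged$study <- factor(merged$study, levels = c("pool", paste0("s", 4:6)))
  two_stage <- pool_fixed_effects(merged)
  expect_equal(two_stage$B_meta, direct$B_meta, tolerance = 1e-10)
  expect_equal(two_stage$SE_meta, direct$SE_meta, tolerance = 1e-10)
})

test_that("meta_analyse over written datasets matches in-memory pooling", {
  spec <- test_spec()
  panel <- test_panel()
  sim <- make_sumstats(spec, panel, build = 38)
  base <- suppressMessages(harmonise_sumstats(sim$raw, panel))

  root <- withr::local_tempdir()
  set.seed(55)
  studies <- lapply(1:3, function(i) {
    tbl <- base$tbl
    tbl$B <- tbl$B + rnorm(nrow(tbl), 0, tbl$SE)
    write_output(tbl, file.path(root, paste0("study", i)), "hivestyle")
  })
  res <- meta_analyse(studies, min_k = 2)
  expect_s3_class(res, "meta_result")
  expect_equal(sort(unique(res$k)), 3L)
  expect_true(all(!is.na(res$CHR) & !is.na(res$POS_37) & !is.na(res$POS_38)))

  long <- dplyr::bind_rows(lapply(seq_along(studies), function(i) {
    x <- read_cleaned(studies[[i]])
    x$study <- paste0("study", i)
    x
  }))
  long$study <- factor(long$study, paste0("study", 1:3))
  want <- pool_fixed_effects(long, min_k = 2)
  got <- dplyr::arrange(tibble::as_tibble(res), .data$RSID, .data$EffectAllele)
  want <- dplyr::arrange(want, .data$RSID, .data$EffectAllele)
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(meta_analyse(studies[1]), "at least 2")
  g <- glance(res)
  expect_equal(g$n_studies, 3L)
  expect_equal(g$mean_k, 3)
})

test_that("meta output writes hivestyle and METAL-style files", {
  long <- simulate_long(20, 3, seed = 2)
  long$CHR <- "1"; long$POS_37 <- seq_len(nrow(long)); long$POS_38 <- long$POS_37 + 10L
  res <- structure(pool_fixed_effects(long), class = c("meta_result", "tbl_df",
                                                       "tbl", "data.frame"),
                   studies = paste0("s", 1:3))
  dir <- withr::local_tempdir()
  write_meta(res, file.path(dir, "pooled"), format = "hivestyle")
  back <- read_cleaned(file.path(dir, "pooled"))
  expect_equal(nrow(back), 20L)
  expect_equal(sort(back$B), sort(res$B_meta))

  metal <- file.path(dir, "pooled.metal.tsv")
  write_meta(res, metal, format = "metal")
  m <- readr::read_tsv(metal, show_col_types = FALSE)
  expect_equal(names(m), c("MarkerName", "Allele1", "Allele2", "Effect",
                           "StdErr", "P-value", "Direction", "HetISq",
                           "HetChiSq", "HetDf", "HetPVal"))
  expect_equal(nrow(m), 20L)
})

test_that("pooled errors are calibrated against simulated truth", {
  # k studies per variant with true effect beta ~ N(0, 0.01^2): the
  # standardized pooled error (B_meta - beta) / SE_meta should be ~N(0, 1)
  set.seed(17)
  n_var <- 4000L; k <- 10L
  beta <- rnorm(n_var, 0, 0.01)
  long <- tidyr::crossing(v = seq_len(n_var), study = seq_len(k)) |>
    dplyr::mutate(RSID = paste0("rs", .data$v),
                  EffectAllele = "A", OtherAllele = "G",
                  SE = runif(n_var * k, 0.05, 0.15),
                  B = beta[.data$v] + rnorm(n_var * k) * .data$SE,
                  study = factor(paste0("s", .data$study),
                                 paste0("s", seq_len(k))))
  res <- pool_fixed_effects(long)
  z <- (res$B_meta - beta[as.integer(sub("rs", "", res$RSID))]) / res$SE_meta
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(stats::var(z) - 1), 0.05)
})
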