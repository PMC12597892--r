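# Shared fixtures, built once per test run and cached in the session tempdir.

.fixture_cache <- new.env(parent = emptyenv())

# A small clean panel (no corruptions) reused across test files.
test_panel <- function() {
  if (is.null(.fixture_cache$panel)) {
    spec <- test_spec()
    dir <- file.path(tempdir(), "gwash-test-panel")
    .fixture_cache$panel <- make_reference(spec, dir, overwrite = TRUE)
  }
  .fixture_cache$panel
}

test_spec <- function(...) {
  fixture_spec(seed = 42L, n_variants = 400L, chromosomes = c("1", "2", "3"),
               fraction_indels = 0.1, fraction_multiallelic = 0.05,
               merged_rsid_count = 15L, n_samples = 1e5, ...)
}

# Raw sumstats table as a character tibble with canonical headers (skips the
# file layer when a test only needs the cleaning stages).
as_raw <- function(df) {
  dplyr::mutate(tibble::as_tibble(df),
                dplyr::across(dplyr::everything(), as.character))
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
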