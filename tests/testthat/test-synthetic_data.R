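test_that("the synthetic reference set has the documented composition", {
  cmf <- synthetic_cmf()
  expect_equal(nrow(cmf), 183L)
  expect_equal(sum(cmf$feature_type == "tRNA"), 20L)
  expect_equal(sum(cmf$feature_type == "rRNA"), 3L)
  expect_equal(sum(cmf$feature_type == "tmRNA"), 1L)
  expect_equal(sum(cmf$feature_type == "CDS"), 159L)
  expect_false(anyDuplicated(cmf$key) > 0)
  expect_equal(cmf$key, sort(cmf$key, method = "radix"))
  # records normalize back to their own keys
  rt <- normalize_key(tibble::tibble(feature_type = cmf$feature_type,
                                     gene_symbol = cmf$gene_symbol,
                                     product = cmf$product))
  expect_equal(rt$key, cmf$key)
})

test_that("decoy pool keys never collide with the reference set", {
  cmf <- synthetic_cmf()
  pool <- cmfscan:::synthetic_decoy_pool(200)
  pk <- unique(normalize_key(pool)$key)
  expect_length(intersect(pk, cmf$key), 0L)
  expect_equal(sum(pool$product == "hypothetical protein"), 20L)
})

test_that("single genomes respect forced completeness extremes and determinism", {
  cmf <- synthetic_cmf(30)
  g_full <- group_spec("G", 1, completeness_shape = c(1e6, 1e-3),
                       detectability = 1, contamination_rate = 0,
                       quality_noise_sd = 0)
  s <- sample_genome(g_full, cmf, genome_id = "g", seed = 5)
  expect_equal(adherence(s$presence), 100)
  expect_equal(nrow(s$annotation), 30L)

  g_none <- group_spec("G", 1, completeness_shape = c(1e-3, 1e6),
                       detectability = 1, contamination_rate = 5)
  s0 <- sample_genome(g_none, cmf, genome_id = "g", seed = 5)
  expect_equal(sum(s0$presence), 0L)
  expect_true(all(s0$annotation$product %in%
                    cmfscan:::synthetic_decoy_pool()$product))

  s1 <- sample_genome(g_full, cmf, genome_id = "g", seed = 7)
  s2 <- sample_genome(g_full, cmf, genome_id = "g", seed = 7)
  expect_identical(s1, s2)
})

test_that("cohorts are deterministic under the master seed", {
  spec <- cohort_spec(list(
    group_spec("A", 5, c(20, 2), detectability = 0.9, contamination_rate = 2),
    group_spec("B", 4, c(5, 3), detectability = 0.7)
  ), cmf_size = 40, seed = 123)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$annotations, c2$annotations)
  expect_identical(c1$quality, c2$quality)
  expect_equal(nrow(c1$quality), 9L)
  expect_true(all(c1$quality$completeness >= 0 & c1$quality$completeness <= 100))
  # empty cohort
  expect_warning(e <- generate_cohort(cohort_spec(list(
    group_spec("A", 0, c(2, 2), detectability = 0.5)), seed = 1)), "empty")
  expect_equal(nrow(e$quality), 0L)
})

test_that("group mean adherence converges to the analytic expectation", {
  n <- 500
  q <- 0.8
  shape <- c(30, 10)   # E[c] = 0.75
  spec <- cohort_spec(list(
    group_spec("A", n, shape, detectability = q, contamination_rate = 0)
  ), cmf_size = 60, seed = 99)
  co <- generate_cohort(spec)
  rep_ <- adherence_report(build_presence_matrix(co$cmf, co$annotations))
  expected <- 100 * (shape[1] / sum(shape)) * q
  # MC standard error of the mean adherence
  mc_se <- sd(rep_$adherence_percent) / sqrt(n)
  expect_lt(abs(mean(rep_$adherence_percent) - expected), 3 * mc_se + 0.05)
})

test_that("per-gene missingness recovers 1 - E[c] q_j", {
  n <- 400
  q <- c(rep(0.95, 20), rep(0.3, 10))
  shape <- c(40, 10)  # E[c] = 0.8
  spec <- cohort_spec(list(
    group_spec("A", n, shape, detectability = q, contamination_rate = 0)
  ), cmf_size = 30, seed = 7)
  co <- generate_cohort(spec)
  mp <- missing_profile(co$presence_truth, "A")
  expected_missing <- 100 * (1 - 0.8 * q)
  se <- 100 * sqrt(pmax(expected_missing / 100 * (1 - expected_missing / 100), 1e-4) / n)
  expect_true(all(abs(mp$pct_missing - expected_missing) < 4 * se + 2))
})

test_that("lower quality noise strengthens the completeness-adherence correlation", {
  taus <- vapply(c(15, 6, 0.5), function(noise) {
    spec <- cohort_spec(list(
      group_spec("A", 300, c(13.75, 4.58), detectability = 0.9,
                 contamination_rate = 0, quality_noise_sd = noise)
    ), cmf_size = 120, seed = 11)
    co <- generate_cohort(spec)
    rep_ <- adherence_report(build_presence_matrix(co$cmf, co$annotations),
                             co$quality)
    kendall_tau_b(rep_, adherence_percent, completeness)$statistic
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("written GFF3 cohorts re-read to the exact truth matrix", {
  dir <- tempfile()
  spec <- cohort_spec(list(
    group_spec("NCBI", 3, c(60, 3), detectability = 0.95, contamination_rate = 2),
    group_spec("UMGS", 3, c(10, 4), detectability = 0.7, contamination_rate = 3)
  ), cmf_size = 50, seed = 42)
  co <- generate_cohort(spec, dir = dir)
  files <- list.files(file.path(dir, "gff"), full.names = TRUE)
  expect_length(files, 6L)
  groups <- readr::read_tsv(file.path(dir, "groups.tsv"), show_col_types = FALSE)
  anns <- dplyr::bind_rows(lapply(seq_len(nrow(groups)), function(i) {
    suppressWarnings(read_annotation(
      file.path(dir, "gff", paste0(groups$genome_id[i], ".gff")),
      groups$genome_id[i], groups$source_group[i]))
  }))
  mat <- build_presence_matrix(co$cmf, anns)
  expect_identical(mat[order(mat$genome_id), ],
                   co$presence_truth[order(co$presence_truth$genome_id), ])
  q <- read_quality_table(file.path(dir, "checkm.tsv"))
  expect_equal(q$completeness, co$quality$completeness)
})
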