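test_that("sample bookkeeping: every layer carries every configured sample", {
  cfg <- cohort_config(n_per_group = 10L, n_normal = 0L, seed = 7L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$annotations), 80L)  # 4 subtypes x 2 tumor types x 10
  ids <- co$annotations$sample_id
  expect_setequal(colnames(co$expression), ids)
  expect_setequal(colnames(co$betas), ids)
  expect_setequal(colnames(co$detection_p), ids)
  expect_setequal(unique(co$segments$sample), ids)
})

test_that("zero expression noise reproduces the centroids exactly", {
  cfg <- cohort_config(n_per_group = 2L, n_normal = 0L, centroid_sd = 0,
                       dcis_attenuation = 1, seed = 3L)
  co <- generate_cohort(cfg)
  cen_genes <- rownames(co$centroids)
  for (i in seq_len(nrow(co$annotations))) {
    s <- co$annotations$sample_id[i]
    expect_equal(unname(co$expression[cen_genes, s]),
                 unname(co$centroids[, co$annotations$subtype[i]]))
  }
})

test_that("beta values and detection p-values respect their ranges", {
  for (model in c("truncnorm", "beta")) {
    co <- generate_cohort(small_cohort_config(seed = 11L, beta_model = model,
                                              lres_delta = 0.6))
    expect_true(all(co$betas >= 0 & co$betas <= 1, na.rm = TRUE))
    expect_true(all(co$detection_p >= 0 & co$detection_p <= 1))
  }
})

test_that("fixed seed gives identical cohorts; different seeds differ", {
  a <- generate_cohort(small_cohort_config(seed = 5L))
  b <- generate_cohort(small_cohort_config(seed = 5L))
  expect_identical(a$expression, b$expression)
  expect_identical(a$betas, b$betas)
  expect_identical(a$segments, b$segments)
  c2 <- generate_cohort(small_cohort_config(seed = 6L))
  expect_false(identical(a$expression, c2$expression))
})

test_that("written cohort round-trips and manifests hash deterministically", {
  co <- generate_cohort(small_cohort_config(seed = 2L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_cohort(co, d1)
  m2 <- write_cohort(generate_cohort(small_cohort_config(seed = 2L)), d2)
  expect_identical(m1$files, m2$files)
  back <- read_cohort(d1)
  expect_equal(back$expression, co$expression, tolerance = 1e-12)
  expect_equal(back$betas, co$betas, tolerance = 1e-12)
  # reader returns segments in canonical sort order
  expect_equal(back$segments, validate_segments(co$segments))
  expect_equal(back$cpg_positions$start, co$cpg_positions$start)
  # manifests from different seeds must differ
  for (s in 1:5) {
    da <- withr::local_tempdir(); db <- withr::local_tempdir()
    ma <- write_cohort(generate_cohort(small_cohort_config(seed = s)), da)
    mb <- write_cohort(generate_cohort(small_cohort_config(seed = s + 100L)),
                       db)
    expect_false(identical(ma$files, mb$files))
  }
})

test_that("inconsistent configurations fail naming the offending field", {
  expect_error(cohort_config(n_window_cpgs = 500L, n_cpgs = 100L),
               "n_window_cpgs")
  expect_error(cohort_config(lres_delta = 1.5), "lres_delta")
  expect_error(cohort_config(window_span_bp = 1e9), "window_span_bp")
  expect_error(cohort_config(n_genes = 30L), "n_genes")
  expect_error(cohort_config(missing_rate = -0.1), "missing_rate")
})

test_that("segment profiles tile the genome and realize target fractions", {
  co <- generate_cohort(small_cohort_config(seed = 9L))
  seg <- validate_segments(co$segments)   # non-overlap enforced here
  chrom_len <- floor(co$config$genome_length_bp /
                       length(co$config$chromosomes))
  for (s in unique(seg$sample)) {
    ss <- seg[seg$sample == s, ]
    covered <- sum(ss$end - ss$start + 1)
    expect_equal(covered, chrom_len * length(co$config$chromosomes))
  }
  gap <- abs(co$truth$realized_fractions - co$truth$target_fractions)
  expect_true(all(gap <= 0.01))
})

test_that("a zero window shift leaves tumor types exchangeable in the window", {
  # with lres_delta = 0 the rank test on per-sample window means should
  # reject only at the nominal rate across seeds
  rejections <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(small_cohort_config(seed = 1000L + s,
                                              lres_delta = 0))
    win_cpgs <- co$cpg_positions$name[
      co$cpg_positions$chrom == co$window$chrom &
        co$cpg_positions$start >= co$window$start &
        co$cpg_positions$start <= co$window$end]
    means <- colMeans(co$betas[win_cpgs, , drop = FALSE], na.rm = TRUE)
    ann <- co$annotations
    basal <- ann$subtype %in% "Basal"
    p <- mann_whitney(means[ann$sample_id[basal & ann$tumor_type == "DCIS"]],
                      means[ann$sample_id[basal & ann$tumor_type == "IBC"]])$p
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, ceiling(n_seeds * 0.05 + 2 * sqrt(n_seeds * 0.0475)))
})

test_that("planted effects are recorded in the truth record", {
  co <- generate_cohort(small_cohort_config(seed = 4L))
  expect_length(co$truth$lres_samples, 10L)
  expect_true(all(grepl("^Basal_IBC", co$truth$lres_samples)))
  expect_length(co$truth$diff_genes, 5L)
  expect_true(all(co$truth$diff_genes %in% co$gene_models$name))
  expect_setequal(names(co$truth$realized_fractions),
                  co$annotations$sample_id)
})
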