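test_that("Fisher exact 2x2 p-values match hypergeometric enumeration", {
  a <- rep(c("x", "x", "y", "y"), 1)
  b <- c("g1", "g1", "g2", "g2")
  # table [[2,0],[0,2]]: p = 1/3
  res <- fisher_exact_distribution(a, b)
  expect_equal(res$p_value, 1 / 3)
  # table [[3,0],[0,3]]: p = 2/20 = 0.1
  a6 <- rep(c("x", "y"), each = 3)
  b6 <- rep(c("g1", "g2"), each = 3)
  expect_equal(fisher_exact_distribution(a6, b6)$p_value, 0.1)
  # identical row distributions: p = 1
  a8 <- rep(c("x", "y"), 4)
  b8 <- rep(c("g1", "g2"), each = 4)
  expect_equal(fisher_exact_distribution(a8, b8)$p_value, 1)
  expect_error(fisher_exact_distribution(rep("x", 4), b8[1:4]),
               "2 categories")
})

test_that("Fisher 2x2 agrees with full enumeration for all small tables", {
  for (n in 4:12) {
    set.seed(n)
    for (rep in 1:8) {
      a <- sample(c("x", "y"), n, replace = TRUE)
      b <- sample(c("u", "v"), n, replace = TRUE)
      tab <- table(a, b)
      if (nrow(tab) < 2L || ncol(tab) < 2L) next
      res <- fisher_exact_distribution(a, b)
      expect_equal(res$p_value, oracle_fisher_2x2(tab), tolerance = 1e-9)
    }
  }
})

test_that("2xK tables use the exact test at small n, Monte-Carlo at large", {
  set.seed(10)
  a <- sample(c("A", "B", "C", "D"), 60, replace = TRUE)
  b <- sample(c("DCIS", "IBC"), 60, replace = TRUE)
  res <- fisher_exact_distribution(a, b)
  expect_equal(res$method, "exact")
  a2 <- sample(c("A", "B", "C", "D"), 400, replace = TRUE)
  b2 <- sample(c("DCIS", "IBC"), 400, replace = TRUE)
  res2 <- fisher_exact_distribution(a2, b2, seed = 4L)
  expect_match(res2$method, "monte-carlo")
  # Monte-Carlo branch is seed-stable
  res3 <- fisher_exact_distribution(a2, b2, seed = 4L)
  expect_equal(res2$p_value, res3$p_value)
})

test_that("stratified group tests compare tumor types per subtype", {
  summ <- data.frame(
    sample_id = paste0("s", 1:8),
    subtype = rep("Basal", 8),
    tumor_type = rep(c("DCIS", "IBC"), each = 4)[c(1, 2, 5, 6, 3, 4, 7, 8)],
    stringsAsFactors = FALSE)
  summ$tumor_type <- rep(c("DCIS", "IBC"), each = 4)
  summ$gii <- c(0.1, 0.2, NA, NA, 0.5, 0.6, NA, NA)
  res <- stratified_group_tests(summ, "gii")
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 1 / 3)   # 2 of the C(4,2)=6 assignments
  expect_equal(res$direction, "IBC")
  # identical distributions: direction none
  summ$flat <- rep(c(1, 2, 3, 4), 2)
  res2 <- stratified_group_tests(summ, "flat")
  expect_equal(res2$direction, "none")
  expect_equal(res2$p_value, 1)
  # undersized cells are skipped with a notice
  summ$thin <- c(0.5, rep(NA, 3), 1, 2, 3, 4)
  expect_message(expect_error(stratified_group_tests(summ, "thin"),
                              "enough samples"), "skipping")
  expect_error(stratified_group_tests(summ, "nope"), "unknown feature")
})

test_that("group tests are rank-based: monotone transforms change nothing", {
  set.seed(44)
  summ <- data.frame(sample_id = paste0("s", 1:30),
                     subtype = rep(c("Basal", "LumA"), 15),
                     tumor_type = rep(c("DCIS", "IBC"), each = 15),
                     f = rnorm(30))
  base <- stratified_group_tests(summ, "f")
  summ2 <- summ
  summ2$f <- exp(summ$f)
  trans <- stratified_group_tests(summ2, "f")
  expect_equal(trans$p_value, base$p_value)
  expect_equal(trans$u_statistic, base$u_statistic)
  # and invariant to sample order
  summ3 <- summ[sample(30), ]
  shuffled <- stratified_group_tests(summ3, "f")
  expect_equal(shuffled[order(shuffled$subtype), c("u_statistic", "p_value")],
               base[order(base$subtype), c("u_statistic", "p_value")],
               ignore_attr = TRUE)
})

test_that("sample summaries join layers and sort by subtype then correlation", {
  calls <- data.frame(sample_id = c("a", "b", "c", "d"),
                      subtype = c("LumA", "Basal", "Basal", "Basal"),
                      second_subtype = "LumB",
                      cor_Basal = c(0.1, 0.5, 0.8, 0.65),
                      cor_LumA = c(0.7, 0.2, 0.1, 0.3),
                      stringsAsFactors = FALSE)
  ann <- data.frame(sample_id = c("a", "b", "c", "d"),
                    tumor_type = c("IBC", "DCIS", "IBC", "IBC"),
                    purity = c(0.5, 0.6, 0.7, 0.8))
  wsc <- data.frame(sample_id = c("a", "b", "c"), mean_z = c(1, 2, 3),
                    n_cpgs = 5)
  expect_warning(
    summ <- build_sample_summary(calls, annotations = ann,
                                 window_scores = wsc),
    "window-score")
  expect_equal(summ$sample_id, c("c", "d", "b", "a"))
  expect_true(is.na(summ$window_mean_z[summ$sample_id == "d"]))
  # duplicate ids in a layer are an error
  expect_error(build_sample_summary(calls, annotations = rbind(ann, ann[1, ])),
               "duplicate")
})

test_that("the pipeline runs end to end, deterministically, on the demo config", {
  cfg_path <- system.file("extdata", "demo_config.yaml",
                          package = "stratomics")
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressWarnings(suppressMessages({
    run_pipeline(cfg_path, outdir = out1)
    run_pipeline(cfg_path, outdir = out2)
  }))
  rep1 <- jsonlite::read_json(file.path(out1, "report.json"),
                              simplifyVector = TRUE)
  expect_true(all(unlist(rep1$stages) == "ok"))
  tsvs <- grep("\\.tsv$", list.files(out1), value = TRUE)
  expect_true(length(tsvs) >= 6)
  for (f in tsvs) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     info = f)
  }
})

test_that("an expression-only configuration skips downstream layers", {
  co <- generate_cohort(small_cohort_config(seed = 13L))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  cfg <- list(seed = 13L,
              inputs = list(expression = file.path(d, "expression.tsv"),
                            centroids = file.path(d, "centroids.tsv"),
                            annotations = file.path(d, "samples.tsv")))
  out <- withr::local_tempdir()
  suppressWarnings(suppressMessages(run_pipeline(cfg, outdir = out)))
  rep <- jsonlite::read_json(file.path(out, "report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$stages$copy_number, "skipped")
  expect_equal(rep$stages$methylation, "skipped")
  expect_equal(rep$stages$subtyping, "ok")
  expect_true(file.exists(file.path(out, "subtype_calls.tsv")))
})
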