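beta_mat <- function(values, cpgs, samples) {
  matrix(values, nrow = length(cpgs), dimnames = list(cpgs, samples))
}

test_that("detection-p masking is strictly greater than the threshold", {
  b <- beta_mat(c(0.5, 0.5, 0.5), "cg1", paste0("s", 1:3))
  p <- beta_mat(c(0.06, 0.05, 0.00), "cg1", paste0("s", 1:3))
  masked <- qc_mask(b, p)
  expect_true(is.na(masked["cg1", "s1"]))   # 0.06 masked
  expect_equal(masked["cg1", "s2"], 0.5)    # 0.05 kept (boundary)
  expect_equal(masked["cg1", "s3"], 0.5)
  expect_equal(unname(attr(masked, "masked")["n"]), 1)
  # all-pass p-values leave the matrix unchanged
  p0 <- beta_mat(rep(0, 3), "cg1", paste0("s", 1:3))
  expect_equal(qc_mask(b, p0), b, ignore_attr = TRUE)
})

test_that("CpG removal uses a strict missing-fraction threshold", {
  b10 <- matrix(0.5, 2, 10, dimnames = list(c("cgA", "cgB"), paste0("s", 1:10)))
  b10["cgA", 1:3] <- NA  # 30% missing: dropped
  kept <- qc_filter_cpgs(b10)
  expect_equal(rownames(kept), "cgB")
  expect_equal(attr(kept, "dropped"), "cgA")
  b8 <- matrix(0.5, 1, 8, dimnames = list("cgC", paste0("s", 1:8)))
  b8[1, 1:2] <- NA       # exactly 25%: kept (strict >)
  expect_equal(rownames(qc_filter_cpgs(b8)), "cgC")
  expect_error(qc_filter_cpgs(beta_mat(rep(NA_real_, 3), "cg1",
                                       paste0("s", 1:3))), "all CpGs")
})

test_that("kNN imputation averages the nearest rows at the missing sample", {
  # 5 x 4 toy matrix, one missing entry, k = 2: hand-computed expectation
  b <- rbind(
    cg1 = c(0.10, 0.20, NA,   0.40),
    cg2 = c(0.12, 0.22, 0.30, 0.42),  # distance to cg1 on shared: tiny
    cg3 = c(0.11, 0.19, 0.50, 0.41),  # next nearest
    cg4 = c(0.90, 0.80, 0.70, 0.60),  # far
    cg5 = c(0.85, 0.95, 0.75, 0.65))  # far
  colnames(b) <- paste0("s", 1:4)
  out <- knn_impute(b, k = 2)
  # nearest two rows to cg1 over s1, s2, s4 are cg2 and cg3
  expect_equal(out["cg1", "s3"], mean(c(0.30, 0.50)))
  expect_equal(out[-1, ], b[-1, ])    # observed entries untouched
  # no missing entries: identity
  expect_equal(knn_impute(b[-1, ]), b[-1, ])
  # constant neighborhood imputes the constant
  bb <- rbind(cg1 = c(0.5, NA), cg2 = c(0.5, 0.5), cg3 = c(0.5, 0.5),
              cg4 = c(0.5, 0.5))
  colnames(bb) <- c("s1", "s2")
  expect_equal(knn_impute(bb, k = 3)["cg1", "s2"], 0.5)
  # entirely missing row is an error naming the CpG
  bad <- rbind(cgX = c(NA_real_, NA_real_), cgY = c(0.1, 0.2))
  colnames(bad) <- c("s1", "s2")
  expect_error(knn_impute(bad), "cgX")
  # imputed values stay in [0, 1]
  set.seed(6)
  br <- matrix(runif(200), 20, dimnames = list(paste0("cg", 1:20),
                                               paste0("s", 1:10)))
  br[sample(200, 15)] <- NA
  imp <- knn_impute(br)
  expect_false(anyNA(imp))
  expect_true(all(imp >= 0 & imp <= 1))
})

test_that("masking then filtering then imputing preserves observed values", {
  set.seed(18)
  for (i in 1:10) {
    b <- matrix(runif(120), 12, dimnames = list(paste0("cg", 1:12),
                                                paste0("s", 1:10)))
    p <- matrix(runif(120, 0, 0.06), 12, dimnames = dimnames(b))
    masked <- qc_mask(b, p)
    kept <- qc_filter_cpgs(masked)
    imp <- knn_impute(kept)
    obs <- !is.na(kept)
    expect_equal(imp[obs], kept[obs])
    expect_false(anyNA(imp))
    # when nothing is masked the pipeline is the identity
    imp0 <- knn_impute(qc_filter_cpgs(qc_mask(b, p * 0)))
    expect_equal(imp0, b, ignore_attr = TRUE)
  }
})

test_that("single-CpG genes profile as the centered beta", {
  b <- beta_mat(c(0.2, 0.5, 0.8), "cg1", paste0("s", 1:3))
  pos <- data.frame(chrom = "c1", start = 500, end = 500, name = "cg1")
  gm <- data.frame(chrom = "c1", start = 400, end = 600, name = "gA")
  pr <- gene_methylation_profile(b, pos, gm, flank_bp = 0)
  expect_equal(unname(pr$profile["gA", ]), c(-0.3, 0, 0.3))
  expect_equal(pr$info$n_cpgs, 1L)
})

test_that("profiles equal eigen-decomposition PC1 scores with fixed sign", {
  set.seed(33)
  for (i in 1:40) {
    n_cpg <- sample(2:8, 1)
    n_smp <- sample(6:15, 1)
    b <- matrix(runif(n_cpg * n_smp), n_cpg,
                dimnames = list(paste0("cg", seq_len(n_cpg)),
                                paste0("s", seq_len(n_smp))))
    pos <- data.frame(chrom = "c1", start = seq_len(n_cpg) * 10,
                      end = seq_len(n_cpg) * 10,
                      name = rownames(b))
    gm <- data.frame(chrom = "c1", start = 1, end = 1000, name = "g")
    pr <- gene_methylation_profile(b, pos, gm, flank_bp = 0)
    prof <- pr$profile["g", ]
    # oracle: eigenvector of the covariance of the centered sample x CpG
    # matrix, scores via projection
    m <- t(b - rowMeans(b))
    e1 <- eigen(stats::cov(m), symmetric = TRUE)$vectors[, 1]
    oracle <- as.numeric(m %*% e1)
    expect_equal(abs(unname(prof)), abs(oracle), tolerance = 1e-8)
    # orientation rule: non-negative correlation with per-sample mean beta
    expect_gte(sum(prof * (colMeans(b) - mean(colMeans(b)))), 0)
  }
})

test_that("hypermethylated samples land at the top after sign fixing", {
  # two perfectly correlated CpGs: profile is proportional to the shared
  # pattern, and the most methylated sample scores highest
  b <- rbind(cg1 = c(0.1, 0.5, 0.9), cg2 = c(0.2, 0.6, 1.0))
  colnames(b) <- paste0("s", 1:3)
  pos <- data.frame(chrom = "c1", start = c(10, 20), end = c(10, 20),
                    name = c("cg1", "cg2"))
  gm <- data.frame(chrom = "c1", start = 1, end = 100, name = "g")
  pr <- gene_methylation_profile(b, pos, gm, flank_bp = 0)
  prof <- pr$profile["g", ]
  expect_equal(unname(which.max(prof)), 3L)
  expect_equal(stats::cor(prof, b["cg1", ]), 1, tolerance = 1e-10)
  # zero-variance neighbourhood: zero profile plus warning
  bz <- rbind(cg1 = rep(0.4, 3), cg2 = rep(0.7, 3))
  colnames(bz) <- paste0("s", 1:3)
  expect_warning(prz <- gene_methylation_profile(bz, pos, gm, flank_bp = 0),
                 "zero-variance")
  expect_equal(unname(prz$profile["g", ]), rep(0, 3))
})

test_that("Mann-Whitney engine is exact for small untied samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 0.1)   # 2/20 of the C(6,3) assignments
  expect_equal(mw$method, "exact")
  # identical groups: p = 1
  mw1 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw1$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "observations")
})

test_that("differential methylation applies the joint FDR + effect filter", {
  set.seed(55)
  n_per <- 12
  samples <- paste0("s", seq_len(2 * n_per))
  tumor <- rep(c("DCIS", "IBC"), each = n_per)
  subtype <- rep("Basal", 2 * n_per)
  prof <- matrix(rnorm(40 * 2 * n_per), 40,
                 dimnames = list(paste0("g", 1:40), samples))
  shifted <- paste0("g", 1:6)
  prof[shifted, tumor == "IBC"] <- prof[shifted, tumor == "IBC"] + 3
  res <- differential_methylation(prof, tumor, subtype)
  expect_true(all(res$significant[res$gene_id %in% shifted]))
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  expect_equal(res$effect_size,
               abs(apply(prof, 1, function(v) {
                 median(v[tumor == "DCIS"]) - median(v[tumor == "IBC"])
               })), ignore_attr = TRUE)
  # strict top-20% filter bounds the number of passing genes
  expect_lte(sum(res$significant), ceiling(0.2 * nrow(prof)))
  # undersized subtypes are skipped with a notice
  subtype2 <- c(rep("Basal", 2 * n_per - 1), "LumB")
  expect_message(differential_methylation(prof, tumor, subtype2), "LumB")
})

test_that("BH q-values follow the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, method = "BH"), rep(0.04, 4))
  set.seed(2)
  for (i in 1:50) {
    pv <- runif(sample(3:30, 1))
    expect_equal(stats::p.adjust(pv, method = "BH"), oracle_bh(pv))
  }
})

test_that("window mean-Z standardizes across the pooled samples", {
  b <- beta_mat(c(0.2, 0.8), "cg1", c("s1", "s2"))
  pos <- data.frame(chrom = "c5", start = 100, end = 100, name = "cg1")
  win <- list(chrom = "c5", start = 1, end = 1000)
  sc <- window_mean_z(b, pos, win)
  expect_equal(sc$mean_z, c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-10)
  expect_equal(sc$n_cpgs, c(1L, 1L))
  # a sample sitting at the per-CpG cohort mean scores zero
  b3 <- rbind(cg1 = c(0.1, 0.3, 0.2), cg2 = c(0.5, 0.7, 0.6))
  colnames(b3) <- paste0("s", 1:3)
  pos3 <- data.frame(chrom = "c5", start = c(100, 200), end = c(100, 200),
                     name = c("cg1", "cg2"))
  sc3 <- window_mean_z(b3, pos3, win)
  expect_equal(sc3$mean_z[3], 0, tolerance = 1e-12)
  # adding a constant shifts nothing
  sc3b <- window_mean_z(pmin(b3 + 0.1, 1), pos3, win)
  expect_equal(sc3b$mean_z, sc3$mean_z, tolerance = 1e-12)
  expect_error(window_mean_z(b3, pos3, list(chrom = "c9", start = 1,
                                            end = 10)), "no CpGs")
})

test_that("window score vs purity uses Spearman with degenerate guards", {
  sc <- data.frame(sample_id = paste0("s", 1:3), mean_z = c(1, 2, 3))
  expect_error(window_purity_association(sc, c(s1 = 0.5, s2 = 0.5,
                                               s3 = 0.5)), "constant input")
  res <- window_purity_association(sc, c(s1 = 0.1, s2 = 0.5, s3 = 0.9))
  expect_equal(res$rho, 1)
  res2 <- window_purity_association(sc, c(s1 = 0.9, s2 = 0.1, s3 = 0.5))
  expect_equal(res2$rho, -0.5)
  expect_error(window_purity_association(sc[1:2, ], c(s1 = 1, s2 = 2)),
               ">= 3 samples")
})
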