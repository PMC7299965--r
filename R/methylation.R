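# Methylation beta-value QC, imputation, per-gene first-principal-component
# profiles, differential methylation with a joint FDR + effect-size filter,
# and windowed mean-Z scoring for long-range epigenetic silencing (LRES).

#' Mask unreliable beta values by detection p-value
#'
#' Beta values whose detection p-value is strictly above `p_threshold`
#' (default 0.05) are set to missing. The count and fraction of newly masked
#' entries are attached as attribute `"masked"`.
#'
#' @param betas CpG x sample matrix of beta values in \[0, 1\] (may contain
#'   NA).
#' @param detection_p CpG x sample matrix of detection p-values, same shape.
#' @param p_threshold Strict masking threshold; default 0.05.
#' @return The beta matrix with failing entries set to NA.
#' @export
qc_mask <- function(betas, detection_p, p_threshold = 0.05) {
  stopifnot(is.matrix(betas), is.matrix(detection_p),
            all(dim(betas) == dim(detection_p)))
  fail <- !is.na(detection_p) & detection_p > p_threshold
  n_new <- sum(fail & !is.na(betas))
  betas[fail] <- NA_real_
  attr(betas, "masked") <- c(n = n_new, fraction = n_new / length(betas))
  betas
}

#' Remove CpGs with too many failed beta values
#'
#' Drops CpG rows whose missing fraction is strictly above `fail_fraction`
#' (default 0.25). The ids of dropped CpGs are attached as attribute
#' `"dropped"`.
#'
#' @param betas Masked CpG x sample beta matrix.
#' @param fail_fraction Strict upper bound on the tolerated per-CpG missing
#'   fraction.
#' @return Filtered beta matrix.
#' @export
qc_filter_cpgs <- function(betas, fail_fraction = 0.25) {
  stopifnot(is.matrix(betas))
  frac <- rowMeans(is.na(betas))
  drop <- frac > fail_fraction
  if (all(drop)) stop("all CpGs failed the missing-fraction filter")
  out <- betas[!drop, , drop = FALSE]
  attr(out, "dropped") <- rownames(betas)[drop]
  out
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' Each missing entry is replaced by the mean, over the k CpG rows nearest
#' to its row, of those rows' values in the same sample. Row distance is the
#' mean squared difference over jointly observed samples (a Euclidean
#' distance rescaled by the fraction of samples observed in both rows).
#' Neighbours missing the target sample are skipped; if no neighbour
#' provides a value the row mean is used. Imputed values are clipped to
#' \[0, 1\].
#'
#' @param betas CpG x sample beta matrix; every row must have at least one
#'   observed value.
#' @param k Number of neighbouring CpG rows; default 10.
#' @return Complete beta matrix (no missing values).
#' @export
knn_impute <- function(betas, k = 10L) {
  stopifnot(is.matrix(betas), k >= 1L)
  if (!anyNA(betas)) return(betas)
  all_na <- rowSums(!is.na(betas)) == 0L
  if (any(all_na)) {
    stop("CpG row(s) entirely missing: ",
         paste(rownames(betas)[all_na], collapse = ", "))
  }
  obs <- !is.na(betas)
  need <- which(rowSums(!obs) > 0L)
  x <- betas
  for (i in need) {
    xi <- betas[i, ]
    # mean squared difference over jointly observed samples, per row
    diff2 <- sweep(betas, 2L, xi)^2
    shared <- obs & matrix(obs[i, ], nrow(betas), ncol(betas), byrow = TRUE)
    n_shared <- rowSums(shared)
    d <- rowSums(ifelse(shared, diff2, 0)) / n_shared
    d[i] <- Inf
    d[n_shared == 0L] <- Inf
    ord <- order(d)
    nb <- ord[seq_len(min(k, sum(is.finite(d[ord]))))]
    for (j in which(!obs[i, ])) {
      vals <- betas[nb, j]
      vals <- vals[!is.na(vals)]
      x[i, j] <- if (length(vals)) mean(vals) else mean(xi, na.rm = TRUE)
    }
  }
  pmin(pmax(x, 0), 1)
}

#' Per-gene methylation profiles via the first principal component
#'
#' For each gene, the CpGs lying within the gene body or `flank_bp` up- or
#' downstream are collected; each CpG is centered across samples (covariance
#' PCA — beta values share a scale, so no per-CpG standardisation) and the
#' per-sample score on the first principal component is the gene's
#' methylation profile. The PC sign is fixed so the profile correlates
#' non-negatively with the per-sample mean beta over the gene's CpGs, making
#' "more methylated" read as "higher profile". Single-CpG genes get that
#' CpG's centered beta; genes with no CpGs are absent from the output;
#' zero-variance neighbourhoods yield all-zero profiles with a warning.
#'
#' @param betas Imputed CpG x sample beta matrix (no missing values).
#' @param cpg_positions `data.frame` with chrom, start, end, name per CpG
#'   (1-based inclusive, e.g. from [read_bed()]); `name` must match beta row
#'   ids.
#' @param gene_models `data.frame` with chrom, start, end, name per gene.
#' @param flank_bp Flank added on both sides of the gene body; default
#'   50000.
#' @return List with `profile` (gene x sample matrix of PC1 scores, each row
#'   mean-zero) and `info` (`data.frame`: gene_id, n_cpgs, sign).
#' @export
gene_methylation_profile <- function(betas, cpg_positions, gene_models,
                                     flank_bp = 50000) {
  stopifnot(is.matrix(betas))
  if (anyNA(betas)) stop("impute the beta matrix before profiling")
  pos <- cpg_positions[cpg_positions$name %in% rownames(betas), , drop = FALSE]
  profiles <- list()
  info <- list()
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    hit <- pos$chrom == g$chrom &
      pos$start >= (g$start - flank_bp) & pos$start <= (g$end + flank_bp)
    ids <- pos$name[hit]
    if (length(ids) == 0L) next
    sub <- betas[ids, , drop = FALSE]            # CpGs x samples
    centered <- sub - rowMeans(sub)
    if (length(ids) == 1L) {
      prof <- as.numeric(centered)
      sgn <- 1L
    } else {
      m <- t(centered)                           # samples x CpGs, col-centered
      if (all(abs(m) < .Machine$double.eps * 100)) {
        warning("zero-variance CpG neighbourhood for gene ", g$name)
        prof <- numeric(ncol(sub))
        sgn <- 1L
      } else {
        sv <- svd(m, nu = 0L, nv = 1L)
        prof <- as.numeric(m %*% sv$v[, 1L])
        mean_beta <- colMeans(sub)
        cs <- sum(prof * (mean_beta - mean(mean_beta)))
        sgn <- if (cs < 0) -1L else 1L
        prof <- prof * sgn
      }
    }
    profiles[[g$name]] <- prof
    info[[g$name]] <- data.frame(gene_id = g$name, n_cpgs = length(ids),
                                 sign = sgn, stringsAsFactors = FALSE)
  }
  if (!length(profiles)) stop("no gene had any CpG in its neighbourhood")
  mat <- do.call(rbind, profiles)
  colnames(mat) <- colnames(betas)
  info <- do.call(rbind, info)
  rownames(info) <- NULL
  list(profile = mat, info = info)
}

#' Two-sided Mann-Whitney U test
#'
#' The rank-test engine shared by differential methylation and the
#' stratified group comparisons: exact null distribution when the combined
#' sample size is at most `exact_max` and there are no ties, otherwise the
#' normal approximation with continuity and tie correction.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max Largest combined n for which the exact distribution is
#'   used; default 20.
#' @return List with `u` (U statistic for `x`), `p` (two-sided p-value) and
#'   `method` ("exact" or "normal").
#' @export
mann_whitney <- function(x, y, exact_max = 20L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) stop("both groups need observations")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(u = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal")
}

#' Differential methylation of gene profiles, per subtype
#'
#' Within each subtype, every gene's profile values are compared between
#' DCIS and IBC with a two-sided Mann-Whitney U test; p-values are
#' Benjamini-Hochberg adjusted across genes within the subtype; the effect
#' size is the absolute difference of group medians. A gene is significant
#' when its q-value is below `fdr_alpha` and its effect size is strictly
#' above the (1 - `effect_top_fraction`) empirical quantile of effect sizes
#' within that subtype (a joint filter that targets the biologically
#' relevant differences). Subtypes where either tumor type has fewer than
#' two samples are skipped with a message.
#'
#' @param profiles Gene x sample matrix of methylation profiles.
#' @param tumor_type Character vector ("DCIS"/"IBC"), named by sample or in
#'   column order.
#' @param subtype Character vector of subtype labels, same convention.
#' @param fdr_alpha FDR threshold; default 0.05.
#' @param effect_top_fraction Fraction defining the top effect sizes;
#'   default 0.20.
#' @return `data.frame` with gene_id, subtype, u_statistic, p_value, fdr_q,
#'   effect_size, significant.
#' @export
differential_methylation <- function(profiles, tumor_type, subtype,
                                     fdr_alpha = 0.05,
                                     effect_top_fraction = 0.20) {
  stopifnot(is.matrix(profiles))
  tumor_type <- align_labels(tumor_type, colnames(profiles), "tumor_type")
  subtype <- align_labels(subtype, colnames(profiles), "subtype")
  out <- list()
  for (st in unique(subtype[!is.na(subtype)])) {
    in_st <- !is.na(subtype) & subtype == st
    a <- in_st & tumor_type == "DCIS"
    b <- in_st & tumor_type == "IBC"
    if (sum(a) < 2L || sum(b) < 2L) {
      message("subtype ", st, " skipped: fewer than 2 samples per tumor type")
      next
    }
    res <- apply(profiles, 1L, function(v) {
      mw <- mann_whitney(v[a], v[b])
      c(u = mw$u, p = mw$p,
        eff = abs(stats::median(v[a]) - stats::median(v[b])))
    })
    q <- stats::p.adjust(res["p", ], method = "BH")
    eff <- res["eff", ]
    cut <- stats::quantile(eff, probs = 1 - effect_top_fraction, names = FALSE)
    out[[st]] <- data.frame(gene_id = rownames(profiles), subtype = st,
                            u_statistic = res["u", ], p_value = res["p", ],
                            fdr_q = q, effect_size = eff,
                            significant = q < fdr_alpha & eff > cut,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no subtype had enough samples in both tumor types")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Windowed mean-Z methylation score
#'
#' Scores each sample for coordinated (hyper)methylation across a genomic
#' window — the long-range epigenetic silencing readout. Every CpG in the
#' window is standardised across all supplied samples (tumors and normals
#' pooled, sample sd); a sample's score is the mean Z over the window's
#' CpGs. Constant CpGs contribute zero with a warning.
#'
#' @param betas Imputed CpG x sample beta matrix.
#' @param cpg_positions CpG annotation `data.frame` (chrom, start, end,
#'   name; 1-based inclusive).
#' @param window List or one-row `data.frame` with chrom, start, end.
#' @return `data.frame` with sample_id, mean_z, n_cpgs, and window
#'   coordinates.
#' @export
window_mean_z <- function(betas, cpg_positions, window) {
  stopifnot(is.matrix(betas))
  if (anyNA(betas)) stop("impute the beta matrix before window scoring")
  pos <- cpg_positions[cpg_positions$name %in% rownames(betas), , drop = FALSE]
  hit <- pos$chrom == window$chrom &
    pos$start >= window$start & pos$start <= window$end
  ids <- pos$name[hit]
  if (length(ids) == 0L) stop("no CpGs fall inside the window")
  sub <- betas[ids, , drop = FALSE]
  mu <- rowMeans(sub)
  s <- apply(sub, 1L, stats::sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " constant CpG(s) in window contribute zero")
    s[s == 0] <- 1
  }
  z <- (sub - mu) / s
  data.frame(sample_id = colnames(betas), mean_z = colMeans(z),
             n_cpgs = length(ids), chrom = window$chrom,
             start = window$start, end = window$end,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between window methylation score and tumor purity
#'
#' Spearman rank correlation (two-sided) between per-sample window mean-Z
#' scores and tumor cell fraction — a check that window hypermethylation is
#' not an artifact of normal-cell admixture.
#'
#' @param scores `data.frame` from [window_mean_z()].
#' @param purity Numeric tumor-cell fractions named by sample id (or in row
#'   order of `scores`).
#' @return List with rho, p_value and n.
#' @export
window_purity_association <- function(scores, purity) {
  if (!is.null(names(purity))) purity <- purity[scores$sample_id]
  ok <- !is.na(scores$mean_z) & !is.na(purity)
  if (sum(ok) < 3L) stop("need >= 3 samples with both score and purity")
  x <- scores$mean_z[ok]; y <- purity[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

# Align a possibly named label vector to a set of sample ids.
align_labels <- function(labels, ids, what) {
  if (!is.null(names(labels))) {
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop(what, " must have one entry per sample")
  }
  labels
}
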