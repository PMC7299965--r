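# Expression preprocessing: quantile normalization, probe collapsing and
# receptor-status calling from bimodal marker-gene expression.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' obtained by averaging the per-sample sorted value vectors. Ranks within a
#' sample are preserved; tied entries receive the mean of the reference
#' quantile values at the ranks the tie group occupies (the dominant
#' microarray convention). The operation is idempotent, and after it every
#' sample has an identical value multiset, hence identical column sums.
#'
#' @param mat Numeric gene x sample matrix (log2 scale), no missing values,
#'   at least two samples.
#' @return Matrix of the same shape, quantile normalized.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(mat)) stop("missing values present; impute upstream before quantile normalization")
  target <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(x) {
    r_lo <- rank(x, ties.method = "min")
    r_hi <- rank(x, ties.method = "max")
    # a tie group occupies ranks r_lo..r_hi; it gets their mean target value
    vapply(seq_along(x), function(i) mean(target[r_lo[i]:r_hi[i]]),
           numeric(1L))
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Collapse probe-level expression to gene level
#'
#' Genes measured by several probes get the arithmetic mean of their probe
#' rows; single-probe genes pass through unchanged. Probes without a gene
#' mapping are dropped and counted in a message.
#'
#' @param probe_mat Numeric probe x sample matrix with probe ids as row
#'   names.
#' @param probe_map `data.frame` with columns probe_id and gene_id; each
#'   probe maps to exactly one gene.
#' @return Gene x sample matrix.
#' @export
collapse_probes <- function(probe_mat, probe_map) {
  stopifnot(is.matrix(probe_mat), !is.null(rownames(probe_mat)))
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe_id)) {
    stop("each probe must map to exactly one gene")
  }
  gene <- probe_map$gene_id[match(rownames(probe_mat), probe_map$probe_id)]
  unmapped <- sum(is.na(gene))
  if (unmapped > 0L) {
    message(unmapped, " probe(s) without gene mapping dropped")
  }
  keep <- !is.na(gene)
  m <- probe_mat[keep, , drop = FALSE]
  gene <- gene[keep]
  if (nrow(m) == 0L) stop("no mapped probes left")
  out <- rowsum(m, group = gene, reorder = FALSE) /
    as.vector(table(factor(gene, levels = unique(gene))))
  out[unique(gene), , drop = FALSE]
}

#' Call receptor status from bimodal marker-gene expression
#'
#' ER (and, with the same machinery, PR) status is read off the expression of
#' a single marker gene whose cohort distribution is bimodal: a
#' two-component equal-variance Gaussian mixture is fitted and the cutoff is
#' placed at the point of equal posterior probability between the two
#' components. A sample is called positive iff its expression is strictly
#' above the cutoff. If the fitted components are separated by less than one
#' common standard deviation the fit is considered degenerate: with a
#' `fallback_cutoff` a warning is raised and the fallback used, otherwise the
#' call errors with "not bimodal". Supplying `cutoff` skips the fit entirely.
#'
#' @param x Named numeric vector of one gene's expression across samples
#'   (names are sample ids); at least 10 samples unless `cutoff` is given.
#' @param gene Marker gene label stored in the output (e.g. "ESR1", "PGR").
#' @param cutoff Optional fixed cutoff (log2 units); bypasses the mixture
#'   fit.
#' @param fallback_cutoff Optional cutoff used (with a warning) when the
#'   mixture fit is degenerate.
#' @return `data.frame` with columns sample_id, gene, status
#'   ("positive"/"negative"), cutoff and posterior (probability of the
#'   assigned component; `NA` when the cutoff was supplied).
#' @export
call_receptor_status <- function(x, gene = "ESR1", cutoff = NULL,
                                 fallback_cutoff = NULL) {
  stopifnot(is.numeric(x))
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("S", seq_along(x))
  if (!is.null(cutoff)) {
    return(data.frame(sample_id = ids, gene = gene,
                      status = ifelse(x > cutoff, "positive", "negative"),
                      cutoff = cutoff, posterior = NA_real_,
                      stringsAsFactors = FALSE))
  }
  if (length(x) < 10L) stop("need >= 10 samples to fit the mixture")
  if (stats::sd(x) == 0) {
    if (!is.null(fallback_cutoff)) {
      warning("degenerate mixture fit; using fallback cutoff")
      return(call_receptor_status(x, gene, cutoff = fallback_cutoff))
    }
    stop("not bimodal")
  }
  # model selection (BIC) between one and two equal-variance components:
  # a one-component winner means no reliable bimodal cutoff exists
  fit <- Mclust(x, G = 1:2, modelNames = "E", verbose = FALSE)
  if (is.null(fit) || fit$G < 2L) {
    if (!is.null(fallback_cutoff)) {
      warning("degenerate mixture fit; using fallback cutoff")
      return(call_receptor_status(x, gene, cutoff = fallback_cutoff))
    }
    stop("not bimodal")
  }
  mu <- fit$parameters$mean
  sigma <- sqrt(fit$parameters$variance$sigmasq[1L])
  lo <- min(mu); hi <- max(mu)
  if ((hi - lo) < sigma) {
    if (!is.null(fallback_cutoff)) {
      warning("degenerate mixture fit (separation < 1 sd); using fallback cutoff")
      return(call_receptor_status(x, gene, cutoff = fallback_cutoff))
    }
    stop("not bimodal")
  }
  pro <- fit$parameters$pro
  i_lo <- which.min(mu); i_hi <- which.max(mu)
  # equal-posterior point: pro_lo * dnorm(c, mu_lo, s) = pro_hi * dnorm(c, mu_hi, s)
  post_diff <- function(c) {
    log(pro[i_lo]) + stats::dnorm(c, mu[i_lo], sigma, log = TRUE) -
      log(pro[i_hi]) - stats::dnorm(c, mu[i_hi], sigma, log = TRUE)
  }
  cut <- stats::uniroot(post_diff, lower = lo, upper = hi,
                        extendInt = "downX")$root
  status <- ifelse(x > cut, "positive", "negative")
  dens_lo <- pro[i_lo] * stats::dnorm(x, mu[i_lo], sigma)
  dens_hi <- pro[i_hi] * stats::dnorm(x, mu[i_hi], sigma)
  post_hi <- dens_hi / (dens_lo + dens_hi)
  posterior <- ifelse(status == "positive", post_hi, 1 - post_hi)
  data.frame(sample_id = ids, gene = gene, status = status,
             cutoff = cut, posterior = posterior, stringsAsFactors = FALSE)
}
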