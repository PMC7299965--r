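# Centroid-based intrinsic subtyping with ER-composition-balanced centering.
#
# The nearest-centroid intrinsic subtype classifier assumes the cohort has
# roughly the ER-positive fraction of the classifier's training cohort
# (about 60%). Cohorts with a different composition are adjusted by centering
# each gene on a weighted mean of the ER-positive and ER-negative stratum
# means, m = w_pos * mean(ER+) + (1 - w_pos) * mean(ER-), instead of the
# plain cohort mean.

#' ER-composition-balanced gene centering
#'
#' @param mat Numeric gene x sample matrix (log2 scale).
#' @param er_status Character vector ("positive"/"negative"), one entry per
#'   sample, either named by sample id or in column order.
#' @param w_pos Weight on the ER-positive stratum mean; default 0.6,
#'   matching the training-cohort composition the classifier expects.
#' @return List with `matrix` (centered gene x sample matrix) and `center`
#'   (the per-gene weighted mean m that was subtracted).
#' @export
balanced_center <- function(mat, er_status, w_pos = 0.6) {
  stopifnot(is.matrix(mat), w_pos >= 0, w_pos <= 1)
  if (!is.null(names(er_status)) && !is.null(colnames(mat))) {
    miss <- setdiff(colnames(mat), names(er_status))
    if (length(miss)) stop("missing ER status for sample(s): ",
                           paste(miss, collapse = ", "))
    er_status <- er_status[colnames(mat)]
  }
  if (length(er_status) != ncol(mat)) {
    stop("er_status must have one entry per sample")
  }
  if (anyNA(er_status)) {
    stop("missing ER status for sample(s): ",
         paste(colnames(mat)[is.na(er_status)], collapse = ", "))
  }
  pos <- er_status == "positive"
  if (!any(pos)) stop("ER-positive stratum is empty")
  if (all(pos)) stop("ER-negative stratum is empty")
  m <- w_pos * rowMeans(mat[, pos, drop = FALSE]) +
    (1 - w_pos) * rowMeans(mat[, !pos, drop = FALSE])
  list(matrix = mat - m, center = m)
}

#' Assign intrinsic subtypes by Spearman correlation to centroids
#'
#' Each sample's (centered) expression vector is rank-correlated against
#' every centroid over the genes shared between matrix and centroid set
#' (mid-ranks for ties); the subtype with the highest coefficient is
#' assigned and the runner-up recorded. An exact tie in the maximum goes to
#' the subtype listed earliest in the centroid columns, with a message.
#'
#' @param centered Numeric gene x sample matrix (typically the output of
#'   [balanced_center()]).
#' @param centroids Numeric gene x subtype matrix; column order defines
#'   subtype display order and tie-breaking.
#' @return `data.frame` with sample_id, subtype, second_subtype, one
#'   `cor_<subtype>` column per centroid, and n_genes_used.
#' @export
assign_subtype <- function(centered, centroids) {
  stopifnot(is.matrix(centered), is.matrix(centroids))
  if (ncol(centroids) < 2L) stop("need >= 2 centroids")
  shared <- intersect(rownames(centered), rownames(centroids))
  if (length(shared) < 3L) {
    stop("fewer than 3 genes shared with the centroid set")
  }
  if (length(shared) < 0.8 * nrow(centroids)) {
    warning(sprintf("only %d of %d centroid genes found in the matrix",
                    length(shared), nrow(centroids)))
  }
  x <- centered[shared, , drop = FALSE]
  cc <- centroids[shared, , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance expression vector for sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  cors <- stats::cor(x, cc, method = "spearman")  # samples x subtypes
  subtypes <- colnames(centroids)
  pick <- apply(cors, 1L, function(r) {
    best <- which(r == max(r))
    if (length(best) > 1L) message("subtype tie broken by centroid order")
    first <- best[1L]
    r2 <- r
    r2[first] <- -Inf
    second <- which.max(r2)
    c(first, second)
  })
  out <- data.frame(sample_id = colnames(centered),
                    subtype = subtypes[pick[1L, ]],
                    second_subtype = subtypes[pick[2L, ]],
                    stringsAsFactors = FALSE)
  for (k in seq_along(subtypes)) out[[paste0("cor_", subtypes[k])]] <- cors[, k]
  out$n_genes_used <- length(shared)
  rownames(out) <- NULL
  out
}

#' Flag core basal tumors
#'
#' Core basal tumors are those whose correlation to the basal-like centroid
#' is strictly above a threshold (default 0.6). The flag is computed for all
#' samples; interpretation is conventionally restricted to invasive tumors
#' by downstream reports.
#'
#' @param calls Subtype-call `data.frame` from [assign_subtype()].
#' @param threshold Strict lower bound on the basal correlation; default
#'   0.6.
#' @param basal Name of the basal-like subtype column (`cor_<basal>`).
#' @return `calls` with a logical `core_basal` column appended.
#' @export
call_core_basal <- function(calls, threshold = 0.6, basal = "Basal") {
  col <- paste0("cor_", basal)
  if (!col %in% names(calls)) {
    stop("calls contain no correlation column for basal subtype '", basal, "'")
  }
  calls$core_basal <- calls[[col]] > threshold
  calls
}

#' Mean inter-centroid gap
#'
#' Mean over genes of the mean absolute pairwise difference between centroid
#' values — a scale for choosing within-subtype noise levels relative to
#' centroid separation.
#'
#' @param centroids Gene x subtype matrix.
#' @export
mean_centroid_gap <- function(centroids) {
  stopifnot(is.matrix(centroids), ncol(centroids) >= 2L)
  pairs <- utils::combn(ncol(centroids), 2L)
  mean(apply(pairs, 2L, function(p) {
    mean(abs(centroids[, p[1L]] - centroids[, p[2L]]))
  }))
}
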