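# Gene-expression signature scores: per-sample (weighted) means of per-gene
# standard scores. Z-scores are computed over the full cohort supplied, so a
# unit-weight signature has cohort-mean score zero by construction.

#' Per-gene standard scores
#'
#' Transforms each gene row to (x - mean) / sd across samples. The standard
#' deviation uses the sample (n - 1) estimator by default. Zero-variance
#' genes become rows of zeros with a warning; their ids are attached as
#' attribute `"zero_variance"` so signature scoring can exclude them.
#'
#' @param mat Numeric gene x sample matrix.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return Matrix of standard scores, same shape as `mat`.
#' @export
zscore_by_gene <- function(mat, sd_type = c("sample", "population")) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  sd_type <- match.arg(sd_type)
  mu <- rowMeans(mat)
  centered <- mat - mu
  ss <- rowSums(centered^2)
  denom <- if (sd_type == "sample") ncol(mat) - 1L else ncol(mat)
  s <- sqrt(ss / denom)
  zero <- s == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) set to all-zero Z rows")
    s[zero] <- 1
  }
  z <- centered / s
  attr(z, "zero_variance") <- rownames(mat)[zero]
  z
}

#' Score one signature
#'
#' score(sample) = mean over the signature genes found in the matrix of
#' weight * z(gene, sample). Genes absent from the matrix are dropped and
#' counted; an entirely absent signature is an error.
#'
#' @param z Standard-score matrix from [zscore_by_gene()].
#' @param genes Character vector of signature gene ids.
#' @param weights Numeric weights, one per gene (recycled scalar allowed);
#'   conventionally +1/-1.
#' @param name Signature name used in messages.
#' @param exclude_zero_variance Drop genes flagged zero-variance by
#'   [zscore_by_gene()]; default TRUE.
#' @return Numeric vector of scores named by sample, with attribute
#'   `"n_genes_found"`.
#' @export
score_signature <- function(z, genes, weights = 1, name = "signature",
                            exclude_zero_variance = TRUE) {
  stopifnot(is.matrix(z), length(genes) >= 1L)
  if (anyDuplicated(genes)) stop("duplicate gene ids in signature ", name)
  weights <- rep_len(weights, length(genes))
  found <- genes %in% rownames(z)
  if (exclude_zero_variance) {
    found <- found & !(genes %in% attr(z, "zero_variance"))
  }
  if (!any(found)) stop("no genes of signature '", name, "' found in matrix")
  w <- weights[found]
  sub <- z[genes[found], , drop = FALSE]
  scores <- colMeans(sub * w)
  attr(scores, "n_genes_found") <- sum(found)
  scores
}

#' Score a table of signatures
#'
#' @param z Standard-score matrix from [zscore_by_gene()].
#' @param defs Signature definitions: `data.frame` with columns signature,
#'   gene_id, weight (see [read_signature_defs()]).
#' @return `data.frame` with sample_id and one column per signature;
#'   attribute `"n_genes_found"` maps signature to the count of genes used.
#' @export
score_signatures <- function(z, defs) {
  stopifnot(all(c("signature", "gene_id", "weight") %in% names(defs)))
  sig_names <- unique(defs$signature)
  out <- data.frame(sample_id = colnames(z), stringsAsFactors = FALSE)
  n_found <- integer(0)
  for (s in sig_names) {
    d <- defs[defs$signature == s, ]
    sc <- score_signature(z, d$gene_id, d$weight, name = s)
    out[[s]] <- as.numeric(sc)
    n_found[s] <- attr(sc, "n_genes_found")
  }
  attr(out, "n_genes_found") <- n_found
  out
}
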