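# Segment-based copy-number summaries: gene-level copy number by maximal
# overlap, genomic instability index, and cohort aberration frequencies.
# All intervals are 1-based inclusive (see R/io.R).

#' Gene-level copy number by maximal segment overlap
#'
#' For each sample and gene, the copy number of the segment overlapping the
#' gene interval by the most base pairs is assigned to the gene. Equal
#' overlap is broken in favour of the segment with the smaller start. Genes
#' with no overlapping segment get `NA`, and per-sample missing-coverage
#' counts are reported in a message.
#'
#' @param segments Segment `data.frame` (sample, chrom, start, end, cn),
#'   validated via [validate_segments()].
#' @param genes Gene models: `data.frame` with chrom, start, end, name
#'   (1-based inclusive), e.g. from [read_bed()].
#' @return Integer gene x sample matrix of copy numbers (NA where
#'   uncovered).
#' @export
gene_copy_number <- function(segments, genes) {
  segments <- validate_segments(segments)
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  samples <- unique(segments$sample)
  out <- matrix(NA_integer_, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$name, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      cand <- seg[seg$chrom == genes$chrom[i], , drop = FALSE]
      if (nrow(cand) == 0L) next
      ov <- pmin(cand$end, genes$end[i]) - pmax(cand$start, genes$start[i]) + 1L
      ov[ov < 0L] <- 0L
      if (all(ov == 0L)) next
      best <- which(ov == max(ov))
      # tie-break: smaller segment start wins; cand is sorted by start
      out[i, s] <- cand$cn[best[1L]]
    }
    n_missing <- sum(is.na(out[, s]))
    if (n_missing > 0L) {
      message("sample ", s, ": ", n_missing, " gene(s) without segment coverage")
    }
  }
  out
}

#' Copy-number gain/loss status relative to a baseline
#'
#' @param cn_table Gene x sample copy-number matrix from
#'   [gene_copy_number()].
#' @param baseline Integer copy number considered neutral (default 2).
#' @return Character matrix with entries "gain", "loss", "neutral" or NA.
#' @export
cn_status <- function(cn_table, baseline = 2L) {
  status <- matrix(NA_character_, nrow(cn_table), ncol(cn_table),
                   dimnames = dimnames(cn_table))
  status[!is.na(cn_table) & cn_table > baseline] <- "gain"
  status[!is.na(cn_table) & cn_table < baseline] <- "loss"
  status[!is.na(cn_table) & cn_table == baseline] <- "neutral"
  status
}

#' Genomic instability index
#'
#' GII is the fraction of the covered genome whose copy number deviates from
#' the baseline: aberrant_bp / covered_bp, where covered_bp is the total
#' length of a sample's segments. The baseline is cn = 2 by default; when a
#' per-sample `ploidy` is supplied, each sample's baseline is the nearest
#' integer to its ploidy instead.
#'
#' @param segments Segment `data.frame` (sample, chrom, start, end, cn).
#' @param baseline Integer neutral copy number (default 2).
#' @param ploidy Optional named numeric vector of per-sample ploidies.
#' @return `data.frame` with sample_id, gii, covered_bp, aberrant_bp,
#'   baseline.
#' @export
genomic_instability_index <- function(segments, baseline = 2L, ploidy = NULL) {
  segments <- validate_segments(segments)
  samples <- unique(segments$sample)
  res <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    b <- if (!is.null(ploidy)) {
      if (is.na(ploidy[s])) stop("no ploidy for sample ", s)
      as.integer(round(ploidy[s]))
    } else as.integer(baseline)
    w <- seg$end - seg$start + 1
    covered <- sum(w)
    if (covered == 0) stop("sample ", s, " has zero covered genome")
    aberrant <- sum(w[seg$cn != b])
    data.frame(sample_id = s, gii = aberrant / covered,
               covered_bp = covered, aberrant_bp = aberrant, baseline = b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-locus gain and loss frequencies by group
#'
#' For each locus (row of the copy-number table) and each group, the
#' fraction of that group's samples with a gain and the fraction with a
#' loss, relative to the baseline. A sample contributes to at most one of
#' the two at any locus; samples with missing copy number at a locus are
#' excluded from that locus's denominator.
#'
#' @param cn_table Gene (or bin) x sample copy-number matrix.
#' @param groups Character vector of group labels, named by sample id or in
#'   column order.
#' @param baseline Neutral copy number (default 2).
#' @return `data.frame` with locus, group, n, gain_freq, loss_freq.
#' @export
aberration_frequency <- function(cn_table, groups, baseline = 2L) {
  stopifnot(is.matrix(cn_table))
  if (!is.null(names(groups))) groups <- groups[colnames(cn_table)]
  if (length(groups) != ncol(cn_table) || anyNA(groups)) {
    stop("groups must label every sample column")
  }
  lv <- unique(groups)
  if (any(table(groups) < 1L)) stop("empty group")
  out <- list()
  for (g in lv) {
    sub <- cn_table[, groups == g, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    if (all(n_obs == 0L)) stop("group ", g, " has no observed copy numbers")
    gain <- rowSums(sub > baseline, na.rm = TRUE) / pmax(n_obs, 1L)
    loss <- rowSums(sub < baseline, na.rm = TRUE) / pmax(n_obs, 1L)
    gain[n_obs == 0L] <- NA_real_
    loss[n_obs == 0L] <- NA_real_
    out[[g]] <- data.frame(locus = rownames(cn_table), group = g, n = n_obs,
                           gain_freq = gain, loss_freq = loss,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
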