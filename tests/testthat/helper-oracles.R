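# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation.

# Quantile normalization by explicit rank bookkeeping: target distribution
# is the mean of per-column sorted vectors; a tie group occupying sorted
# positions a..b receives mean(target[a:b]).
oracle_quantile_normalize <- function(mat) {
  target <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    for (i in seq_along(x)) {
      a <- sum(x < x[i]) + 1L
      b <- sum(x <= x[i])
      out[i, j] <- mean(target[a:b])
    }
  }
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2L, u_of)
  u_obs <- u_of(seq_len(m))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Benjamini-Hochberg step-up q-values from the defining formula
# q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[o][i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum of probabilities of tables (with the observed margins) no more
# probable than the observed one.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0L, r1 + c1 - n); a_max <- min(r1, c1)
  probs <- vapply(a_min:a_max, function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - a_min + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Per-basepair GII counter on toy genomes.
oracle_gii <- function(seg_one_sample, baseline = 2L) {
  aberrant <- 0; covered <- 0
  for (i in seq_len(nrow(seg_one_sample))) {
    for (bp in seg_one_sample$start[i]:seg_one_sample$end[i]) {
      covered <- covered + 1
      if (seg_one_sample$cn[i] != baseline) aberrant <- aberrant + 1
    }
  }
  aberrant / covered
}

# Brute-force maximal-overlap gene copy number with the smaller-start
# tie-break, by scoring every segment against the gene interval.
oracle_gene_cn <- function(seg_one_sample, gene) {
  best_cn <- NA_integer_; best_ov <- 0L; best_start <- Inf
  for (i in seq_len(nrow(seg_one_sample))) {
    if (seg_one_sample$chrom[i] != gene$chrom) next
    ov <- length(intersect(seg_one_sample$start[i]:seg_one_sample$end[i],
                           gene$start:gene$end))
    if (ov > best_ov ||
        (ov == best_ov && ov > 0L && seg_one_sample$start[i] < best_start)) {
      best_cn <- seg_one_sample$cn[i]
      best_ov <- ov
      best_start <- seg_one_sample$start[i]
    }
  }
  best_cn
}

# Random non-overlapping integer-CN segment set on a toy genome.
random_toy_segments <- function(sample_id = "S1", genome_len = 1000L,
                                chroms = c("c1", "c2"), max_segs = 6L) {
  out <- list()
  for (ch in chroms) {
    cuts <- sort(sample(seq_len(genome_len - 1L),
                        sample.int(max_segs, 1L) - 1L))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, genome_len)
    keep <- sort(sample(seq_along(starts),
                        sample.int(length(starts), 1L)))
    out[[ch]] <- data.frame(sample = sample_id, chrom = ch,
                            start = starts[keep], end = ends[keep],
                            cn = sample(0:4, length(keep), replace = TRUE),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# A compact cohort configuration for tests that need many replicates.
small_cohort_config <- function(seed, ...) {
  cohort_config(n_per_group = 10L, n_normal = 0L, n_genes = 80L,
                n_centroid_genes = 20L, n_cpgs = 400L, n_window_cpgs = 100L,
                n_diff_genes = 5L, seed = seed, ...)
}
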