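# Synthetic multi-omic cohort generator. Produces expression, methylation,
# copy-number segments and annotations with known planted structure
# (subtype-structured expression with bimodal ESR1, a plantable
# hypermethylated window, plantable per-gene DCIS-vs-IBC methylation shifts,
# and subtype-specific recurrent copy-number events with a configurable
# aberrant genome fraction) so every downstream stage of the pipeline can be
# exercised and its recovery of the planted truth scored.

#' Build and validate a synthetic-cohort configuration
#'
#' Defaults describe a small but fully featured cohort: four intrinsic
#' subtypes x two tumor types, Gaussian log2 expression noise around
#' synthetic centroids, bimodal ESR1/PGR, a 800 kb silencing-prone window on
#' chr5 carrying 698 CpGs, recurrent subtype-specific copy-number events
#' (5q loss in basal tumors, a 17q12-like gain in HER2-enriched tumors, 16q
#' loss in luminal tumors) with lower aberrant fractions in DCIS than IBC,
#' and sparse missingness/detection failure in the beta layer.
#'
#' @param n_per_group Samples per (subtype x tumor type) cell.
#' @param subtypes Ordered subtype names.
#' @param tumor_types Tumor types generated per subtype.
#' @param n_normal Number of normal-tissue samples (no subtype, purity 0).
#' @param n_genes Total expression genes (includes centroid, marker,
#'   signature and filler genes).
#' @param n_centroid_genes Genes in the synthetic centroid set.
#' @param n_signature_genes Genes in the planted proliferation-like
#'   signature.
#' @param centroid_sd Within-subtype expression noise sd (log2 units).
#' @param dcis_attenuation Multiplier (< 1) shrinking DCIS centroid-gene
#'   signal toward zero, emulating the weaker centroid correlations of in
#'   situ lesions.
#' @param esr1_modes Named vector `c(low=, high=, sd=)` for the bimodal
#'   ESR1/PGR generator (log2 units).
#' @param p_er_pos_luminal,p_er_pos_nonluminal Probability a
#'   luminal/non-luminal sample is ER-positive.
#' @param sig_delta Mean log2 shift planted on signature genes in basal IBC.
#' @param n_cpgs Total CpGs.
#' @param window_chrom,window_start_bp,window_span_bp Location and span of
#'   the plantable silencing window.
#' @param n_window_cpgs CpGs inside the window.
#' @param lres_delta Beta shift planted on window CpGs of the designated
#'   samples (clipped to \[0, 1\]).
#' @param lres_subtype,lres_tumor_type Which (subtype, tumor type) cell
#'   receives the window shift.
#' @param n_diff_genes Genes with a planted DCIS-vs-IBC methylation
#'   difference.
#' @param diff_delta Beta shift planted on those genes' CpGs in IBC samples.
#' @param beta_sd Beta-value noise sd (truncated-Gaussian model).
#' @param beta_model `"truncnorm"` (Gaussian noise clipped to \[0, 1\],
#'   default) or `"beta"` (Beta distribution with matching mean).
#' @param beta_precision Precision parameter of the Beta alternative.
#' @param genome_length_bp Total genome span, divided equally over
#'   `chromosomes`.
#' @param chromosomes Chromosome names of the synthetic coordinate system.
#' @param aberration_profiles Optional per-(subtype.tumor_type) list of
#'   `list(events = data.frame(chrom, start, end, cn, prob), target_fraction)`;
#'   defaults via [default_aberration_profiles()].
#' @param missing_rate Fraction of beta entries masked missing at source.
#' @param detection_fail_rate Fraction of detection p-values drawn above
#'   0.05.
#' @param purity_range Uniform range for tumor purity.
#' @param seed Integer RNG seed; a fixed seed makes the cohort byte-stable.
#' @return Validated configuration list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 10L,
                          subtypes = c("Basal", "Her2", "LumA", "LumB"),
                          tumor_types = c("DCIS", "IBC"),
                          n_normal = 12L,
                          n_genes = 200L,
                          n_centroid_genes = 50L,
                          n_signature_genes = 11L,
                          centroid_sd = 0.6,
                          dcis_attenuation = 0.7,
                          esr1_modes = c(low = 4, high = 10, sd = 0.5),
                          p_er_pos_luminal = 0.9,
                          p_er_pos_nonluminal = 0.1,
                          sig_delta = 1,
                          n_cpgs = 2000L,
                          window_chrom = "chr5",
                          window_start_bp = 2000001,
                          window_span_bp = 800000,
                          n_window_cpgs = 698L,
                          lres_delta = 0.3,
                          lres_subtype = "Basal",
                          lres_tumor_type = "IBC",
                          n_diff_genes = 20L,
                          diff_delta = 0.2,
                          beta_sd = 0.08,
                          beta_model = c("truncnorm", "beta"),
                          beta_precision = 50,
                          genome_length_bp = 6e7,
                          chromosomes = c("chr1", "chr5", "chr8",
                                          "chr16", "chr17", "chr20"),
                          aberration_profiles = NULL,
                          missing_rate = 0.002,
                          detection_fail_rate = 0.002,
                          purity_range = c(0.3, 0.9),
                          seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group), subtypes = subtypes,
              tumor_types = tumor_types, n_normal = as.integer(n_normal),
              n_genes = as.integer(n_genes),
              n_centroid_genes = as.integer(n_centroid_genes),
              n_signature_genes = as.integer(n_signature_genes),
              centroid_sd = centroid_sd, dcis_attenuation = dcis_attenuation,
              esr1_modes = esr1_modes,
              p_er_pos_luminal = p_er_pos_luminal,
              p_er_pos_nonluminal = p_er_pos_nonluminal,
              sig_delta = sig_delta, n_cpgs = as.integer(n_cpgs),
              window_chrom = window_chrom,
              window_start_bp = window_start_bp,
              window_span_bp = window_span_bp,
              n_window_cpgs = as.integer(n_window_cpgs),
              lres_delta = lres_delta, lres_subtype = lres_subtype,
              lres_tumor_type = lres_tumor_type,
              n_diff_genes = as.integer(n_diff_genes),
              diff_delta = diff_delta, beta_sd = beta_sd,
              beta_model = match.arg(beta_model),
              beta_precision = beta_precision,
              genome_length_bp = genome_length_bp,
              chromosomes = chromosomes,
              aberration_profiles = aberration_profiles,
              missing_rate = missing_rate,
              detection_fail_rate = detection_fail_rate,
              purity_range = purity_range, seed = as.integer(seed))
  counts <- c("n_per_group", "n_normal", "n_genes", "n_centroid_genes",
              "n_signature_genes", "n_cpgs", "n_window_cpgs", "n_diff_genes")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) stop("invalid ", f, ": must be >= 0")
  }
  for (f in c("lres_delta", "diff_delta", "missing_rate",
              "detection_fail_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("invalid ", f, ": must be in [0, 1]")
  }
  if (length(cfg$subtypes) < 2L) stop("invalid subtypes: need >= 2")
  if (cfg$window_span_bp > cfg$genome_length_bp) {
    stop("invalid window_span_bp: exceeds genome_length_bp")
  }
  if (cfg$n_window_cpgs > cfg$n_cpgs) {
    stop("invalid n_window_cpgs: exceeds n_cpgs")
  }
  if (!cfg$window_chrom %in% cfg$chromosomes) {
    stop("invalid window_chrom: not among chromosomes")
  }
  chrom_len <- floor(cfg$genome_length_bp / length(cfg$chromosomes))
  if (cfg$window_start_bp + cfg$window_span_bp - 1 > chrom_len) {
    stop("invalid window_start_bp: window does not fit on ", cfg$window_chrom)
  }
  n_reserved <- cfg$n_centroid_genes + 2L + cfg$n_signature_genes + 11L
  if (cfg$n_genes < n_reserved + cfg$n_diff_genes) {
    stop("invalid n_genes: need at least ", n_reserved + cfg$n_diff_genes,
         " to host centroid, marker, signature and differential genes")
  }
  if (!cfg$lres_subtype %in% cfg$subtypes) {
    stop("invalid lres_subtype: not among subtypes")
  }
  if (is.null(cfg$aberration_profiles)) {
    cfg$aberration_profiles <- default_aberration_profiles(cfg)
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Default recurrent copy-number events per (subtype x tumor type)
#'
#' Basal tumors carry a 5q-like loss (frequent in IBC, a minority of DCIS),
#' HER2-enriched tumors a focal 17q12-like gain spanning the ERBB2 model,
#' luminal tumors a 16q-like loss; DCIS cells have lower target aberrant
#' fractions than IBC throughout, matching the lower genomic instability of
#' in situ lesions.
#'
#' @param cfg A (partially built) `cohort_config` list.
#' @return Named list, one entry per "subtype.tumor_type", each with
#'   `events` (`data.frame`: chrom, start, end, cn, prob) and
#'   `target_fraction`.
#' @export
default_aberration_profiles <- function(cfg) {
  ev <- function(chrom, start, end, cn, prob) {
    data.frame(chrom = chrom, start = start, end = end, cn = cn, prob = prob,
               stringsAsFactors = FALSE)
  }
  none <- ev(character(0), numeric(0), numeric(0), integer(0), numeric(0))
  profiles <- list(
    Basal.IBC  = list(events = ev("chr5", 1, 6e6, 1L, 0.9),
                      target_fraction = 0.35),
    Basal.DCIS = list(events = ev("chr5", 1, 6e6, 1L, 0.2),
                      target_fraction = 0.10),
    Her2.IBC   = list(events = ev("chr17", 4.5e6 + 1, 5.5e6, 4L, 0.9),
                      target_fraction = 0.30),
    Her2.DCIS  = list(events = ev("chr17", 4.5e6 + 1, 5.5e6, 4L, 0.85),
                      target_fraction = 0.18),
    LumA.IBC   = list(events = ev("chr16", 4e6 + 1, 1e7, 1L, 0.8),
                      target_fraction = 0.15),
    LumA.DCIS  = list(events = ev("chr16", 6e6 + 1, 1e7, 1L, 0.7),
                      target_fraction = 0.08),
    LumB.IBC   = list(events = rbind(ev("chr16", 4e6 + 1, 1e7, 1L, 0.6),
                                     ev("chr17", 4.5e6 + 1, 5.5e6, 3L, 0.3)),
                      target_fraction = 0.25),
    LumB.DCIS  = list(events = ev("chr16", 6e6 + 1, 1e7, 1L, 0.5),
                      target_fraction = 0.12)
  )
  out <- list()
  for (st in cfg$subtypes) {
    for (tt in cfg$tumor_types) {
      key <- paste(st, tt, sep = ".")
      out[[key]] <- if (key %in% names(profiles)) profiles[[key]] else
        list(events = none, target_fraction = 0.1)
    }
  }
  out
}

#' Generate a synthetic multi-omic cohort
#'
#' Draws every omic layer from the configuration: centroid-gene expression
#' as subtype centroid plus Gaussian noise (DCIS signal attenuated), bimodal
#' ESR1/PGR consistent with ER truth, a planted proliferation-like program,
#' beta values around per-CpG baselines with the window and per-gene shifts
#' applied before clipping, detection p-values with a configurable failure
#' rate, and per-sample segment profiles tiling the genome without overlap
#' while realising the configured aberrant fraction within +-1%. The truth
#' record identifies every planted effect.
#'
#' @param config A [cohort_config()] object (a plain list is coerced).
#' @return Object of class `synthetic_cohort`: list with expression,
#'   centroids, betas, detection_p, segments, annotations, cpg_positions,
#'   gene_models, signatures, window, truth and config.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  cfg <- config
  set.seed(cfg$seed)
  chrom_len <- floor(cfg$genome_length_bp / length(cfg$chromosomes))
  chrom_lengths <- stats::setNames(rep(chrom_len, length(cfg$chromosomes)),
                                   cfg$chromosomes)

  ## ---- samples -------------------------------------------------------
  grid <- expand.grid(tumor_type = cfg$tumor_types, subtype = cfg$subtypes,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  ann <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(
      sample_id = sprintf("%s_%s_%02d", grid$subtype[i], grid$tumor_type[i],
                          seq_len(cfg$n_per_group)),
      tumor_type = grid$tumor_type[i], subtype = grid$subtype[i],
      stringsAsFactors = FALSE)
  }))
  if (cfg$n_normal > 0L) {
    ann <- rbind(ann, data.frame(
      sample_id = sprintf("NORM_%02d", seq_len(cfg$n_normal)),
      tumor_type = "NORMAL", subtype = NA_character_,
      stringsAsFactors = FALSE))
  }
  n_samples <- nrow(ann)
  is_tumor <- ann$tumor_type != "NORMAL"
  luminal <- !is.na(ann$subtype) & ann$subtype %in% c("LumA", "LumB")
  p_pos <- ifelse(!is_tumor, 0.7,
                  ifelse(luminal, cfg$p_er_pos_luminal,
                         cfg$p_er_pos_nonluminal))
  er_truth <- ifelse(stats::runif(n_samples) < p_pos, "positive", "negative")
  pr_truth <- ifelse(stats::runif(n_samples) <
                       ifelse(er_truth == "positive", 0.8, 0.1),
                     "positive", "negative")
  ann$er_truth <- er_truth
  ann$purity <- ifelse(is_tumor,
                       stats::runif(n_samples, cfg$purity_range[1],
                                    cfg$purity_range[2]), 0)

  ## ---- gene universe -------------------------------------------------
  cen_genes <- sprintf("PAM%03d", seq_len(cfg$n_centroid_genes))
  sig_genes <- sprintf("PRF%02d", seq_len(cfg$n_signature_genes))
  adh_genes <- sprintf("ADH%02d", 1:4)
  emt_genes <- sprintf("EMT%02d", 1:7)
  n_filler <- cfg$n_genes - cfg$n_centroid_genes - 2L -
    cfg$n_signature_genes - 11L
  fil_genes <- sprintf("G%04d", seq_len(n_filler))
  genes <- c(cen_genes, "ESR1", "PGR", sig_genes, adh_genes, emt_genes,
             fil_genes)
  diff_genes <- fil_genes[seq_len(cfg$n_diff_genes)]

  ## ---- expression ----------------------------------------------------
  centroids <- matrix(stats::rnorm(cfg$n_centroid_genes *
                                     length(cfg$subtypes)),
                      nrow = cfg$n_centroid_genes,
                      dimnames = list(cen_genes, cfg$subtypes))
  expr <- matrix(NA_real_, length(genes), n_samples,
                 dimnames = list(genes, ann$sample_id))
  mean_centroid <- rowMeans(centroids)
  for (j in seq_len(n_samples)) {
    if (is_tumor[j]) {
      base <- centroids[, ann$subtype[j]]
      if (ann$tumor_type[j] == "DCIS") base <- base * cfg$dcis_attenuation
    } else {
      base <- 0.3 * mean_centroid
    }
    expr[cen_genes, j] <- base +
      stats::rnorm(cfg$n_centroid_genes, sd = cfg$centroid_sd)
  }
  modes <- cfg$esr1_modes
  expr["ESR1", ] <- stats::rnorm(
    n_samples, ifelse(er_truth == "positive", modes[["high"]],
                      modes[["low"]]), modes[["sd"]])
  expr["PGR", ] <- stats::rnorm(
    n_samples, ifelse(pr_truth == "positive", modes[["high"]],
                      modes[["low"]]), modes[["sd"]])
  other <- c(sig_genes, adh_genes, emt_genes, fil_genes)
  base_means <- stats::runif(length(other), 5, 10)
  expr[other, ] <- base_means +
    matrix(stats::rnorm(length(other) * n_samples, sd = 0.5),
           length(other), n_samples)
  sig_samples <- ann$sample_id[is_tumor & ann$subtype == "Basal" &
                                 ann$tumor_type == "IBC"]
  expr[sig_genes, sig_samples] <- expr[sig_genes, sig_samples] + cfg$sig_delta

  signatures <- rbind(
    data.frame(signature = "proliferation", gene_id = sig_genes, weight = 1),
    data.frame(signature = "emt", gene_id = adh_genes, weight = -1),
    data.frame(signature = "emt", gene_id = emt_genes, weight = 1))

  ## ---- gene models ---------------------------------------------------
  window <- list(chrom = cfg$window_chrom, start = cfg$window_start_bp,
                 end = cfg$window_start_bp + cfg$window_span_bp - 1)
  model_chroms <- setdiff(cfg$chromosomes, cfg$window_chrom)
  gene_len <- 20000
  per_chrom <- ceiling(length(genes) / length(model_chroms))
  spacing <- floor((chrom_len - gene_len) / (per_chrom + 1))
  gm <- data.frame(
    chrom = model_chroms[(seq_along(genes) - 1L) %% length(model_chroms) + 1L],
    start = ((seq_along(genes) - 1L) %/% length(model_chroms) + 1L) * spacing,
    name = genes, stringsAsFactors = FALSE)
  gm$end <- gm$start + gene_len - 1L
  n_pcdh <- 6L
  pcdh_start <- window$start +
    round(seq(0, cfg$window_span_bp - 60000,
              length.out = n_pcdh))
  pcdh <- data.frame(chrom = cfg$window_chrom, start = pcdh_start,
                     name = sprintf("PCDH%02d", seq_len(n_pcdh)),
                     stringsAsFactors = FALSE)
  pcdh$end <- pcdh$start + 50000
  erbb2 <- data.frame(chrom = "chr17", start = 5e6 + 1, name = "ERBB2",
                      end = 5.1e6, stringsAsFactors = FALSE)
  gene_models <- rbind(gm, pcdh, erbb2)[, c("chrom", "start", "end", "name")]

  ## ---- CpG map -------------------------------------------------------
  win_pos <- sort(sample.int(cfg$window_span_bp, cfg$n_window_cpgs)) +
    window$start - 1
  n_rest <- cfg$n_cpgs - cfg$n_window_cpgs
  host <- genes[(seq_len(n_rest) - 1L) %% length(genes) + 1L]
  idx <- match(host, gm$name)
  rest_pos <- round(stats::runif(n_rest, gm$start[idx], gm$end[idx]))
  cpg_positions <- data.frame(
    chrom = c(rep(cfg$window_chrom, cfg$n_window_cpgs), gm$chrom[idx]),
    start = c(win_pos, rest_pos), stringsAsFactors = FALSE)
  cpg_positions$end <- cpg_positions$start
  cpg_positions$name <- sprintf("cg%07d", seq_len(cfg$n_cpgs))
  is_window_cpg <- seq_len(cfg$n_cpgs) <= cfg$n_window_cpgs
  cpg_host <- c(rep(NA_character_, cfg$n_window_cpgs), host)

  ## ---- beta values ---------------------------------------------------
  gene_base <- stats::setNames(stats::runif(length(genes), 0.15, 0.85), genes)
  baseline <- numeric(cfg$n_cpgs)
  baseline[is_window_cpg] <- stats::runif(cfg$n_window_cpgs, 0.10, 0.25)
  baseline[!is_window_cpg] <-
    pmin(pmax(gene_base[cpg_host[!is_window_cpg]] +
                stats::runif(n_rest, -0.05, 0.05), 0.05), 0.95)
  mu <- matrix(baseline, cfg$n_cpgs, n_samples)
  lres_samples <- ann$sample_id[is_tumor &
                                  ann$subtype == cfg$lres_subtype &
                                  ann$tumor_type == cfg$lres_tumor_type]
  mu[is_window_cpg, ann$sample_id %in% lres_samples] <-
    mu[is_window_cpg, ann$sample_id %in% lres_samples] + cfg$lres_delta
  diff_cpg <- !is_window_cpg & cpg_host %in% diff_genes
  ibc <- ann$tumor_type == "IBC"
  mu[diff_cpg, ibc] <- mu[diff_cpg, ibc] + cfg$diff_delta
  mu <- pmin(pmax(mu, 0), 1)
  if (cfg$beta_model == "truncnorm") {
    betas <- mu + matrix(stats::rnorm(length(mu), sd = cfg$beta_sd),
                         nrow(mu), ncol(mu))
    betas <- pmin(pmax(betas, 0), 1)
  } else {
    m <- pmin(pmax(mu, 0.01), 0.99)
    betas <- matrix(stats::rbeta(length(m), m * cfg$beta_precision,
                                 (1 - m) * cfg$beta_precision),
                    nrow(m), ncol(m))
  }
  dimnames(betas) <- list(cpg_positions$name, ann$sample_id)
  if (cfg$missing_rate > 0) {
    betas[stats::runif(length(betas)) < cfg$missing_rate] <- NA_real_
  }
  fail <- stats::runif(length(betas)) < cfg$detection_fail_rate
  detection_p <- matrix(stats::runif(length(betas), 0, 0.04),
                        nrow(betas), ncol(betas), dimnames = dimnames(betas))
  detection_p[fail] <- stats::runif(sum(fail), 0.051, 1)

  ## ---- copy-number segments -----------------------------------------
  seg_list <- vector("list", n_samples)
  realized <- numeric(n_samples)
  for (j in seq_len(n_samples)) {
    key <- paste(ann$subtype[j], ann$tumor_type[j], sep = ".")
    prof <- if (is_tumor[j]) cfg$aberration_profiles[[key]] else
      list(events = cfg$aberration_profiles[[1]]$events[0, ],
           target_fraction = 0)
    sj <- simulate_sample_segments(ann$sample_id[j], prof, chrom_lengths)
    seg_list[[j]] <- sj
    w <- sj$end - sj$start + 1
    realized[j] <- sum(w[sj$cn != 2L]) / sum(w)
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL

  truth <- list(
    lres_samples = lres_samples, diff_genes = diff_genes,
    sig_genes = sig_genes, sig_samples = sig_samples,
    window = window, er_truth = stats::setNames(er_truth, ann$sample_id),
    pr_truth = stats::setNames(pr_truth, ann$sample_id),
    subtype_truth = stats::setNames(ann$subtype, ann$sample_id),
    target_fractions = stats::setNames(
      vapply(seq_len(n_samples), function(j) {
        if (is_tumor[j]) {
          cfg$aberration_profiles[[paste(ann$subtype[j], ann$tumor_type[j],
                                         sep = ".")]]$target_fraction
        } else 0
      }, numeric(1)), ann$sample_id),
    realized_fractions = stats::setNames(realized, ann$sample_id))

  structure(list(expression = expr, centroids = centroids, betas = betas,
                 detection_p = detection_p, segments = segments,
                 annotations = ann, cpg_positions = cpg_positions,
                 gene_models = gene_models, signatures = signatures,
                 window = window, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

# One sample's segment profile: apply each recurrent event independently
# with its probability, then top up with random non-overlapping aberrant
# intervals until the aberrant fraction matches the target (within +-1%),
# and finally tile the rest of the genome at cn = 2.
simulate_sample_segments <- function(sample_id, profile, chrom_lengths) {
  genome <- sum(chrom_lengths)
  ab <- profile$events[stats::runif(nrow(profile$events)) <=
                         profile$events$prob, , drop = FALSE]
  ab <- ab[, c("chrom", "start", "end", "cn")]
  deficit <- round(profile$target_fraction * genome) -
    sum(if (nrow(ab)) ab$end - ab$start + 1 else 0)
  guard <- 0L
  while (deficit > 0.005 * genome && guard < 1000L) {
    guard <- guard + 1L
    chunk <- min(deficit, 2e6)
    gaps <- free_gaps(ab, chrom_lengths)
    gaps <- gaps[gaps$end - gaps$start + 1 >= chunk, , drop = FALSE]
    if (nrow(gaps) == 0L) {
      gaps <- free_gaps(ab, chrom_lengths)
      if (nrow(gaps) == 0L) break
      chunk <- max(gaps$end - gaps$start + 1)
      gaps <- gaps[gaps$end - gaps$start + 1 >= chunk, , drop = FALSE]
    }
    g <- gaps[sample.int(nrow(gaps), 1L), ]
    off <- sample.int(g$end - g$start + 2 - chunk, 1L) - 1L
    ab <- rbind(ab, data.frame(chrom = g$chrom, start = g$start + off,
                               end = g$start + off + chunk - 1,
                               cn = sample(c(1L, 3L), 1L),
                               stringsAsFactors = FALSE))
    deficit <- deficit - chunk
  }
  segs <- list()
  for (chrom in names(chrom_lengths)) {
    a <- ab[ab$chrom == chrom, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    pos <- 1
    for (i in seq_len(nrow(a))) {
      if (a$start[i] > pos) {
        segs[[length(segs) + 1L]] <- data.frame(
          sample = sample_id, chrom = chrom, start = pos,
          end = a$start[i] - 1, cn = 2L, stringsAsFactors = FALSE)
      }
      segs[[length(segs) + 1L]] <- data.frame(
        sample = sample_id, chrom = chrom, start = a$start[i],
        end = a$end[i], cn = a$cn[i], stringsAsFactors = FALSE)
      pos <- a$end[i] + 1
    }
    if (pos <= chrom_lengths[[chrom]]) {
      segs[[length(segs) + 1L]] <- data.frame(
        sample = sample_id, chrom = chrom, start = pos,
        end = chrom_lengths[[chrom]], cn = 2L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, segs)
}

# Maximal intervals not covered by any aberrant interval, per chromosome.
free_gaps <- function(ab, chrom_lengths) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    a <- ab[ab$chrom == chrom, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    pos <- 1
    for (i in seq_len(nrow(a))) {
      if (a$start[i] > pos) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = a$start[i] - 1,
          stringsAsFactors = FALSE)
      }
      pos <- max(pos, a$end[i] + 1)
    }
    if (pos <= chrom_lengths[[chrom]]) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = chrom_lengths[[chrom]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  do.call(rbind, out)
}

#' Write a synthetic cohort to disk
#'
#' Emits every layer in the formats the pipeline consumes (expression,
#' centroid, beta and detection-p TSVs; SEG-like segments; BED-like CpG and
#' gene annotation, 0-based half-open on disk; sample annotation and
#' signature TSVs; JSON truth record and config) plus a `manifest.json`
#' listing file MD5 hashes, the seed and a config hash. Runs with the same
#' seed produce identical hashes.
#'
#' @param cohort A `synthetic_cohort` object.
#' @param directory Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_matrix_tsv(cohort$expression, p("expression.tsv"), "gene_id")
  write_matrix_tsv(cohort$centroids, p("centroids.tsv"), "gene_id")
  write_matrix_tsv(cohort$betas, p("betas.tsv"), "cpg_id")
  write_matrix_tsv(cohort$detection_p, p("detection_p.tsv"), "cpg_id")
  write_seg(cohort$segments, p("segments.seg"))
  write_bed(cohort$cpg_positions, p("cpg_positions.bed"))
  write_bed(cohort$gene_models, p("gene_models.bed"))
  utils::write.table(cohort$annotations, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$signatures, p("signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(cohort$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("expression.tsv", "centroids.tsv", "betas.tsv",
             "detection_p.tsv", "segments.seg", "cpg_positions.bed",
             "gene_models.bed", "samples.tsv", "signatures.tsv",
             "truth.json", "config.json")
  md5 <- tools::md5sum(file.path(directory, files))
  names(md5) <- files
  manifest <- list(files = as.list(md5), seed = cohort$config$seed,
                   config_hash = unname(md5[["config.json"]]))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a written cohort back from disk
#'
#' Inverse of [write_cohort()] up to text formatting of floating-point
#' values.
#'
#' @param directory Directory written by [write_cohort()].
#' @return List with the same layers as a `synthetic_cohort`.
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  list(expression = read_matrix_tsv(p("expression.tsv")),
       centroids = read_matrix_tsv(p("centroids.tsv")),
       betas = read_matrix_tsv(p("betas.tsv")),
       detection_p = read_matrix_tsv(p("detection_p.tsv")),
       segments = read_seg(p("segments.seg")),
       annotations = read_annotations(p("samples.tsv")),
       cpg_positions = read_bed(p("cpg_positions.bed")),
       gene_models = read_bed(p("gene_models.bed")),
       signatures = read_signature_defs(p("signatures.tsv")),
       truth = jsonlite::read_json(p("truth.json"), simplifyVector = TRUE),
       config = jsonlite::read_json(p("config.json"), simplifyVector = TRUE),
       manifest = jsonlite::read_json(p("manifest.json"),
                                      simplifyVector = TRUE))
}
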