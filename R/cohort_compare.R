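# Subtype-stratified DCIS-vs-IBC group statistics, per-sample summary
# assembly, and pipeline orchestration.

#' Fisher exact test of a categorical distribution between two groups
#'
#' Compares the distribution of one categorical label (e.g. subtype or ER
#' status) between two groups (e.g. tumor types). For 2x2 tables the exact
#' two-sided p sums hypergeometric probabilities of tables at most as
#' probable as the observed one; for 2xK tables the Freeman-Halton exact
#' test is used up to `mc_threshold` total samples and a Monte-Carlo
#' approximation (fixed seed, `b` permutations) beyond that.
#'
#' @param labels_a Categorical vector (e.g. subtype per sample).
#' @param labels_b Grouping vector (e.g. tumor type per sample).
#' @param mc_threshold Largest total n for the 2xK exact test; default 200.
#' @param b Monte-Carlo permutations; default 1e5.
#' @param seed Seed for the Monte-Carlo branch; default 1.
#' @return List with `p_value`, `method`, `table` and group sizes `n`.
#' @export
fisher_exact_distribution <- function(labels_a, labels_b,
                                      mc_threshold = 200L, b = 1e5L,
                                      seed = 1L) {
  ok <- !is.na(labels_a) & !is.na(labels_b)
  tab <- table(labels_a[ok], labels_b[ok])
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need >= 2 categories in each margin")
  }
  n <- sum(tab)
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    ft <- stats::fisher.test(tab)
    method <- "exact"
  } else if (n <= mc_threshold) {
    ft <- stats::fisher.test(tab, workspace = 2e7)
    method <- "exact"
  } else {
    set.seed(seed)
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = b)
    method <- sprintf("monte-carlo (B=%d)", as.integer(b))
  }
  list(p_value = ft$p.value, method = method, table = tab,
       n = colSums(tab))
}

#' Subtype-stratified two-group comparisons of sample features
#'
#' For each subtype and each requested feature, compares the feature values
#' between the two tumor types with a two-sided Mann-Whitney U test (same
#' engine as differential methylation). Subtype x feature cells where
#' either group has fewer than `min_n` non-missing values are skipped with
#' a message. P-values are reported raw: this handful of planned
#' comparisons is not multiplicity-corrected, unlike the genome-wide
#' differential methylation scan.
#'
#' @param summary `data.frame` with one row per sample, containing
#'   `tumor_type`, `subtype` and the feature columns (see
#'   [build_sample_summary()]).
#' @param features Character vector of feature column names to test.
#' @param groups The two tumor-type labels to compare; default
#'   `c("DCIS", "IBC")`.
#' @param min_n Minimum per-group sample count; default 2.
#' @return `data.frame` with feature, subtype, test, u_statistic, p_value,
#'   n_dcis, n_ibc and direction (which group has the larger median).
#' @export
stratified_group_tests <- function(summary, features,
                                   groups = c("DCIS", "IBC"), min_n = 2L) {
  bad <- setdiff(features, names(summary))
  if (length(bad)) {
    stop("unknown feature(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(names(summary), collapse = ", "))
  }
  out <- list()
  for (st in unique(summary$subtype[!is.na(summary$subtype)])) {
    for (f in features) {
      x <- summary[[f]][summary$subtype %in% st &
                          summary$tumor_type == groups[1]]
      y <- summary[[f]][summary$subtype %in% st &
                          summary$tumor_type == groups[2]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < min_n || length(y) < min_n) {
        message("skipping ", f, " in subtype ", st,
                ": fewer than ", min_n, " values per group")
        next
      }
      mw <- mann_whitney(x, y)
      mx <- stats::median(x); my <- stats::median(y)
      direction <- if (mx > my) groups[1] else if (my > mx) groups[2] else
        "none"
      out[[length(out) + 1L]] <- data.frame(
        feature = f, subtype = st, test = paste("mann-whitney", mw$method),
        u_statistic = mw$u, p_value = mw$p,
        n_dcis = length(x), n_ibc = length(y), direction = direction,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no subtype x feature cell had enough samples")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the per-sample summary table
#'
#' Outer-joins all computed layers on `sample_id` into one row per sample:
#' annotations, subtype calls (with per-subtype correlations and core-basal
#' flag), receptor calls, signature scores, GII, HER2 copy number and the
#' window mean-Z score. Samples absent from a layer keep `NA` in that
#' layer's columns (with a warning when layers disagree on the sample set);
#' duplicate sample ids within a layer are an error. Rows are ordered by
#' subtype (in `subtype_order`) and, within a subtype, by decreasing
#' correlation to the sample's own subtype.
#'
#' @param calls Subtype calls from [assign_subtype()] /
#'   [call_core_basal()].
#' @param annotations Sample annotation `data.frame` (sample_id,
#'   tumor_type, purity, ...).
#' @param receptor Optional receptor-call `data.frame`s, named by gene, as
#'   from [call_receptor_status()] (list or single `data.frame`).
#' @param scores Optional signature score table from [score_signatures()].
#' @param gii Optional GII table from [genomic_instability_index()].
#' @param her2_cn Optional named vector of HER2 (ERBB2 locus) copy numbers.
#' @param window_scores Optional window score table from [window_mean_z()].
#' @param subtype_order Display order of subtypes; default Basal, Her2,
#'   LumA, LumB.
#' @return Sorted `data.frame`, one row per sample.
#' @export
build_sample_summary <- function(calls, annotations = NULL, receptor = NULL,
                                 scores = NULL, gii = NULL, her2_cn = NULL,
                                 window_scores = NULL,
                                 subtype_order = c("Basal", "Her2",
                                                   "LumA", "LumB")) {
  if (anyDuplicated(calls$sample_id)) stop("duplicate sample ids in calls")
  out <- calls
  merge_layer <- function(out, layer, name) {
    if (is.null(layer)) return(out)
    if (anyDuplicated(layer$sample_id)) {
      stop("duplicate sample ids in ", name, " layer")
    }
    extra <- setdiff(layer$sample_id, out$sample_id)
    missing <- setdiff(out$sample_id, layer$sample_id)
    if (length(extra) || length(missing)) {
      warning(name, " layer and summary disagree on ",
              length(extra) + length(missing), " sample id(s)")
    }
    merge(out, layer, by = "sample_id", all = TRUE)
  }
  out <- merge_layer(out, annotations, "annotation")
  if (!is.null(receptor)) {
    if (is.data.frame(receptor)) receptor <- list(receptor)
    for (rc in receptor) {
      g <- rc$gene[1]
      slim <- data.frame(sample_id = rc$sample_id, stringsAsFactors = FALSE)
      slim[[paste0(g, "_status")]] <- rc$status
      out <- merge_layer(out, slim, paste0(g, " receptor"))
    }
  }
  out <- merge_layer(out, scores, "signature-score")
  if (!is.null(gii)) {
    out <- merge_layer(out, gii[, c("sample_id", "gii")], "GII")
  }
  if (!is.null(her2_cn)) {
    out <- merge_layer(out, data.frame(sample_id = names(her2_cn),
                                       her2_cn = as.numeric(her2_cn),
                                       stringsAsFactors = FALSE), "HER2 CN")
  }
  if (!is.null(window_scores)) {
    slim <- data.frame(sample_id = window_scores$sample_id,
                       window_mean_z = window_scores$mean_z,
                       stringsAsFactors = FALSE)
    out <- merge_layer(out, slim, "window-score")
  }
  own_cor <- vapply(seq_len(nrow(out)), function(i) {
    st <- out$subtype[i]
    col <- paste0("cor_", st)
    if (is.na(st) || !col %in% names(out)) NA_real_ else out[[col]][i]
  }, numeric(1))
  st_rank <- match(out$subtype, subtype_order)
  st_rank[is.na(st_rank)] <- length(subtype_order) + 1L
  out <- out[order(st_rank, -own_cor, out$sample_id, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Run the full subtype-stratified comparison pipeline
#'
#' Orchestrates every stage on either a synthetic cohort (generated from
#' `synthetic:` parameters in the config) or on-disk inputs (`inputs:`
#' paths): receptor calling from ESR1/PGR, balanced centering and centroid
#' subtyping with core-basal flags, signature scores, gene copy number and
#' GII, methylation QC / imputation / profiles / differential methylation /
#' window scores, the Fisher and stratified Mann-Whitney comparisons, and
#' the per-sample summary. Stages whose input layer is absent are reported
#' as "skipped". Writes TSV outputs plus a JSON run report (seed,
#' parameters, QC counts, stage status) to `outdir`; identical config and
#' seed give byte-identical outputs.
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#'   Keys: `seed`, `outdir`, optional `synthetic` (cohort_config
#'   overrides), optional `inputs` (paths per layer), optional `options`
#'   (w_pos, core_basal_threshold, flank_bp, fdr_alpha,
#'   effect_top_fraction, knn_k, detection_p_threshold, cpg_fail_fraction,
#'   quantile_normalize, window).
#' @param outdir Output directory; overrides the config's `outdir`.
#' @return The output directory, invisibly; side effect: TSVs and
#'   `report.json` in `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- if (!is.null(outdir)) outdir else config$outdir
  if (is.null(outdir)) stop("no output directory configured")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  opt <- config$options
  getopt <- function(name, default) {
    if (is.null(opt[[name]])) default else opt[[name]]
  }
  report <- list(seed = seed, parameters = opt, stages = list(), qc = list())
  fail <- function(stage, e) {
    report$stages[[stage]] <<- paste("failed:", conditionMessage(e))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  }

  ## ---- load or simulate inputs --------------------------------------
  layers <- list()
  if (!is.null(config$synthetic)) {
    cfg_args <- config$synthetic
    cfg_args$seed <- seed
    cohort <- generate_cohort(do.call(cohort_config, cfg_args))
    layers <- cohort[c("expression", "centroids", "betas", "detection_p",
                       "segments", "annotations", "cpg_positions",
                       "gene_models", "signatures", "window")]
    report$stages$simulate <- "ok"
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    rd <- function(path, reader) if (is.null(path)) NULL else reader(path)
    layers$expression <- rd(inp$expression, read_matrix_tsv)
    layers$centroids <- rd(inp$centroids, read_matrix_tsv)
    layers$betas <- rd(inp$betas, read_matrix_tsv)
    layers$detection_p <- rd(inp$detection_p, read_matrix_tsv)
    layers$segments <- rd(inp$segments, read_seg)
    layers$annotations <- rd(inp$annotations, read_annotations)
    layers$cpg_positions <- rd(inp$cpg_positions, read_bed)
    layers$gene_models <- rd(inp$gene_models, read_bed)
    layers$signatures <- rd(inp$signatures, read_signature_defs)
    layers$window <- getopt("window", NULL)
    report$stages$load <- "ok"
  } else {
    stop("config must provide either 'synthetic' parameters or 'inputs'")
  }
  if (is.null(layers$expression)) stop("expression layer is required")
  ann <- layers$annotations
  tumor_ids <- if (!is.null(ann)) {
    ann$sample_id[ann$tumor_type %in% c("DCIS", "IBC")]
  } else colnames(layers$expression)
  expr <- layers$expression[, intersect(colnames(layers$expression),
                                        tumor_ids), drop = FALSE]

  ## ---- expression prep ----------------------------------------------
  calls <- NULL; receptor <- NULL
  tryCatch({
    if (isTRUE(getopt("quantile_normalize", FALSE))) {
      expr <- quantile_normalize(expr)
    }
    er <- call_receptor_status(expr["ESR1", ], gene = "ESR1")
    receptor <- list(er)
    if ("PGR" %in% rownames(expr)) {
      receptor$pgr <- call_receptor_status(expr["PGR", ], gene = "PGR")
    }
    report$stages$expression_prep <- "ok"
  }, error = function(e) fail("expression_prep", e))

  ## ---- subtyping -----------------------------------------------------
  tryCatch({
    er_status <- stats::setNames(receptor[[1]]$status,
                                 receptor[[1]]$sample_id)
    centered <- balanced_center(expr, er_status,
                                w_pos = getopt("w_pos", 0.6))
    calls <- assign_subtype(centered$matrix, layers$centroids)
    calls <- call_core_basal(calls,
                             threshold = getopt("core_basal_threshold", 0.6),
                             basal = getopt("basal_name", "Basal"))
    report$stages$subtyping <- "ok"
  }, error = function(e) fail("subtyping", e))
  subtype_of <- stats::setNames(calls$subtype, calls$sample_id)

  ## ---- signatures ----------------------------------------------------
  scores <- NULL
  if (!is.null(layers$signatures)) {
    tryCatch({
      z <- zscore_by_gene(expr)
      scores <- score_signatures(z, layers$signatures)
      report$stages$signatures <- "ok"
    }, error = function(e) fail("signatures", e))
  } else report$stages$signatures <- "skipped"

  ## ---- copy number ---------------------------------------------------
  gii <- NULL; her2 <- NULL; cn_tab <- NULL
  if (!is.null(layers$segments)) {
    tryCatch({
      gii <- genomic_instability_index(layers$segments)
      if (!is.null(layers$gene_models)) {
        cn_tab <- suppressMessages(
          gene_copy_number(layers$segments, layers$gene_models))
        her2_gene <- getopt("her2_gene", "ERBB2")
        if (her2_gene %in% rownames(cn_tab)) {
          her2 <- cn_tab[her2_gene, ]
        }
      }
      report$stages$copy_number <- "ok"
    }, error = function(e) fail("copy_number", e))
  } else report$stages$copy_number <- "skipped"

  ## ---- methylation ---------------------------------------------------
  diffmeth <- NULL; wsc <- NULL
  if (!is.null(layers$betas)) {
    tryCatch({
      b <- layers$betas
      if (!is.null(layers$detection_p)) {
        b <- qc_mask(b, layers$detection_p,
                     getopt("detection_p_threshold", 0.05))
        report$qc$masked_beta_fraction <-
          unname(attr(b, "masked")["fraction"])
      }
      b <- qc_filter_cpgs(b, getopt("cpg_fail_fraction", 0.25))
      report$qc$cpgs_retained <- nrow(b)
      report$qc$cpgs_dropped <- length(attr(b, "dropped"))
      b <- knn_impute(b, k = getopt("knn_k", 10L))
      if (!is.null(layers$gene_models) && !is.null(layers$cpg_positions)) {
        prof <- suppressWarnings(gene_methylation_profile(
          b, layers$cpg_positions, layers$gene_models,
          flank_bp = getopt("flank_bp", 50000)))
        meth_tumors <- intersect(colnames(prof$profile), tumor_ids)
        tt <- stats::setNames(ann$tumor_type, ann$sample_id)
        diffmeth <- suppressMessages(differential_methylation(
          prof$profile[, meth_tumors, drop = FALSE],
          tt[meth_tumors], subtype_of[meth_tumors],
          fdr_alpha = getopt("fdr_alpha", 0.05),
          effect_top_fraction = getopt("effect_top_fraction", 0.20)))
      }
      if (!is.null(layers$window) && !is.null(layers$cpg_positions)) {
        # pooled Z over all samples with methylation: tumors and normals
        wsc <- suppressWarnings(
          window_mean_z(b, layers$cpg_positions, layers$window))
      }
      report$stages$methylation <- "ok"
    }, error = function(e) fail("methylation", e))
  } else report$stages$methylation <- "skipped"

  ## ---- comparisons ---------------------------------------------------
  summary_tab <- NULL; group_tests <- NULL; fisher_tests <- NULL
  tryCatch({
    ann_cols <- intersect(c("sample_id", "tumor_type", "purity"),
                          names(ann))
    summary_tab <- suppressWarnings(build_sample_summary(
      calls,
      annotations = if (!is.null(ann)) ann[ann$sample_id %in% tumor_ids,
                                           ann_cols, drop = FALSE],
      receptor = receptor, scores = scores, gii = gii, her2_cn = her2,
      window_scores = wsc,
      subtype_order = colnames(layers$centroids)))
    feats <- intersect(c("purity", "gii",
                         if (!is.null(scores))
                           setdiff(names(scores), "sample_id"),
                         "window_mean_z"),
                       names(summary_tab))
    group_tests <- suppressMessages(
      stratified_group_tests(summary_tab, feats))
    tt <- summary_tab$tumor_type
    fisher_tests <- data.frame(
      comparison = c("subtype_distribution", "er_distribution"),
      p_value = c(
        fisher_exact_distribution(summary_tab$subtype, tt, seed = seed)$p_value,
        fisher_exact_distribution(summary_tab$ESR1_status, tt,
                                  seed = seed)$p_value),
      stringsAsFactors = FALSE)
    report$stages$comparisons <- "ok"
  }, error = function(e) fail("comparisons", e))

  ## ---- write outputs -------------------------------------------------
  wt <- function(df, file) {
    if (is.null(df)) return()
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(calls, "subtype_calls.tsv")
  wt(scores, "signature_scores.tsv")
  wt(gii, "gii.tsv")
  wt(diffmeth, "differential_methylation.tsv")
  wt(wsc, "window_scores.tsv")
  wt(summary_tab, "sample_summary.tsv")
  wt(group_tests, "group_tests.tsv")
  wt(fisher_tests, "fisher_tests.tsv")
  report$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
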