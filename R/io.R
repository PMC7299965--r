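# Readers and writers for the plain-text formats the pipeline consumes.
# Convention, declared once and enforced here: genomic intervals are 1-based
# and inclusive in memory; BED-like files are 0-based half-open on disk and
# converted on read/write. SEG-like files are read as written (1-based).

#' Read a numeric matrix from a TSV file
#'
#' Expects the identifier (gene or CpG) in the first column and one column
#' per sample, with a header row of sample ids. Used for expression,
#' beta-value, detection p-value and centroid matrices.
#'
#' @param path Path to a tab-delimited file.
#' @return Numeric matrix with row names taken from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("matrix TSV needs an id column plus at least one sample column: ", path)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a numeric matrix to a TSV file
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_name Header for the identifier column.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "gene_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segmented copy-number data (SEG-like TSV)
#'
#' Columns (header required): sample, chrom, start, end, cn. Coordinates are
#' 1-based inclusive as written. Validates per-sample, per-chromosome
#' non-overlap and sorts segments by sample, chromosome and start.
#'
#' @param path Path to the SEG-like file.
#' @return `data.frame` with columns sample, chrom, start, end, cn.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_segments(df)
}

#' @rdname read_seg
#' @param segments Segment `data.frame` as returned by [read_seg()].
#' @export
write_seg <- function(segments, path) {
  segments <- validate_segments(segments)
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a segment table
#'
#' Checks column presence, coordinate sanity (end >= start, integer cn >= 0)
#' and per-sample, per-chromosome non-overlap; returns the table sorted.
#'
#' @param segments `data.frame` with sample, chrom, start, end, cn.
#' @export
validate_segments <- function(segments) {
  need <- c("sample", "chrom", "start", "end", "cn")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segment table lacks column(s): ",
                         paste(miss, collapse = ", "))
  segments <- segments[, need]
  if (any(segments$end < segments$start)) stop("segment with end < start")
  if (any(segments$cn < 0) || any(segments$cn != round(segments$cn))) {
    stop("copy numbers must be non-negative integers")
  }
  o <- order(segments$sample, segments$chrom, segments$start)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  by_sc <- split(segments, list(segments$sample, segments$chrom), drop = TRUE)
  for (s in by_sc) {
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
      stop("overlapping segments for sample ", s$sample[1L],
           " on ", s$chrom[1L])
    }
  }
  segments
}

#' Read a BED-like interval file
#'
#' On disk: chrom, start, end, name (no header), 0-based half-open. In
#' memory: 1-based inclusive, so `start` gains 1.
#'
#' @param path Path to the BED-like file.
#' @return `data.frame` with columns chrom, start, end, name (1-based
#'   inclusive).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED-like file needs chrom, start, end, name: ", path)
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "name")
  df$start <- df$start + 1L
  if (any(df$end < df$start)) stop("invalid interval in ", path)
  df
}

#' @rdname read_bed
#' @param intervals `data.frame` with chrom, start, end, name, 1-based
#'   inclusive.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(intervals)))
  out <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end,
                    name = intervals$name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with header; must contain `sample_id` and `tumor_type`
#' (DCIS/IBC/NORMAL); other columns (subtype truth, ER status, purity) pass
#' through.
#'
#' @param path Path to the annotation TSV.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tumor_type") %in% names(df))) {
    stop("annotation table needs sample_id and tumor_type columns")
  }
  bad <- setdiff(unique(df$tumor_type), c("DCIS", "IBC", "NORMAL"))
  if (length(bad)) stop("unknown tumor_type value(s): ",
                        paste(bad, collapse = ", "))
  df
}

#' Read gene-signature definitions
#'
#' TSV with header columns signature, gene_id, weight. Weights are typically
#' +1/-1 but any real weight is accepted.
#'
#' @param path Path to the signature TSV.
#' @return `data.frame` with columns signature, gene_id, weight.
#' @export
read_signature_defs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("signature", "gene_id", "weight") %in% names(df))) {
    stop("signature file needs columns signature, gene_id, weight")
  }
  df$weight <- as.numeric(df$weight)
  df
}
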