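# Normalization chain: M-A transform per array, within-array loess
# normalization of M on A, across-array quantile normalization of M,
# duplicate-probe averaging, and an optional variance filter. The stage
# order is fixed and mirrors standard two-color practice.

#' Compute M and A values for one array
#'
#' `M = log2(red) - log2(green)` (log2 test/reference fold difference) and
#' `A = (log2(red) + log2(green)) / 2` (average log2 spot intensity).
#'
#' @param array an [intensity_array()].
#' @return A `data.frame` with columns `probe_id`, `gene_id`, `M`, `A`.
#' @export
compute_ma <- function(array) {
  stopifnot(inherits(array, "intensity_array"))
  lr <- log2(array$red_signal)
  lg <- log2(array$green_signal)
  data.frame(probe_id = array$probe_id, gene_id = array$gene_id,
             M = lr - lg, A = (lr + lg) / 2, stringsAsFactors = FALSE)
}

#' Within-array loess normalization of M on A
#'
#' Fits a locally weighted degree-1 polynomial regression of M on A
#' (tricube weights, `span` fraction of points per local fit, `iterations`
#' robustifying iterations — `stats::lowess`) and returns the residuals
#' `M - fit(A)`. This removes smooth intensity-dependent dye bias while
#' leaving probe-specific signal untouched.
#'
#' @param M,A numeric vectors of equal length (>= 10 spots).
#' @param span fraction of points used in each local fit.
#' @param iterations number of robustifying iterations.
#' @return Normalized M values (numeric vector).
#' @export
loess_normalize_array <- function(M, A, span = 0.3, iterations = 4L) {
  if (length(M) != length(A))
    stop_fmt("M and A must have equal length (got %d and %d)",
             length(M), length(A))
  if (length(M) < 10L)
    stop_fmt("loess normalization needs at least 10 spots, got %d",
             length(M))
  assert_number(span, "span", 0, 1, open_min = TRUE)
  if (!all(is.finite(M)) || !all(is.finite(A)))
    stop_fmt("M and A must be finite")
  if (diff(range(A)) < .Machine$double.eps^0.5) {
    warn_fmt("constant A values: subtracting mean(M) instead of a loess fit")
    return(M - mean(M))
  }
  fit <- stats::lowess(A, M, f = span, iter = iterations)
  fitted <- stats::approx(fit$x, fit$y, xout = A, rule = 2,
                          ties = mean)$y
  M - fitted
}

#' Quantile normalization across arrays
#'
#' Standard quantile normalization of a complete probes-by-samples matrix:
#' each column's sorted values are replaced by the row means of the
#' column-sorted matrix, so every column ends with an identical empirical
#' distribution. Ties within a column receive the mean of the reference
#' values they span (`limma::normalizeQuantiles` with `ties = TRUE`).
#'
#' @param mat complete numeric matrix with >= 2 columns.
#' @return The normalized matrix, dimnames preserved.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L)
    stop_fmt("quantile normalization needs at least 2 columns")
  if (anyNA(mat))
    stop_fmt("quantile normalization requires a complete matrix (NAs found)")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Average on-array duplicate probes
#'
#' Rows sharing a probe id are replaced by their arithmetic mean per
#' sample. Output rows are sorted by probe id and unique.
#'
#' @param mat numeric matrix (spots x samples).
#' @param probe_ids character vector of probe ids per row; defaults to
#'   `rownames(mat)`.
#' @return Matrix with one row per unique probe id.
#' @export
average_duplicates <- function(mat, probe_ids = rownames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(probe_ids) || length(probe_ids) != nrow(mat))
    stop_fmt("'probe_ids' must supply one id per matrix row")
  sums <- rowsum(mat, group = probe_ids, reorder = TRUE)
  counts <- as.vector(table(probe_ids)[rownames(sums)])
  sums / counts
}

#' Keep the most variable probes
#'
#' Ranks probes by variance across all samples (descending, ties broken by
#' probe id in lexicographic order) and keeps the top
#' `ceiling(keep_fraction * n)` probes, preserving the original row order.
#'
#' @param x an `expr_matrix` or a numeric matrix with probe-id rownames.
#' @param keep_fraction fraction of probes to keep, in (0, 1].
#' @return Object of the same type with the retained probes.
#' @export
variance_filter <- function(x, keep_fraction) {
  assert_number(keep_fraction, "keep_fraction", 0, 1, open_min = TRUE)
  if (inherits(x, "expr_matrix")) {
    keep <- variance_filter_idx(x$M, keep_fraction)
    return(expression_matrix(x$M[keep, , drop = FALSE],
                             x$A[keep, , drop = FALSE],
                             x$samples, x$genes[keep, , drop = FALSE]))
  }
  mat <- as.matrix(x)
  mat[variance_filter_idx(mat, keep_fraction), , drop = FALSE]
}

variance_filter_idx <- function(mat, keep_fraction) {
  if (keep_fraction == 1) return(seq_len(nrow(mat)))
  v <- row_vars(mat)
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  ord <- order(-v, ids)
  sort(ord[seq_len(ceiling(keep_fraction * nrow(mat)))])
}

#' Normalized expression matrix with sample metadata
#'
#' Container for the pipeline's working data: a probes-by-samples matrix of
#' normalized M values, the matching matrix of A values (kept for meanA
#' summaries), the sample sheet, and the probe-to-gene map.
#'
#' @param M,A numeric matrices with identical dimensions, unique probe-id
#'   rownames, and sample-id colnames in sample-sheet order.
#' @param samples sample sheet `data.frame` (see [read_sample_sheet()]).
#' @param genes `data.frame` with columns `probe_id`, `gene_id`, aligned
#'   with the matrix rows.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(M, A, samples, genes) {
  M <- as.matrix(M); A <- as.matrix(A)
  if (!identical(dim(M), dim(A)))
    stop_fmt("M and A must have identical dimensions")
  if (anyNA(M) || anyNA(A))
    stop_fmt("expression matrix must be complete (NAs found)")
  if (is.null(rownames(M)) || anyDuplicated(rownames(M)))
    stop_fmt("M must have unique probe-id rownames")
  if (!identical(colnames(M), samples$sample_id))
    stop_fmt("column order must match the sample sheet")
  if (!identical(genes$probe_id, rownames(M)))
    stop_fmt("gene map must align with matrix rows")
  structure(list(M = M, A = A, samples = samples, genes = genes),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$M)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%d platforms, %d donors)\n",
              nrow(x$M), ncol(x$M), length(unique(x$samples$platform)),
              length(unique(x$samples$donor_id))))
  invisible(x)
}

#' Run the full normalization chain on a set of arrays
#'
#' Fixed stage order: M-A computation per array, within-array loess
#' normalization of M on A, across-array quantile normalization of M,
#' duplicate-probe averaging (of both M and A), then an optional variance
#' filter. A values are not quantile normalized; they are carried along for
#' meanA summaries and diagnostics.
#'
#' @param arrays list of [intensity_array()] objects, one per sample in the
#'   sheet (matched by their `sample_id` attribute). All arrays must share
#'   the same spot layout (identical probe-id sequence).
#' @param sheet sample sheet `data.frame`.
#' @param span,iterations loess parameters, see [loess_normalize_array()].
#' @param keep_fraction optional variance filter; 1 (default) keeps all
#'   probes.
#' @param quantile apply across-array quantile normalization (default TRUE).
#' @return An [expression_matrix()].
#' @export
normalize_experiment <- function(arrays, sheet, span = 0.3, iterations = 4L,
                                 keep_fraction = 1, quantile = TRUE) {
  ids <- vapply(arrays, function(a) attr(a, "sample_id") %||% NA_character_,
                character(1L))
  if (anyNA(ids)) stop_fmt("every array needs a sample_id attribute")
  missing <- setdiff(sheet$sample_id, ids)
  if (length(missing))
    stop_fmt("no intensity array for sample(s): %s",
             paste(missing, collapse = ", "))
  arrays <- arrays[match(sheet$sample_id, ids)]

  ref_probes <- arrays[[1L]]$probe_id
  for (a in arrays)
    if (!identical(a$probe_id, ref_probes))
      stop_fmt("array '%s' has a different spot layout than '%s'",
               attr(a, "sample_id"), attr(arrays[[1L]], "sample_id"))

  mas <- lapply(arrays, compute_ma)
  Mn <- vapply(mas, function(ma)
    loess_normalize_array(ma$M, ma$A, span = span, iterations = iterations),
    numeric(length(ref_probes)))
  Amat <- vapply(mas, function(ma) ma$A, numeric(length(ref_probes)))
  colnames(Mn) <- colnames(Amat) <- sheet$sample_id

  if (quantile && ncol(Mn) >= 2L) Mn <- quantile_normalize(Mn)

  M <- average_duplicates(Mn, ref_probes)
  A <- average_duplicates(Amat, ref_probes)
  gene_map <- unique(data.frame(probe_id = ref_probes,
                                gene_id = arrays[[1L]]$gene_id,
                                stringsAsFactors = FALSE))
  gene_map <- gene_map[order(gene_map$probe_id), , drop = FALSE]
  if (anyDuplicated(gene_map$probe_id))
    stop_fmt("a probe id maps to more than one gene id")
  rownames(gene_map) <- NULL

  x <- expression_matrix(M, A, sheet, gene_map)
  if (keep_fraction < 1) x <- variance_filter(x, keep_fraction)
  x
}
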