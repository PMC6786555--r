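# Per-platform concordance: pairwise Pearson correlations between samples,
# the within-donor vs across-donor signal-to-noise ratio, and sample PCA.
#
# The S/N statistic is the ratio of the two means (mean within-donor pair
# correlation divided by mean across-donor pair correlation), not the mean
# of per-pair ratios: >1 means individual identity is detectable above
# technical noise.

#' Pairwise sample correlations within a platform
#'
#' Pearson (or Spearman) correlation of probe M values for every pair of
#' samples belonging to one platform.
#'
#' @param x an [expression_matrix()].
#' @param platform platform name present in the sample sheet.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix over the platform's samples.
#' @export
pairwise_sample_correlations <- function(x, platform,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"))
  sids <- x$samples$sample_id[x$samples$platform == platform]
  if (length(sids) < 2L)
    stop_fmt("platform '%s' has %d sample(s); need at least 2",
             platform, length(sids))
  sub <- x$M[, sids, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  flat <- colnames(sub)[sds < .Machine$double.eps^0.5]
  if (length(flat))
    stop_fmt("zero-variance sample(s) in platform '%s': %s",
             platform, paste(flat, collapse = ", "))
  stats::cor(sub, method = method)
}

#' Within/across-donor signal-to-noise ratio for one platform
#'
#' Averages the correlation over all unordered sample pairs sharing a donor
#' (within) and over all unordered pairs with different donors (across),
#' and reports their ratio. Pairs are restricted to the platform the
#' correlation matrix was computed on.
#'
#' @param corr correlation matrix from [pairwise_sample_correlations()].
#' @param sheet sample sheet covering the matrix's samples.
#' @param platform platform label recorded in the result.
#' @return One-row `data.frame` with columns `platform`,
#'   `mean_within_donor_correlation`, `mean_across_donor_correlation`,
#'   `sn_ratio`, `n_within_pairs`, `n_across_pairs`.
#' @export
signal_to_noise <- function(corr, sheet, platform) {
  samples <- rownames(corr)
  if (is.null(samples) || !identical(samples, colnames(corr)))
    stop_fmt("'corr' must be a correlation matrix with sample dimnames")
  donors <- sheet$donor_id[match(samples, sheet$sample_id)]
  if (anyNA(donors))
    stop_fmt("sample(s) missing from the sheet: %s",
             paste(samples[is.na(donors)], collapse = ", "))
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  same <- donors[ut[, 1L]] == donors[ut[, 2L]]
  if (!any(same))
    stop_fmt("platform '%s' has no within-donor pair (need >= 2 replicates for >= 1 donor)",
             platform)
  if (all(same))
    stop_fmt("platform '%s' has no across-donor pair (need >= 2 donors)",
             platform)
  r <- corr[ut]
  mw <- mean(r[same])
  ma <- mean(r[!same])
  data.frame(platform = platform,
             mean_within_donor_correlation = mw,
             mean_across_donor_correlation = ma,
             sn_ratio = mw / ma,
             n_within_pairs = sum(same),
             n_across_pairs = sum(!same),
             stringsAsFactors = FALSE)
}

#' Concordance table over all platforms
#'
#' Convenience wrapper computing [pairwise_sample_correlations()] and
#' [signal_to_noise()] for every platform in the sample sheet.
#'
#' @param x an [expression_matrix()].
#' @param method correlation method, see [pairwise_sample_correlations()].
#' @return `data.frame` with one row per platform.
#' @export
concordance_table <- function(x, method = "pearson") {
  platforms <- unique(x$samples$platform)
  out <- do.call(rbind, lapply(platforms, function(p) {
    signal_to_noise(pairwise_sample_correlations(x, p, method = method),
                    x$samples, p)
  }))
  rownames(out) <- NULL
  out
}

#' Principal component analysis of samples
#'
#' Samples are observations and probes variables; probes are centered but
#' not scaled to unit variance (M values already share a common scale after
#' quantile normalization). Scores come from the singular value
#' decomposition of the centered matrix.
#'
#' @param x an [expression_matrix()].
#' @param n_components number of components to return; default all
#'   `min(dim)` available.
#' @return Object of class `pca_result`: list with `scores` (samples x
#'   components), `explained_variance` (fractions, non-increasing, summing
#'   to 1 over all components), `sdev`, and `n_components`.
#' @export
pca_samples <- function(x, n_components = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$M) < 2L) stop_fmt("PCA needs at least 2 samples")
  k_max <- min(dim(x$M))
  n_components <- n_components %||% k_max
  n_components <- assert_count(n_components, "n_components")
  if (n_components > k_max)
    stop_fmt("n_components (%d) exceeds min(dim) = %d", n_components, k_max)
  pr <- stats::prcomp(t(x$M), center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x[, seq_len(n_components), drop = FALSE],
                 explained_variance = ev,
                 sdev = pr$sdev,
                 n_components = n_components),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components kept (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), x$n_components,
              100 * x$explained_variance[1L],
              100 * (x$explained_variance[2L] %||% NA_real_)))
  invisible(x)
}

#' Scatter plot of PCA scores colored by donor, shaped by platform
#'
#' @param pca a `pca_result` from [pca_samples()].
#' @param sheet sample sheet covering the scored samples.
#' @param components which two components to plot.
#' @param file optional output path (`.png`, `.svg` or `.pdf`); plots to
#'   the active device when `NULL`.
#' @return Invisibly, the plotted score matrix.
#' @export
plot_pca <- function(pca, sheet, components = c(1L, 2L), file = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  if (max(components) > ncol(pca$scores))
    stop_fmt("requested component beyond the %d kept", ncol(pca$scores))
  sc <- pca$scores[, components, drop = FALSE]
  donors <- factor(sheet$donor_id[match(rownames(sc), sheet$sample_id)])
  plats <- factor(sheet$platform[match(rownames(sc), sheet$sample_id)])
  if (!is.null(file)) open_device(file)
  graphics::plot(sc[, 1L], sc[, 2L],
                 col = as.integer(donors), pch = as.integer(plats),
                 xlab = sprintf("PC%d (%.1f%%)", components[1L],
                                100 * pca$explained_variance[components[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2L],
                                100 * pca$explained_variance[components[2L]]),
                 main = "Sample PCA of normalized M values")
  graphics::legend("topright", legend = levels(plats),
                   pch = seq_along(levels(plats)), bty = "n", cex = 0.8)
  if (!is.null(file)) grDevices::dev.off()
  invisible(sc)
}

open_device <- function(file) {
  ext <- tolower(sub(".*\\.", "", file))
  switch(ext,
         png = grDevices::png(file, width = 900, height = 700),
         svg = grDevices::svg(file, width = 8, height = 6),
         pdf = grDevices::pdf(file, width = 8, height = 6),
         stop_fmt("unsupported figure format '.%s' (use png, svg or pdf)",
                  ext))
}
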