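# Gene selection rules (top-variance genes; genes relatively higher in one
# platform) and a local hypergeometric over-representation test with
# Benjamini-Hochberg FDR. This is a plain hypergeometric tail, not DAVID's
# modified Fisher (EASE) score, so FDRs from DAVID-based analyses are not
# expected to match numerically.

#' Select the most variable genes within a platform
#'
#' Probes are collapsed to genes (`collapse = "max"`: the most variable
#' probe represents the gene; `"mean"` averages probe variances), genes are
#' ranked by within-donor variance descending with boundary ties broken by
#' gene id in lexicographic order, and the top `ceiling(fraction * n)`
#' genes are returned in rank order.
#'
#' @param metrics output of [within_platform_metrics()] for one platform.
#' @param fraction fraction of genes to select, in (0, 1).
#' @param collapse probe-to-gene collapse rule, `"max"` (default) or
#'   `"mean"`.
#' @return Character vector of selected gene ids, most variable first.
#' @export
select_top_variance_genes <- function(metrics, fraction = 0.05,
                                      collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  assert_number(fraction, "fraction", 0, 1, open_min = TRUE, open_max = TRUE)
  fun <- if (collapse == "max") max else mean
  gene_var <- tapply(metrics$Var, metrics$gene_id, fun)
  ids <- names(gene_var)
  ord <- order(-as.numeric(gene_var), ids)
  n_top <- ceiling(fraction * length(ids))
  ids[ord[seq_len(n_top)]]
}

#' Genes relatively higher in one platform than another
#'
#' From per-probe paired tests ([cross_platform_test()]): probes are
#' collapsed to genes by their most significant probe (ties broken by probe
#' id), genes with p < `alpha` are kept and partitioned by the sign of the
#' mean paired difference.
#'
#' @param cross output of [cross_platform_test()].
#' @param alpha significance threshold on the per-gene p-value.
#' @return List with `higher_in_a`, `higher_in_b` (character vectors of
#'   gene ids) and the platform names.
#' @export
select_platform_higher_genes <- function(cross, alpha = 0.05) {
  assert_number(alpha, "alpha", 0, 1, open_min = TRUE)
  ord <- order(cross$pval, cross$probe_id)
  best <- cross[ord[!duplicated(cross$gene_id[ord])], , drop = FALSE]
  sig <- best[best$pval < alpha, , drop = FALSE]
  list(higher_in_a = sort(sig$gene_id[sig$mean_diff > 0]),
       higher_in_b = sort(sig$gene_id[sig$mean_diff < 0]),
       platform_a = cross$platform_a[1L],
       platform_b = cross$platform_b[1L])
}

#' Hypergeometric gene-set over-representation test
#'
#' For each set: one-sided tail probability `P(X >= overlap)` with
#' `X ~ Hypergeometric(universe, set-in-universe, selected)`, then
#' Benjamini-Hochberg FDR across all tested sets. Fold enrichment is
#' `(overlap / selected) / (set-in-universe / universe)`.
#'
#' @param selected character vector of selected gene ids (subset of
#'   `universe`).
#' @param universe character vector of all measured gene ids.
#' @param sets a [gene_sets()] collection; sets are intersected with the
#'   universe before testing.
#' @return `data.frame` sorted by p-value with columns `set`,
#'   `description`, `universe_size`, `set_in_universe`, `selected_size`,
#'   `overlap`, `fold_enrichment`, `pval`, `fdr`.
#' @export
overrepresentation_test <- function(selected, universe, sets) {
  stopifnot(inherits(sets, "gene_sets"))
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (!length(universe)) stop_fmt("empty universe")
  if (!length(selected)) stop_fmt("empty selection")
  outside <- setdiff(selected, universe)
  if (length(outside))
    stop_fmt("selected gene(s) not in the universe: %s",
             paste(utils::head(outside, 5L), collapse = ", "))
  N <- length(universe)
  n_sel <- length(selected)
  rows <- lapply(names(sets$sets), function(nm) {
    in_univ <- intersect(sets$sets[[nm]], universe)
    K <- length(in_univ)
    k <- length(intersect(in_univ, selected))
    p <- stats::phyper(k - 1, K, N - K, n_sel, lower.tail = FALSE)
    fold <- if (K > 0) (k / n_sel) / (K / N) else NA_real_
    data.frame(set = nm, description = sets$description[[nm]],
               universe_size = N, set_in_universe = K,
               selected_size = n_sel, overlap = k,
               fold_enrichment = fold, pval = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pval, method = "BH")
  out <- out[order(out$pval, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
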