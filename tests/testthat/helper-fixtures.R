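# Shared fixtures and independent oracles, all built in code.

# single-platform spec with tunable noise structure
one_platform <- function(platform = "P1", n_replicates = 3L, sigma = 0.25,
                         kappa = 0.3, alpha = 1) {
  data.frame(platform = platform, n_replicates = n_replicates,
             sigma = sigma, kappa = kappa, alpha = alpha,
             stringsAsFactors = FALSE)
}

# small expression_matrix built directly from an M matrix
make_expr <- function(M, donors, platforms, A = NULL) {
  stopifnot(ncol(M) == length(donors), length(donors) == length(platforms))
  if (is.null(colnames(M)))
    colnames(M) <- sprintf("s%02d", seq_len(ncol(M)))
  if (is.null(rownames(M)))
    rownames(M) <- sprintf("p%03d", seq_len(nrow(M)))
  rep_idx <- stats::ave(seq_along(donors),
                        paste(donors, platforms), FUN = seq_along)
  sheet <- data.frame(sample_id = colnames(M), donor_id = donors,
                      platform = platforms,
                      replicate_index = as.integer(rep_idx),
                      stringsAsFactors = FALSE)
  A <- A %||% matrix(10, nrow(M), ncol(M), dimnames = dimnames(M))
  genes <- data.frame(probe_id = rownames(M),
                      gene_id = paste0("g_", rownames(M)),
                      stringsAsFactors = FALSE)
  expression_matrix(M, A, sheet, genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# correlation matrix with prescribed mean within/across-donor correlations:
# 2 donors x 2 replicates, all within pairs = w, all across pairs = a
corr_fixture <- function(w, a) {
  samples <- c("d1r1", "d1r2", "d2r1", "d2r2")
  corr <- matrix(a, 4, 4, dimnames = list(samples, samples))
  diag(corr) <- 1
  corr["d1r1", "d1r2"] <- corr["d1r2", "d1r1"] <- w
  corr["d2r1", "d2r2"] <- corr["d2r2", "d2r1"] <- w
  sheet <- data.frame(sample_id = samples,
                      donor_id = c("d1", "d1", "d2", "d2"),
                      platform = "X", replicate_index = c(1L, 2L, 1L, 2L),
                      stringsAsFactors = FALSE)
  list(corr = corr, sheet = sheet)
}

# exhaustive hypergeometric upper tail P(X >= k)
hyper_tail_enum <- function(k, set_in_universe, universe, selected) {
  j <- seq(max(k, 0), min(set_in_universe, selected))
  sum(choose(set_in_universe, j) *
        choose(universe - set_in_universe, selected - j)) /
    choose(universe, selected)
}

# textbook Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(rev(cummin(rev(p[o] * n / seq_len(n)))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# mean silhouette width (euclidean) over a score matrix and labels
mean_silhouette <- function(scores, labels) {
  d <- as.matrix(stats::dist(scores))
  labels <- as.character(labels)
  sil <- vapply(seq_len(nrow(scores)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# per-probe replicate variance computed from raw arrays, bypassing the
# normalization chain (mean over donors of the within-donor variance)
raw_replicate_variance <- function(ex) {
  mas <- lapply(ex$arrays, compute_ma)
  probes <- mas[[1]]$probe_id
  M <- vapply(mas, function(ma) ma$M, numeric(length(probes)))
  by_donor <- split(seq_len(nrow(ex$sheet)), ex$sheet$donor_id)
  per_donor <- vapply(by_donor, function(idx) {
    sub <- M[, idx, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2) / (ncol(sub) - 1)
  }, numeric(length(probes)))
  v <- rowMeans(per_donor)
  tapply(v, probes, mean)[sort(unique(probes))]
}
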