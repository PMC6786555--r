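# Per-probe variability within each platform (Var, donor-effect p-value,
# absolute fold difference, meanM, meanA), per-probe paired tests between
# platforms, and Pearson correlations of these measures with probe physical
# properties. F and t statistics are computed vectorized over probes from
# group sums of squares; unit tests check them against stats::aov and
# stats::t.test on small fixtures.

#' Per-probe variability metrics within one platform
#'
#' For every probe: `Var` = mean over donors of the unbiased sample
#' variance of M across that donor's technical replicates; `FD` = mean over
#' donors of the mean absolute pairwise M difference between replicates
#' (log2 units); `pval` = one-way ANOVA F-test p-value for donor
#' differences with replicates as within-group observations (or a
#' one-sample t-test of M against 0 with `pval_method = "ttest"`);
#' `meanM`/`meanA` = means over all the platform's samples. Donors with a
#' single replicate are dropped from Var/FD/pval with a warning.
#'
#' @param x an [expression_matrix()].
#' @param platform platform name.
#' @param pval_method `"anova"` (default, donor-effect F test) or
#'   `"ttest"` (one-sample t of M vs 0 across the platform's samples).
#' @return `data.frame` with columns `probe_id`, `gene_id`, `platform`,
#'   `Var`, `pval`, `FD`, `meanM`, `meanA`.
#' @export
within_platform_metrics <- function(x, platform,
                                    pval_method = c("anova", "ttest")) {
  pval_method <- match.arg(pval_method)
  stopifnot(inherits(x, "expr_matrix"))
  sel <- x$samples$platform == platform
  if (!any(sel)) stop_fmt("unknown platform '%s'", platform)
  sids <- x$samples$sample_id[sel]
  donors <- x$samples$donor_id[sel]
  Mall <- x$M[, sids, drop = FALSE]
  Aall <- x$A[, sids, drop = FALSE]

  idx_by_donor <- split(seq_along(sids), donors)
  singles <- names(idx_by_donor)[lengths(idx_by_donor) < 2L]
  if (length(singles)) {
    warn_fmt("dropping donor(s) with a single replicate in '%s': %s",
             platform, paste(singles, collapse = ", "))
    idx_by_donor <- idx_by_donor[lengths(idx_by_donor) >= 2L]
  }
  if (length(idx_by_donor) < 2L)
    stop_fmt("platform '%s' needs >= 2 donors with >= 2 replicates",
             platform)

  per_donor_var <- matrix(vapply(idx_by_donor, function(idx)
    row_vars(Mall[, idx, drop = FALSE]), numeric(nrow(Mall))),
    nrow = nrow(Mall))
  Var <- rowMeans(per_donor_var)

  per_donor_fd <- matrix(vapply(idx_by_donor, function(idx) {
    pairs <- utils::combn(idx, 2L)
    rowMeans(matrix(vapply(seq_len(ncol(pairs)), function(k)
      abs(Mall[, pairs[1L, k]] - Mall[, pairs[2L, k]]),
      numeric(nrow(Mall))), nrow = nrow(Mall)))
  }, numeric(nrow(Mall))), nrow = nrow(Mall))
  FD <- rowMeans(per_donor_fd)

  pval <- if (pval_method == "anova")
    row_anova_pvalues(Mall, idx_by_donor)
  else
    row_onesample_t_pvalues(Mall)

  data.frame(probe_id = rownames(Mall),
             gene_id = x$genes$gene_id[match(rownames(Mall),
                                             x$genes$probe_id)],
             platform = platform, Var = Var, pval = pval, FD = FD,
             meanM = rowMeans(Mall), meanA = rowMeans(Aall),
             stringsAsFactors = FALSE, row.names = NULL)
}

# one-way ANOVA p-value per row from group sums of squares
row_anova_pvalues <- function(M, idx_by_group) {
  used <- unlist(idx_by_group, use.names = FALSE)
  Msub <- M[, used, drop = FALSE]
  N <- length(used)
  k <- length(idx_by_group)
  grand <- rowMeans(Msub)
  ssb <- rowSums(matrix(vapply(idx_by_group, function(idx) {
    lengths_idx <- length(idx)
    lengths_idx * (rowMeans(M[, idx, drop = FALSE]) - grand)^2
  }, numeric(nrow(M))), nrow = nrow(M)))
  sst <- rowSums((Msub - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(fstat, k - 1, N - k, lower.tail = FALSE)
  degenerate <- ssw < 1e-24
  p[degenerate & ssb >= 1e-24] <- 0
  p[degenerate & ssb < 1e-24] <- 1
  p
}

row_onesample_t_pvalues <- function(M) {
  n <- ncol(M)
  m <- rowMeans(M)
  s <- sqrt(row_vars(M))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1)
  p[s == 0 & abs(m) < 1e-12] <- 1
  p[s == 0 & abs(m) >= 1e-12] <- 0
  p
}

#' Per-probe paired test between two platforms
#'
#' Replicates are first averaged to one M value per (donor, platform); for
#' each probe a two-sided paired t-test across the donors common to both
#' platforms is computed on the differences `M_a - M_b`. Conventions for
#' degenerate probes: all per-donor differences exactly zero gives p = 1;
#' zero variance with a nonzero mean difference gives p = 0. With
#' `method = "welch"` an unpaired Welch t-test on the per-donor means is
#' used instead.
#'
#' @param x an [expression_matrix()].
#' @param platform_a,platform_b platform names (>= 3 donors must have data
#'   in both).
#' @param method `"paired"` (default) or `"welch"`.
#' @return `data.frame` with columns `probe_id`, `gene_id`, `platform_a`,
#'   `platform_b`, `mean_diff`, `statistic`, `pval`.
#' @export
cross_platform_test <- function(x, platform_a, platform_b,
                                method = c("paired", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"))
  Ma <- donor_mean_matrix(x, platform_a)
  Mb <- donor_mean_matrix(x, platform_b)
  common <- intersect(colnames(Ma), colnames(Mb))
  if (length(common) < 3L)
    stop_fmt("platforms '%s' and '%s' share %d donor(s); need >= 3",
             platform_a, platform_b, length(common))
  Ma <- Ma[, common, drop = FALSE]
  Mb <- Mb[, common, drop = FALSE]
  n <- length(common)
  if (method == "paired") {
    D <- Ma - Mb
    m <- rowMeans(D)
    s <- sqrt(row_vars(D))
    tstat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), n - 1)
    zero_sd <- s < 1e-12
    p[zero_sd & abs(m) < 1e-12] <- 1
    tstat[zero_sd & abs(m) < 1e-12] <- 0
    p[zero_sd & abs(m) >= 1e-12] <- 0
  } else {
    m <- rowMeans(Ma) - rowMeans(Mb)
    va <- row_vars(Ma) / n
    vb <- row_vars(Mb) / n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n - 1) + vb^2 / (n - 1))
    tstat <- m / se
    p <- 2 * stats::pt(-abs(tstat), df)
    zero_sd <- se < 1e-12
    p[zero_sd & abs(m) < 1e-12] <- 1
    tstat[zero_sd & abs(m) < 1e-12] <- 0
    p[zero_sd & abs(m) >= 1e-12] <- 0
  }
  data.frame(probe_id = rownames(Ma),
             gene_id = x$genes$gene_id[match(rownames(Ma),
                                             x$genes$probe_id)],
             platform_a = platform_a, platform_b = platform_b,
             mean_diff = m, statistic = tstat, pval = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

# probes x donors matrix of replicate-averaged M values for one platform
donor_mean_matrix <- function(x, platform) {
  sel <- x$samples$platform == platform
  if (!any(sel)) stop_fmt("unknown platform '%s'", platform)
  sids <- x$samples$sample_id[sel]
  donors <- x$samples$donor_id[sel]
  out <- matrix(vapply(split(sids, donors), function(ss)
    rowMeans(x$M[, ss, drop = FALSE]), numeric(nrow(x$M))),
    nrow = nrow(x$M),
    dimnames = list(rownames(x$M), names(split(sids, donors))))
  out
}

probe_property_names <- c("Dist3", "Dist5", "TranscriptSize", "GeneSize",
                          "GCpercent", "meanM", "meanA")

#' Correlate probe variability measures with probe properties
#'
#' Pearson correlation (and its two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom) between
#' every variability measure (`Var`, `pval`, `FD`, plus any cross-platform
#' p-value vectors passed via `cross`) and every probe property (`Dist3`,
#' `Dist5`, `TranscriptSize`, `GeneSize`, `GCpercent`, `meanM`, `meanA`).
#' Probes without annotation are dropped listwise with a reported count. A
#' constant measure or property yields a row flagged `degenerate` with
#' missing r and p. `significant` flags p < 0.01.
#'
#' @param metrics output of [within_platform_metrics()] for one platform.
#' @param annotation probe annotation table (see [read_annotation()]).
#' @param cross optional named list of [cross_platform_test()] results (or
#'   named numeric vectors keyed by probe id); each becomes an extra
#'   measure column, conventionally named `vs_<other platform>`.
#' @return Long `data.frame` with columns `platform`, `measure`,
#'   `property`, `n`, `r`, `p`, `significant`, `degenerate`; attribute
#'   `n_dropped` counts unannotated probes.
#' @export
correlate_with_properties <- function(metrics, annotation, cross = NULL) {
  joined <- merge(metrics, annotation[, c("probe_id", "Dist3", "Dist5",
                                          "TranscriptSize", "GeneSize",
                                          "GCpercent")],
                  by = "probe_id", sort = TRUE)
  n_dropped <- nrow(metrics) - nrow(joined)
  if (n_dropped > 0)
    message(sprintf("correlate_with_properties: dropped %d unannotated probe(s)",
                    n_dropped))
  if (nrow(joined) < 3L)
    stop_fmt("need >= 3 annotated probes, got %d", nrow(joined))

  measures <- list(Var = joined$Var, pval = joined$pval, FD = joined$FD)
  if (!is.null(cross)) {
    if (is.null(names(cross)) || any(!nzchar(names(cross))))
      stop_fmt("'cross' must be a named list")
    for (nm in names(cross)) {
      cv <- cross[[nm]]
      if (is.data.frame(cv)) cv <- setNames(cv$pval, cv$probe_id)
      measures[[nm]] <- as.numeric(cv[joined$probe_id])
    }
  }

  rows <- list()
  for (meas in names(measures)) {
    for (prop in probe_property_names) {
      mv <- measures[[meas]]
      pv <- joined[[prop]]
      ok <- is.finite(mv) & is.finite(pv)
      n <- sum(ok)
      degen <- n < 3L || stats::sd(mv[ok]) < .Machine$double.eps^0.5 ||
        stats::sd(pv[ok]) < .Machine$double.eps^0.5
      if (degen) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- stats::cor(mv[ok], pv[ok])
        p <- cor_pvalue(r, n)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        platform = metrics$platform[1L], measure = meas, property = prop,
        n = n, r = r, p = p,
        significant = !degen && !is.na(p) && p < 0.01,
        degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- n_dropped
  out
}

# two-sided p-value of a Pearson r via the exact t transform
cor_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}

#' Scatter plot of probe variance against GC percent
#'
#' Plots per-probe within-donor variance against probe GC percent with an
#' ordinary least-squares line, and returns the fit numerically.
#'
#' @param metrics output of [within_platform_metrics()].
#' @param annotation probe annotation table.
#' @param file optional output path (`.png`, `.svg` or `.pdf`).
#' @return Invisibly, a list with `slope`, `intercept`, `r`, `n`.
#' @export
plot_variance_vs_gc <- function(metrics, annotation, file = NULL) {
  joined <- merge(metrics[, c("probe_id", "Var", "platform")],
                  annotation[, c("probe_id", "GCpercent")], by = "probe_id")
  if (!nrow(joined)) stop_fmt("no probes shared between metrics and annotation")
  fit <- stats::lm(Var ~ GCpercent, data = joined)
  cf <- stats::coef(fit)
  if (!is.null(file)) open_device(file)
  graphics::plot(joined$GCpercent, joined$Var, pch = 16, cex = 0.4,
                 col = "grey30", xlab = "GC percent",
                 ylab = "Within-donor variance of M",
                 main = sprintf("Probe variance vs GC%% (%s)",
                                joined$platform[1L]))
  graphics::abline(fit, col = "red", lwd = 2)
  if (!is.null(file)) grDevices::dev.off()
  r <- if (stats::sd(joined$Var) > 0 && stats::sd(joined$GCpercent) > 0)
    stats::cor(joined$Var, joined$GCpercent) else NA_real_
  invisible(list(slope = unname(cf[["GCpercent"]]),
                 intercept = unname(cf[["(Intercept)"]]),
                 r = r, n = nrow(joined)))
}
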