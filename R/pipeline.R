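# End-to-end orchestration: simulate (or read) -> normalize -> concordance
# -> PCA -> probe metrics -> enrichment, with every stage's output written
# as a standalone TSV plus a single JSON + Markdown report. All outputs are
# deterministic under a fixed seed: stage timings are logged to stderr only
# and never written into the result files.

pipeline_stages <- c("normalize", "concordance", "pca", "metrics",
                     "enrichment")

#' Run the full concordance pipeline
#'
#' Either simulates a synthetic experiment (`sim_config` given) or reads
#' intensity tables from `intensity_dir` together with `sample_sheet` and
#' `annotation` paths, then runs the requested stages in their fixed
#' order. Later stages require earlier ones: `concordance`, `pca` and
#' `metrics` need `normalize`; `enrichment` needs `metrics`.
#'
#' @param outdir output directory, created if needed.
#' @param sim_config a [simulation_config()], or `NULL` to read real data.
#' @param intensity_dir,sample_sheet,annotation input paths used when
#'   `sim_config` is `NULL`; `intensity_dir` must contain one
#'   `<sample_id>.tsv` per sheet row.
#' @param gmt optional path to a GMT file; when `NULL` and the experiment
#'   is simulated, a synthetic gene-set collection is generated from the
#'   measured universe.
#' @param dialect intensity-table dialect, see [read_intensity_table()].
#' @param stages character subset of
#'   `c("normalize", "concordance", "pca", "metrics", "enrichment")`.
#' @param span,iterations loess parameters.
#' @param keep_fraction optional probe variance filter (1 = off).
#' @param top_fraction fraction for top-variance gene selection.
#' @param alpha threshold for the platform-higher gene selection.
#' @param pval_method within-platform p-value method, see
#'   [within_platform_metrics()].
#' @param n_gene_sets number of synthetic gene sets when none are supplied.
#' @param verbose log stage progress and timings to stderr.
#' @return The report, invisibly (class `pipeline_report`); also written as
#'   `report.json` and `report.md` in `outdir`.
#' @export
run_pipeline <- function(outdir,
                         sim_config = simulation_config(),
                         intensity_dir = NULL, sample_sheet = NULL,
                         annotation = NULL, gmt = NULL, dialect = "fe",
                         stages = pipeline_stages,
                         span = 0.3, iterations = 4L, keep_fraction = 1,
                         top_fraction = 0.05, alpha = 0.05,
                         pval_method = "anova", n_gene_sets = 25L,
                         verbose = TRUE) {
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    stop_fmt("unknown stage(s): %s", paste(bad, collapse = ", "))
  need <- function(stage, requires) {
    if (stage %in% stages && !requires %in% stages)
      stop_fmt("stage '%s' requires stage '%s'", stage, requires)
  }
  for (s in c("concordance", "pca", "metrics")) need(s, "normalize")
  need("enrichment", "metrics")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop_fmt("stage '%s' failed: %s", stage, conditionMessage(e)))
    log_msg("[%s] done in %.1fs", stage, proc.time()[["elapsed"]] - t0)
    res
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(sim_config)) {
    stopifnot(inherits(sim_config, "simulation_config"))
    inputs <- timed("simulate", {
      ann <- simulate_annotation(sim_config)
      ex <- simulate_experiment(sim_config, ann)
      list(arrays = ex$arrays, sheet = ex$sheet, ann = ann,
           truth = ex$truth)
    })
    write_annotation(inputs$ann, file.path(outdir, "annotation.tsv"))
    write_sample_sheet(inputs$sheet, file.path(outdir, "sample_sheet.tsv"))
    jsonlite::write_json(inputs$truth,
                         file.path(outdir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
    seed <- sim_config$seed
  } else {
    if (is.null(intensity_dir) || is.null(sample_sheet) ||
        is.null(annotation))
      stop_fmt("without sim_config, intensity_dir, sample_sheet and annotation are required")
    inputs <- timed("read", {
      sheet <- read_sample_sheet(sample_sheet)
      arrays <- lapply(sheet$sample_id, function(sid)
        read_intensity_table(file.path(intensity_dir,
                                       paste0(sid, ".tsv")),
                             dialect = dialect, sample_id = sid))
      list(arrays = arrays, sheet = sheet,
           ann = read_annotation(annotation), truth = NULL)
    })
    seed <- NA_integer_
  }
  log_msg("[inputs] %d arrays, %d probes annotated",
          length(inputs$arrays), nrow(inputs$ann))

  report <- list(
    tool = "bloodconcord",
    version = as.character(utils::packageVersion("bloodconcord")),
    seed = seed,
    parameters = list(span = span, iterations = iterations,
                      keep_fraction = keep_fraction,
                      top_fraction = top_fraction, alpha = alpha,
                      pval_method = pval_method,
                      stages = as.list(stages)),
    samples = list(n_samples = length(inputs$arrays),
                   n_donors = length(unique(inputs$sheet$donor_id)),
                   platforms = lapply(split(
                     inputs$sheet, inputs$sheet$platform),
                     function(df) list(platform = df$platform[1L],
                                       n_samples = nrow(df)))))
  names(report$samples$platforms) <- NULL

  if (!"normalize" %in% stages) {
    report_paths <- write_report(report, outdir)
    return(invisible(structure(report, class = "pipeline_report",
                               paths = report_paths)))
  }

  # --- normalize ----------------------------------------------------------
  x <- timed("normalize", normalize_experiment(
    inputs$arrays, inputs$sheet, span = span, iterations = iterations,
    keep_fraction = keep_fraction))
  write_matrix_tsv(x$M, file.path(outdir, "matrix_M.tsv"))
  write_matrix_tsv(x$A, file.path(outdir, "matrix_A.tsv"))
  report$samples$n_probes <- nrow(x$M)

  platforms <- unique(x$samples$platform)

  # --- concordance --------------------------------------------------------
  if ("concordance" %in% stages) {
    conc <- timed("concordance", concordance_table(x))
    write_table(conc, file.path(outdir, "concordance.tsv"))
    report$concordance <- lapply(seq_len(nrow(conc)), function(i)
      as.list(conc[i, , drop = FALSE]))
  }

  # --- pca ----------------------------------------------------------------
  if ("pca" %in% stages) {
    pca <- timed("pca", pca_samples(x))
    scores <- data.frame(sample_id = rownames(pca$scores),
                         pca$scores[, seq_len(min(5L, ncol(pca$scores))),
                                    drop = FALSE],
                         check.names = FALSE, stringsAsFactors = FALSE)
    write_table(scores, file.path(outdir, "pca_scores.tsv"))
    plot_pca(pca, x$samples, file = file.path(outdir, "pca_plot.png"))
    report$pca <- list(
      n_components = pca$n_components,
      explained_variance = as.list(
        pca$explained_variance[seq_len(min(5L,
                                           length(pca$explained_variance)))]))
  }

  # --- metrics ------------------------------------------------------------
  metrics_by_platform <- NULL
  cross_tests <- list()
  if ("metrics" %in% stages) {
    res <- timed("metrics", {
      mb <- lapply(platforms, function(p)
        within_platform_metrics(x, p, pval_method = pval_method))
      names(mb) <- platforms
      ct <- list()
      if (length(platforms) >= 2L) {
        pairs <- utils::combn(platforms, 2L)
        for (k in seq_len(ncol(pairs)))
          ct[[paste(pairs[1L, k], pairs[2L, k], sep = "_vs_")]] <-
            cross_platform_test(x, pairs[1L, k], pairs[2L, k])
      }
      list(mb = mb, ct = ct)
    })
    metrics_by_platform <- res$mb
    cross_tests <- res$ct
    write_table(do.call(rbind, metrics_by_platform),
                file.path(outdir, "metrics.tsv"))
    if (length(cross_tests))
      write_table(do.call(rbind, cross_tests),
                  file.path(outdir, "cross_platform_tests.tsv"))

    propcorr <- do.call(rbind, lapply(platforms, function(p) {
      others <- Filter(function(ct)
        p %in% c(ct$platform_a[1L], ct$platform_b[1L]), cross_tests)
      cross_named <- NULL
      if (length(others)) {
        cross_named <- others
        names(cross_named) <- vapply(others, function(ct) {
          other <- setdiff(c(ct$platform_a[1L], ct$platform_b[1L]), p)
          paste0("vs_", other)
        }, character(1L))
      }
      correlate_with_properties(metrics_by_platform[[p]], inputs$ann,
                                cross = cross_named)
    }))
    write_table(propcorr, file.path(outdir, "property_correlations.tsv"))
    gcfit <- plot_variance_vs_gc(metrics_by_platform[[1L]], inputs$ann,
                                 file = file.path(outdir,
                                                  "variance_vs_gc.png"))
    report$property_correlations <- list(
      n_rows = nrow(propcorr),
      n_significant = sum(propcorr$significant, na.rm = TRUE),
      var_gc = lapply(platforms, function(p) {
        row <- propcorr[propcorr$platform == p &
                          propcorr$measure == "Var" &
                          propcorr$property == "GCpercent", ]
        list(platform = p, r = row$r[1L], p = row$p[1L])
      }),
      var_gc_ols = gcfit[c("slope", "intercept")])
  }

  # --- enrichment ---------------------------------------------------------
  if ("enrichment" %in% stages) {
    enr <- timed("enrichment", {
      universe <- sort(unique(x$genes$gene_id))
      sets <- if (!is.null(gmt)) read_gmt(gmt)
        else simulate_gene_sets(universe, n_sets = n_gene_sets,
                                seed = if (is.na(seed)) 1L else seed)
      top <- lapply(platforms, function(p) {
        sel <- select_top_variance_genes(metrics_by_platform[[p]],
                                         fraction = top_fraction)
        cbind(platform = p,
              overrepresentation_test(sel, universe, sets))
      })
      names(top) <- platforms
      higher <- NULL
      if (length(cross_tests)) {
        hg <- select_platform_higher_genes(cross_tests[[1L]],
                                           alpha = alpha)
        higher <- list(
          platform_a = hg$platform_a, platform_b = hg$platform_b,
          n_higher_in_a = length(hg$higher_in_a),
          n_higher_in_b = length(hg$higher_in_b),
          enrichment_a = if (length(hg$higher_in_a))
            overrepresentation_test(hg$higher_in_a, universe, sets)
          else NULL,
          enrichment_b = if (length(hg$higher_in_b))
            overrepresentation_test(hg$higher_in_b, universe, sets)
          else NULL)
      }
      list(top = top, higher = higher)
    })
    write_table(do.call(rbind, enr$top),
                file.path(outdir, "enrichment_top_variance.tsv"))
    if (!is.null(enr$higher)) {
      hdf <- rbind(
        if (!is.null(enr$higher$enrichment_a))
          cbind(higher_in = enr$higher$platform_a,
                enr$higher$enrichment_a) else NULL,
        if (!is.null(enr$higher$enrichment_b))
          cbind(higher_in = enr$higher$platform_b,
                enr$higher$enrichment_b) else NULL)
      if (!is.null(hdf))
        write_table(hdf, file.path(outdir,
                                   "enrichment_platform_higher.tsv"))
    }
    report$enrichment <- list(
      n_gene_sets = if (!is.null(gmt)) length(read_gmt(gmt))
        else n_gene_sets,
      top_variance = lapply(platforms, function(p) {
        head_rows <- utils::head(enr$top[[p]], 5L)
        list(platform = p,
             top_sets = lapply(seq_len(nrow(head_rows)), function(i)
               as.list(head_rows[i, c("set", "overlap", "pval", "fdr")])))
      }),
      platform_higher = if (!is.null(enr$higher))
        enr$higher[c("platform_a", "platform_b",
                     "n_higher_in_a", "n_higher_in_b")] else NULL)
  }

  validate_report(report)
  report_paths <- write_report(report, outdir)
  log_msg("[report] written to %s", outdir)
  invisible(structure(report, class = "pipeline_report",
                      paths = report_paths))
}

write_report <- function(report, outdir) {
  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, json_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  md_path <- file.path(outdir, "report.md")
  writeLines(render_report_md(report), md_path)
  c(json = json_path, md = md_path)
}

render_report_md <- function(report) {
  lines <- c(sprintf("# bloodconcord report (v%s)", report$version),
             "",
             sprintf("- seed: %s", report$seed),
             sprintf("- samples: %d (%d donors)",
                     report$samples$n_samples, report$samples$n_donors),
             sprintf("- probes after preprocessing: %s",
                     report$samples$n_probes %||% "not normalized"),
             "")
  if (!is.null(report$concordance)) {
    lines <- c(lines, "## Within/across-donor concordance", "",
               "| platform | mean within r | mean across r | S/N ratio | within pairs | across pairs |",
               "|---|---|---|---|---|---|")
    for (row in report$concordance)
      lines <- c(lines, sprintf("| %s | %.4f | %.4f | %.4f | %d | %d |",
                                row$platform,
                                row$mean_within_donor_correlation,
                                row$mean_across_donor_correlation,
                                row$sn_ratio, row$n_within_pairs,
                                row$n_across_pairs))
    lines <- c(lines, "")
  }
  if (!is.null(report$pca)) {
    ev <- unlist(report$pca$explained_variance)
    lines <- c(lines, "## PCA", "",
               sprintf("- explained variance (first %d): %s",
                       length(ev),
                       paste(sprintf("%.3f", ev), collapse = ", ")), "")
  }
  if (!is.null(report$property_correlations)) {
    lines <- c(lines, "## Probe variability vs probe properties", "",
               sprintf("- correlation rows: %d (significant at p<0.01: %d)",
                       report$property_correlations$n_rows,
                       report$property_correlations$n_significant))
    for (vg in report$property_correlations$var_gc)
      lines <- c(lines, sprintf("- Var vs GC%% [%s]: r = %.4f (p = %.3g)",
                                vg$platform, vg$r, vg$p))
    lines <- c(lines, "")
  }
  if (!is.null(report$enrichment)) {
    lines <- c(lines, "## Gene-set over-representation", "",
               sprintf("- gene sets tested: %d",
                       report$enrichment$n_gene_sets))
    for (tv in report$enrichment$top_variance) {
      first <- tv$top_sets[[1L]]
      lines <- c(lines,
                 sprintf("- top-variance genes [%s]: best set %s (overlap %d, p = %.3g, FDR = %.3g)",
                         tv$platform, first$set, first$overlap,
                         first$pval, first$fdr))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Validate a pipeline report against the bundled JSON schema
#'
#' Checks the report structure against the schema shipped at
#' `inst/extdata/report-schema.json`: required properties and primitive
#' types, recursively (a pragmatic subset of JSON Schema sufficient for
#' this report).
#'
#' @param report a `pipeline_report` (or plain list with the same shape).
#' @param schema_path path to the schema JSON.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report,
                            schema_path = system.file(
                              "extdata", "report-schema.json",
                              package = "bloodconcord")) {
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  check_schema(report, schema, "report")
  invisible(TRUE)
}

check_schema <- function(x, schema, where) {
  type <- schema$type
  if (is.null(type)) return(invisible(TRUE))
  ok <- switch(type,
               object = is.list(x),
               array = is.list(x) || is.vector(x),
               string = is.character(x) && length(x) == 1L,
               number = is.numeric(x) && length(x) == 1L,
               integer = is.numeric(x) && length(x) == 1L &&
                 (is.na(x) || x == round(x)),
               boolean = is.logical(x) && length(x) == 1L,
               TRUE)
  if (!ok)
    stop_fmt("report schema violation at %s: expected %s", where, type)
  if (type == "object") {
    for (req in schema$required %||% list())
      if (is.null(x[[req]]))
        stop_fmt("report schema violation: missing required field '%s' at %s",
                 req, where)
    for (nm in names(schema$properties %||% list()))
      if (!is.null(x[[nm]]))
        check_schema(x[[nm]], schema$properties[[nm]],
                     paste(where, nm, sep = "."))
  } else if (type == "array" && !is.null(schema$items)) {
    for (i in seq_along(x))
      check_schema(x[[i]], schema$items, sprintf("%s[%d]", where, i))
  }
  invisible(TRUE)
}
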