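# Readers and writers for the plain-text formats used throughout the
# pipeline: two-channel intensity tables, sample sheets, probe annotations,
# GMT gene sets, and generic result/matrix TSVs.

intensity_dialects <- list(
  fe    = c(probe_id = "ProbeID", gene_id = "GeneID",
            red_signal = "rMedianSignal", green_signal = "gMedianSignal"),
  plain = c(probe_id = "probe_id", gene_id = "gene_id",
            red_signal = "red_signal", green_signal = "green_signal")
)

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_fmt("%s file not found: '%s'", what, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_fmt("%s file '%s' is missing required column(s): %s",
             what, path, paste(missing, collapse = ", "))
  df
}

#' Construct a two-channel intensity array
#'
#' One hybridization's raw median signals for the red (Cy5, test sample) and
#' green (Cy3, universal reference) channels. Probe ids may repeat: arrays
#' can carry on-array duplicate spots, which are averaged later in the
#' pipeline. Both signals must be strictly positive so that log2 ratios are
#' defined.
#'
#' @param probe_id,gene_id character vectors, one entry per spot.
#' @param red_signal,green_signal positive fluorescence signals per spot.
#' @param sample_id single string identifying the hybridization.
#' @return A `data.frame` of class `intensity_array` with columns
#'   `probe_id`, `gene_id`, `red_signal`, `green_signal` and a
#'   `sample_id` attribute.
#' @export
intensity_array <- function(probe_id, gene_id, red_signal, green_signal,
                            sample_id) {
  n <- length(probe_id)
  if (length(gene_id) != n || length(red_signal) != n ||
      length(green_signal) != n)
    stop_fmt("intensity_array fields must have equal length")
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop_fmt("'sample_id' must be a single non-empty string")
  bad <- which(!is.finite(red_signal) | !is.finite(green_signal) |
                 red_signal <= 0 | green_signal <= 0)
  if (length(bad))
    stop_fmt("non-positive or non-finite signal at row %d (sample '%s')",
             bad[1L], sample_id)
  out <- data.frame(probe_id = as.character(probe_id),
                    gene_id = as.character(gene_id),
                    red_signal = as.numeric(red_signal),
                    green_signal = as.numeric(green_signal),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("intensity_array", "data.frame")
  out
}

#' Read a two-channel intensity table
#'
#' Two dialects are supported: `"fe"` (default), with Feature-Extraction
#' style columns `ProbeID`, `GeneID`, `rMedianSignal`, `gMedianSignal` —
#' the dialect the synthetic-data writer emits — and `"plain"` with columns
#' `probe_id`, `gene_id`, `red_signal`, `green_signal`.
#'
#' @param path path to a tab-separated file.
#' @param dialect column-naming dialect, `"fe"` or `"plain"`.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return An [intensity_array()].
#' @export
read_intensity_table <- function(path, dialect = c("fe", "plain"),
                                 sample_id = NULL) {
  dialect <- match.arg(dialect)
  cols <- intensity_dialects[[dialect]]
  df <- read_tsv_checked(path, unname(cols), "intensity")
  sid <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  bad <- which(!is.finite(df[[cols[["red_signal"]]]]) |
                 !is.finite(df[[cols[["green_signal"]]]]) |
                 df[[cols[["red_signal"]]]] <= 0 |
                 df[[cols[["green_signal"]]]] <= 0)
  if (length(bad))
    stop_fmt("intensity file '%s': non-positive signal at data row %d",
             path, bad[1L])
  intensity_array(df[[cols[["probe_id"]]]], df[[cols[["gene_id"]]]],
                  df[[cols[["red_signal"]]]], df[[cols[["green_signal"]]]],
                  sample_id = sid)
}

#' Write a two-channel intensity table
#'
#' @param x an [intensity_array()].
#' @param path output path.
#' @param dialect column-naming dialect, see [read_intensity_table()].
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path, dialect = c("fe", "plain")) {
  dialect <- match.arg(dialect)
  cols <- intensity_dialects[[dialect]]
  out <- data.frame(x$probe_id, x$gene_id, x$red_signal, x$green_signal,
                    stringsAsFactors = FALSE)
  names(out) <- unname(cols)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id` (unique), `donor_id`, `platform`,
#' `replicate_index`. The concordance stages additionally require at least
#' two donors with at least two technical replicates per (donor, platform);
#' that is checked where the statistic is computed, not here.
#'
#' @param path path to a tab-separated sample sheet.
#' @return A `data.frame` with the four columns above.
#' @export
read_sample_sheet <- function(path) {
  req <- c("sample_id", "donor_id", "platform", "replicate_index")
  df <- read_tsv_checked(path, req, "sample sheet")
  df <- df[req]
  df$sample_id <- as.character(df$sample_id)
  df$donor_id <- as.character(df$donor_id)
  df$platform <- as.character(df$platform)
  df$replicate_index <- as.integer(df$replicate_index)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop_fmt("sample sheet '%s' has duplicated sample_id(s): %s",
             path, paste(dup, collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @param x a sample-sheet `data.frame`.
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

annotation_cols <- c("probe_id", "gene_id", "Dist3", "Dist5",
                     "TranscriptSize", "GeneSize", "GCpercent")

#' Read a probe annotation table
#'
#' Per-probe physical properties used in the probe-variability correlation
#' analysis: distances from the probe to the transcript 3' and 5' ends
#' (`Dist3`, `Dist5`, 0-based nucleotide offsets), transcript and gene
#' sizes in nucleotides, and GC percent in \[0, 100\].
#'
#' @param path path to a tab-separated annotation table.
#' @return A `data.frame` with columns `probe_id`, `gene_id`, `Dist3`,
#'   `Dist5`, `TranscriptSize`, `GeneSize`, `GCpercent`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path, annotation_cols, "annotation")
  df <- df[annotation_cols]
  df$probe_id <- as.character(df$probe_id)
  df$gene_id <- as.character(df$gene_id)
  num <- c("Dist3", "Dist5", "TranscriptSize", "GeneSize", "GCpercent")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  bad <- which(df$GCpercent < 0 | df$GCpercent > 100 | is.na(df$GCpercent))
  if (length(bad))
    stop_fmt("annotation '%s': GCpercent outside [0, 100] at data row %d",
             path, bad[1L])
  bad <- which(df$Dist3 < 0 | df$Dist5 < 0 |
                 df$TranscriptSize < 0 | df$GeneSize < 0)
  if (length(bad))
    stop_fmt("annotation '%s': negative size or distance at data row %d",
             path, bad[1L])
  df
}

#' @rdname read_annotation
#' @param x an annotation `data.frame`.
#' @export
write_annotation <- function(x, path) {
  utils::write.table(x[annotation_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids; no set may be
#'   empty and names must be unique. Set members need not all be present in
#'   the measured universe — they are intersected with it at test time.
#' @param description named character vector of set descriptions (recycled
#'   to empty strings when absent).
#' @return An object of class `gene_sets`.
#' @export
gene_sets <- function(sets, description = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_fmt("'sets' must be a named list of gene id vectors")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop_fmt("duplicated gene set name(s): %s", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g[nzchar(g)])))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop_fmt("empty gene set(s): %s", paste(empty, collapse = ", "))
  if (is.null(description)) description <- setNames(rep("", length(sets)),
                                                    names(sets))
  description <- description[names(sets)]
  description[is.na(description)] <- ""
  names(description) <- names(sets)
  structure(list(sets = sets, description = description),
            class = "gene_sets")
}

#' @export
length.gene_sets <- function(x) length(x$sets)

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Each line is tab-separated: set name, description, then one or more gene
#' ids. Malformed lines raise an error naming the line number.
#'
#' @param path path to a GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fmt("GMT file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  desc <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[!is.na(fields)]
    genes <- if (length(fields) >= 3L) fields[-(1:2)][nzchar(fields[-(1:2)])]
             else character(0)
    if (length(fields) < 3L || length(genes) == 0L)
      stop_fmt(paste0("malformed GMT line %d in '%s' ",
                      "(need name, description, >=1 gene)"), i, path)
    if (fields[1L] %in% names(sets))
      stop_fmt("duplicated gene set name '%s' at GMT line %d", fields[1L], i)
    sets[[fields[1L]]] <- genes
    desc[fields[1L]] <- fields[2L]
  }
  if (!length(sets)) stop_fmt("GMT file '%s' contains no gene sets", path)
  gene_sets(sets, desc)
}

#' @rdname read_gmt
#' @param x a [gene_sets()] collection.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$description[[nm]], x$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param x a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a probes-by-samples matrix as TSV
#'
#' The first column holds probe ids, remaining columns one sample each.
#'
#' @param mat numeric matrix with probe-id rownames.
#' @param path file path.
#' @return `write_matrix_tsv`: `path` invisibly; `read_matrix_tsv`: the
#'   matrix with rownames restored.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_checked(path, "probe_id", "matrix")
  mat <- as.matrix(df[, setdiff(names(df), "probe_id"), drop = FALSE])
  rownames(mat) <- as.character(df$probe_id)
  mat
}
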