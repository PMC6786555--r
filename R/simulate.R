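# Synthetic two-color microarray experiments with known donor, platform,
# dye-bias and probe-property-linked noise structure. The generative model
# is additive on the log2 (M value) scale:
#
#   M[p, s] = mu[p] + alpha_plat * beta[p, donor(s)] + delta[p, plat(s)]
#             + eps[p, s],   eps ~ N(0, sigma[p, plat])
#   sigma[p, plat] = sigma_plat * (1 + kappa_plat * z(GC[p])),
#                    truncated below at 0.1 * sigma_plat
#   A[p, s] ~ N(intensity_mean, intensity_sd)
#   R = 2^(A + M/2 + b(A)),  G = 2^(A - M/2)
#   b(A) = dye_bias_amplitude * sin((A - intensity_mean) / intensity_sd)
#
# b(A) injects a smooth intensity-dependent dye bias — exactly the artifact
# that within-array loess normalization is supposed to remove, which makes
# the generator a clean end-to-end test of the normalization chain.

#' Default platform specifications
#'
#' Three blood-collection platforms with the replicate structure of the
#' emulated study design: a whole-blood stabilization tube run in triplicate
#' (`RNAgard`), a second stabilization tube run in duplicate (`PAXgene`),
#' and PBMCs preserved in Trizol run in triplicate (`PBMC_Trizol`). With 8
#' donors this yields 8 x (3 + 2 + 3) = 64 arrays. Per-platform knobs:
#' `sigma` (replicate noise sd, log2 units), `kappa` (strength of the
#' GC-linked noise inflation), `alpha` (donor-signal attenuation in
#' \[0, 1\]; lower alpha means the platform captures less of the true
#' between-individual signal).
#'
#' @return A `data.frame` with columns `platform`, `n_replicates`, `sigma`,
#'   `kappa`, `alpha`.
#' @export
default_platform_specs <- function() {
  data.frame(
    platform = c("RNAgard", "PAXgene", "PBMC_Trizol"),
    n_replicates = c(3L, 2L, 3L),
    sigma = c(0.25, 0.25, 0.25),
    kappa = c(0.3, 0.3, 0.3),
    alpha = c(1.0, 0.9, 0.7),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic two-color experiment
#'
#' Defaults emulate the study design the package targets: 8 donors, three
#' platforms with 3/2/3 technical replicates (64 arrays), 2000 probes with
#' 5% on-array duplicates, additive log2-scale donor and platform effects,
#' a smooth intensity-dependent dye bias, and replicate noise whose sd
#' increases with probe GC content (the degradation-like property link).
#'
#' @param n_donors number of donors (biological individuals).
#' @param platform_specs `data.frame` as returned by
#'   [default_platform_specs()].
#' @param n_probes number of distinct probes per array.
#' @param duplicate_fraction fraction of probes spotted twice per array,
#'   in \[0, 1).
#' @param donor_effect_sd sd of the per-(probe, donor) effects beta, log2
#'   units; 0 gives the no-individual-signal null.
#' @param probe_baseline_sd sd of per-probe baselines mu (probe-specific
#'   offset versus the universal reference RNA), log2 units.
#' @param platform_effect_sd sd of per-(probe, platform) offsets delta,
#'   log2 units.
#' @param dye_bias_amplitude amplitude of the smooth intensity-dependent
#'   dye bias b(A), log2 units.
#' @param intensity_mean,intensity_sd mean and sd of the spot average
#'   log-intensities A, log2 units.
#' @param seed single integer seed; all randomness flows from it, and the
#'   same seed yields bit-identical output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_donors = 8L,
                              platform_specs = default_platform_specs(),
                              n_probes = 2000L,
                              duplicate_fraction = 0.05,
                              donor_effect_sd = 0.3,
                              probe_baseline_sd = 1.0,
                              platform_effect_sd = 0.3,
                              dye_bias_amplitude = 0.3,
                              intensity_mean = 10,
                              intensity_sd = 1.5,
                              seed = 1L) {
  n_donors <- assert_count(n_donors, "n_donors")
  n_probes <- assert_count(n_probes, "n_probes")
  seed <- assert_count(seed, "seed", min = 0L)
  assert_number(duplicate_fraction, "duplicate_fraction", 0, 1,
                open_max = TRUE)
  assert_number(donor_effect_sd, "donor_effect_sd", 0)
  assert_number(probe_baseline_sd, "probe_baseline_sd", 0)
  assert_number(platform_effect_sd, "platform_effect_sd", 0)
  assert_number(dye_bias_amplitude, "dye_bias_amplitude", 0)
  assert_number(intensity_mean, "intensity_mean")
  assert_number(intensity_sd, "intensity_sd", 0)
  req <- c("platform", "n_replicates", "sigma", "kappa", "alpha")
  if (!is.data.frame(platform_specs) ||
      length(missing <- setdiff(req, names(platform_specs))))
    stop_fmt("platform_specs must be a data.frame with columns %s",
             paste(req, collapse = ", "))
  if (nrow(platform_specs) < 1L)
    stop_fmt("platform_specs must define at least one platform")
  if (anyDuplicated(platform_specs$platform))
    stop_fmt("platform names must be unique")
  for (j in seq_len(nrow(platform_specs))) {
    assert_count(platform_specs$n_replicates[j], "n_replicates")
    assert_number(platform_specs$sigma[j], "sigma", 0)
    assert_number(platform_specs$kappa[j], "kappa", 0)
    assert_number(platform_specs$alpha[j], "alpha", 0, 1)
  }
  platform_specs$platform <- as.character(platform_specs$platform)
  platform_specs$n_replicates <- as.integer(platform_specs$n_replicates)
  structure(list(n_donors = n_donors, platform_specs = platform_specs,
                 n_probes = n_probes,
                 duplicate_fraction = duplicate_fraction,
                 donor_effect_sd = donor_effect_sd,
                 probe_baseline_sd = probe_baseline_sd,
                 platform_effect_sd = platform_effect_sd,
                 dye_bias_amplitude = dye_bias_amplitude,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd, seed = seed),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  n_arrays <- x$n_donors * sum(x$platform_specs$n_replicates)
  cat(sprintf(
    "simulation_config: %d donors x platforms (%s) = %d arrays, %d probes, seed %d\n",
    x$n_donors,
    paste(sprintf("%s:%d", x$platform_specs$platform,
                  x$platform_specs$n_replicates), collapse = ", "),
    n_arrays, x$n_probes, x$seed))
  invisible(x)
}

#' Read a simulation configuration from JSON or YAML
#'
#' Fields mirror the arguments of [simulation_config()];
#' `platform_specs` is a list/array of records with fields `platform`,
#' `n_replicates`, `sigma`, `kappa`, `alpha`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: '%s'", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  ps <- cfg$platform_specs
  if (!is.null(ps) && !is.data.frame(ps)) {
    # accept either a column-wise named list (YAML) or a list of records
    cfg$platform_specs <- if (!is.null(names(ps)) && "platform" %in% names(ps))
      as.data.frame(ps, stringsAsFactors = FALSE)
    else do.call(rbind, lapply(ps, function(rec)
      as.data.frame(rec, stringsAsFactors = FALSE)))
  }
  do.call(simulation_config, cfg)
}

probe_length_nt <- 60L  # 60-mer oligo probes

#' Simulate a probe annotation table
#'
#' Generates per-probe physical properties: GC percent uniform on
#' \[30, 70\], log-normal transcript and gene sizes (gene size = transcript
#' size plus log-normal intron content), and a probe position uniform along
#' the transcript. Distances are 0-based nucleotide offsets satisfying
#' `Dist3 + Dist5 + 60 == TranscriptSize` for the 60-mer probes simulated
#' here. Probes map 1:1 to genes.
#'
#' @param config a [simulation_config()].
#' @return An annotation `data.frame` (see [read_annotation()]).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 0L))
  n <- config$n_probes
  gc <- stats::runif(n, 30, 70)
  tsize <- pmax(round(stats::rlnorm(n, log(2000), 0.6)),
                probe_length_nt + 40L)
  gsize <- tsize + round(stats::rlnorm(n, log(8000), 0.8))
  dist5 <- floor(stats::runif(n) * (tsize - probe_length_nt + 1))
  dist5 <- pmin(dist5, tsize - probe_length_nt)  # guard runif(n) == 1 edge
  dist3 <- tsize - probe_length_nt - dist5
  data.frame(probe_id = sprintf("P%05d", seq_len(n)),
             gene_id = sprintf("G%05d", seq_len(n)),
             Dist3 = as.numeric(dist3), Dist5 = as.numeric(dist5),
             TranscriptSize = as.numeric(tsize),
             GeneSize = as.numeric(gsize), GCpercent = gc,
             stringsAsFactors = FALSE)
}

# Smooth intensity-dependent dye bias: a sine evaluated over roughly one
# third of its period across the observed A range (+-3 sd spans +-1 rad),
# i.e. a gentle monotone S-curve like the trends seen on real M-A plots —
# slowly varying, not oscillatory.
dye_bias <- function(A, config) {
  if (config$dye_bias_amplitude == 0) return(rep(0, length(A)))
  s <- if (config$intensity_sd > 0) config$intensity_sd else 1
  config$dye_bias_amplitude * sin((A - config$intensity_mean) / (3 * s))
}

#' Simulate a two-color experiment with known ground truth
#'
#' Draws latent M values from the additive log2-scale model (probe
#' baseline + attenuated donor effect + platform offset + replicate noise
#' whose sd is GC-linked via kappa), adds a smooth intensity-dependent dye
#' bias, and converts to channel signals `R = 2^(A + M/2 + b(A))`,
#' `G = 2^(A - M/2)`. A `duplicate_fraction` of probes is spotted twice per
#' array with independent noise.
#'
#' @param config a [simulation_config()].
#' @param annotation annotation from [simulate_annotation()] (or any table
#'   with matching `n_probes` rows and a `GCpercent` column).
#' @return An object of class `sim_experiment`: a list with `arrays` (list
#'   of [intensity_array()]), `sheet` (sample sheet `data.frame`), and
#'   `truth` (list with per-probe `mu`, probes x donors `beta`, probes x
#'   platforms `delta` and `sigma`, plus `duplicated_probes`).
#' @export
simulate_experiment <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(annotation) != config$n_probes)
    stop_fmt("annotation has %d probes but config expects %d",
             nrow(annotation), config$n_probes)
  specs <- config$platform_specs
  n <- config$n_probes
  set.seed(derive_seed(config$seed, 1L))

  donors <- sprintf("D%02d", seq_len(config$n_donors))
  sheet <- do.call(rbind, lapply(seq_len(nrow(specs)), function(j) {
    do.call(rbind, lapply(seq_len(config$n_donors), function(d) {
      data.frame(
        sample_id = sprintf("%s_%s_r%d", donors[d], specs$platform[j],
                            seq_len(specs$n_replicates[j])),
        donor_id = donors[d], platform = specs$platform[j],
        replicate_index = seq_len(specs$n_replicates[j]),
        stringsAsFactors = FALSE)
    }))
  }))
  rownames(sheet) <- NULL

  mu <- stats::rnorm(n, 0, config$probe_baseline_sd)
  beta <- matrix(stats::rnorm(n * config$n_donors, 0, config$donor_effect_sd),
                 n, dimnames = list(annotation$probe_id, donors))
  delta <- matrix(stats::rnorm(n * nrow(specs), 0, config$platform_effect_sd),
                  n, dimnames = list(annotation$probe_id, specs$platform))
  zgc <- as.numeric(scale(annotation$GCpercent))
  if (any(!is.finite(zgc))) zgc <- rep(0, n)  # constant GC degenerates
  sigma <- vapply(seq_len(nrow(specs)), function(j) {
    pmax(specs$sigma[j] * (1 + specs$kappa[j] * zgc), 0.1 * specs$sigma[j])
  }, numeric(n))
  sigma <- matrix(sigma, n, dimnames = list(annotation$probe_id,
                                            specs$platform))

  n_dup <- round(config$duplicate_fraction * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  spot <- c(seq_len(n), dup_idx)

  arrays <- vector("list", nrow(sheet))
  names(mu) <- annotation$probe_id
  for (s in seq_len(nrow(sheet))) {
    j <- match(sheet$platform[s], specs$platform)
    d <- match(sheet$donor_id[s], donors)
    m_latent <- mu + specs$alpha[j] * beta[, d] + delta[, j]
    eps <- stats::rnorm(length(spot), 0, sigma[spot, j])
    M <- m_latent[spot] + eps
    A <- stats::rnorm(length(spot), config$intensity_mean,
                      config$intensity_sd)
    b <- dye_bias(A, config)
    arrays[[s]] <- intensity_array(
      annotation$probe_id[spot], annotation$gene_id[spot],
      red_signal = 2^(A + M / 2 + b), green_signal = 2^(A - M / 2),
      sample_id = sheet$sample_id[s])
  }
  names(arrays) <- sheet$sample_id

  truth <- list(mu = setNames(mu, annotation$probe_id), beta = beta,
                delta = delta, sigma = sigma,
                duplicated_probes = annotation$probe_id[dup_idx])
  structure(list(arrays = arrays, sheet = sheet, truth = truth),
            class = "sim_experiment")
}

#' Simulate a gene-set collection
#'
#' Draws random gene sets from a universe of gene ids, optionally with
#' per-gene sampling weights (e.g. to build a set enriched for genes known
#' to be noisy in the generator's ground truth).
#'
#' @param gene_ids universe of gene ids to draw from.
#' @param n_sets number of sets.
#' @param min_size,max_size inclusive bounds on set sizes.
#' @param weights optional non-negative per-gene sampling weights.
#' @param seed integer seed.
#' @return A [gene_sets()] collection.
#' @export
simulate_gene_sets <- function(gene_ids, n_sets = 25L, min_size = 10L,
                               max_size = 60L, weights = NULL, seed = 1L) {
  n_sets <- assert_count(n_sets, "n_sets")
  min_size <- assert_count(min_size, "min_size")
  max_size <- assert_count(max_size, "max_size", min = min_size)
  max_size <- min(max_size, length(gene_ids))
  min_size <- min(min_size, max_size)
  set.seed(derive_seed(seed, 2L))
  size_range <- seq(min_size, max_size)
  sizes <- size_range[sample.int(length(size_range), n_sets, replace = TRUE)]
  sets <- lapply(sizes, function(k)
    sample(gene_ids, k, replace = FALSE, prob = weights))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  gene_sets(sets, setNames(rep("synthetic gene set", n_sets), names(sets)))
}

#' Write a simulated experiment to disk
#'
#' Writes one intensity TSV per array (named `<sample_id>.tsv`), the sample
#' sheet as `sample_sheet.tsv`, and the generative ground truth as
#' `ground_truth.json`.
#'
#' @param x a `sim_experiment` from [simulate_experiment()].
#' @param dir output directory, created if needed.
#' @param dialect intensity-table dialect, see [read_intensity_table()].
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir, dialect = "fe") {
  stopifnot(inherits(x, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (arr in x$arrays)
    write_intensity_table(arr, file.path(dir, paste0(attr(arr, "sample_id"),
                                                     ".tsv")), dialect)
  write_sample_sheet(x$sheet, file.path(dir, "sample_sheet.tsv"))
  jsonlite::write_json(x$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
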