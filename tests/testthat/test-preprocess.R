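test_that("M and A follow the log2 ratio definitions", {
  arr <- intensity_array(c("P1", "P2", "P3"), c("G1", "G2", "G3"),
                         red_signal = c(200, 150, 100),
                         green_signal = c(100, 150, 200),
                         sample_id = "s")
  ma <- compute_ma(arr)
  expect_equal(ma$M[1], 1)
  expect_equal(ma$A[1], (log2(200) + log2(100)) / 2)  # = 7.143856
  expect_equal(ma$A[1], 7.1438561897, tolerance = 1e-9)
  expect_equal(ma$M[2], 0)
  expect_equal(ma$M[3], -1)  # channel swap antisymmetry
  expect_equal(ma$A[1], ma$A[3])
})

test_that("loess normalization removes exact linear trends and keeps shifts", {
  set.seed(1)
  A <- runif(200, 6, 14)
  expect_equal(loess_normalize_array(rep(0, 200), A), rep(0, 200))

  M <- 0.5 + 0.1 * A  # exactly linear, no noise
  resid <- loess_normalize_array(M, A)
  interior <- A > quantile(A, 0.1) & A < quantile(A, 0.9)
  expect_lt(max(abs(resid[interior])), 1e-6)

  M2 <- sin(A) + rnorm(200, 0, 0.1)
  expect_equal(loess_normalize_array(M2 + 3.7, A),
               loess_normalize_array(M2, A), tolerance = 1e-10)
})

test_that("loess normalization guards degenerate inputs", {
  expect_error(loess_normalize_array(1:5, 1:5), "at least 10")
  expect_warning(out <- loess_normalize_array(1:20, rep(5, 20)),
                 "constant A")
  expect_equal(out, 1:20 - mean(1:20))
})

test_that("quantile normalization matches the hand-executed reference", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  # ties: sorted row means are (2, 2.5, 3.5); the tied pair spans the two
  # lowest reference quantiles and gets their mean, 2.25
  mt <- cbind(a = c(1, 1, 2), b = c(3, 4, 5))
  expect_equal(unname(quantile_normalize(mt)),
               cbind(c(2.25, 2.25, 3.5), c(2, 2.5, 3.5)))

  same <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)

  set.seed(2)
  big <- matrix(rnorm(200), 50, 4)
  q <- quantile_normalize(big)
  sorted <- apply(q, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)

  expect_error(quantile_normalize(matrix(1:3)), "2 columns")
  big[1, 1] <- NA
  expect_error(quantile_normalize(big), "complete")
})

test_that("duplicate averaging matches direct summation", {
  mat <- rbind(1, 2, 5)
  rownames(mat) <- c("P", "P", "Q")
  out <- average_duplicates(mat)
  expect_equal(unname(out["P", 1]), 1.5)
  expect_equal(unname(out["Q", 1]), 5)

  mat3 <- matrix(c(1, 2, 4, 10, 20, 40), 3,
                 dimnames = list(c("P", "P", "P"), c("s1", "s2")))
  expect_equal(average_duplicates(mat3),
               matrix(c((1 + 2 + 4) / 3, (10 + 20 + 40) / 3), 1,
                      dimnames = list("P", c("s1", "s2"))))

  nodup <- matrix(rnorm(6), 3, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(average_duplicates(nodup), nodup)
})

test_that("variance filter keeps the top fraction with lexicographic ties", {
  set.seed(3)
  mat <- matrix(rnorm(30), 10, 3) * (10:1)
  rownames(mat) <- sprintf("p%02d", 1:10)
  kept <- variance_filter(mat, 0.5)
  expect_equal(nrow(kept), 5L)
  v <- apply(mat, 1, var)
  expect_setequal(rownames(kept), names(sort(v, decreasing = TRUE))[1:5])
  expect_equal(variance_filter(mat, 1), mat)

  # two probes tied exactly at the boundary: lexicographically smaller wins
  tied <- rbind(c(0, 2), c(0, 2), c(0, 1))
  rownames(tied) <- c("zz", "aa", "mm")
  kept2 <- variance_filter(tied, 1 / 3)
  expect_equal(rownames(kept2), "aa")
})

test_that("the normalization chain removes injected dye bias per A-decile", {
  cfg <- simulation_config(
    n_probes = 2000L, duplicate_fraction = 0, n_donors = 2L,
    donor_effect_sd = 0, probe_baseline_sd = 0, platform_effect_sd = 0,
    dye_bias_amplitude = 0.5,
    platform_specs = one_platform(n_replicates = 2L, sigma = 0, kappa = 0),
    seed = 5L)
  ex <- simulate_experiment(cfg, simulate_annotation(cfg))
  for (arr in ex$arrays[1:2]) {
    ma <- compute_ma(arr)
    expect_gt(mean(abs(ma$M)), 0.1)  # bias clearly present before
    Mn <- loess_normalize_array(ma$M, ma$A)
    deciles <- cut(ma$A, quantile(ma$A, 0:10 / 10), include.lowest = TRUE)
    expect_lt(max(abs(tapply(Mn, deciles, mean))), 0.02)
  }
})

test_that("normalize_experiment runs the fixed stage order end to end", {
  cfg <- simulation_config(n_probes = 120L, duplicate_fraction = 0.1,
                           n_donors = 3L,
                           platform_specs = one_platform(n_replicates = 2L),
                           seed = 8L)
  ex <- simulate_experiment(cfg, simulate_annotation(cfg))
  x <- normalize_experiment(ex$arrays, ex$sheet)
  expect_s3_class(x, "expr_matrix")
  expect_equal(dim(x$M), c(120L, 6L))  # duplicates collapsed
  expect_false(anyDuplicated(rownames(x$M)) > 0)
  expect_identical(colnames(x$M), ex$sheet$sample_id)

  xf <- normalize_experiment(ex$arrays, ex$sheet, keep_fraction = 0.25)
  expect_equal(nrow(xf$M), 30L)

  # without on-array duplicates the quantile property survives the chain
  cfg0 <- simulation_config(n_probes = 120L, duplicate_fraction = 0,
                            n_donors = 3L,
                            platform_specs = one_platform(n_replicates = 2L),
                            seed = 8L)
  ex0 <- simulate_experiment(cfg0, simulate_annotation(cfg0))
  x0 <- normalize_experiment(ex0$arrays, ex0$sheet)
  sorted <- apply(x0$M, 2, sort)
  for (j in 2:ncol(sorted))
    expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
})
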