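test_that("Var and FD follow the stated per-donor formulas", {
  # donor A replicates (1.0, 1.2), donor B (0.8, 1.0):
  # Var = (0.02 + 0.02)/2, FD = (0.2 + 0.2)/2
  M <- rbind(p1 = c(1.0, 1.2, 0.8, 1.0),
             p2 = c(2, 2, 2, 2))
  x <- make_expr(M, donors = c("dA", "dA", "dB", "dB"),
                 platforms = rep("X", 4))
  m <- within_platform_metrics(x, "X")
  expect_equal(m$Var[m$probe_id == "p1"], 0.02)
  expect_equal(m$FD[m$probe_id == "p1"], 0.2)
  expect_equal(m$Var[m$probe_id == "p2"], 0)
  expect_equal(m$FD[m$probe_id == "p2"], 0)
  expect_equal(m$meanM[m$probe_id == "p1"], 1.0)
  expect_equal(m$meanA, c(10, 10))
})

test_that("ANOVA p-values match aov on a 3-donor by 3-replicate fixture", {
  set.seed(10)
  M <- matrix(rnorm(9 * 8), 8, 9)
  donors <- rep(c("d1", "d2", "d3"), each = 3)
  x <- make_expr(M, donors = donors, platforms = rep("X", 9))
  m <- within_platform_metrics(x, "X")
  for (i in 1:8) {
    fit <- summary(stats::aov(M[i, ] ~ factor(donors)))
    expect_equal(m$pval[i], fit[[1]][["Pr(>F)"]][1], tolerance = 1e-10)
  }
  # brute-force F from group sums of squares for one probe
  y <- M[1, ]
  grand <- mean(y)
  ssb <- sum(3 * (tapply(y, donors, mean) - grand)^2)
  ssw <- sum((y - rep(tapply(y, donors, mean), each = 3))^2)
  f <- (ssb / 2) / (ssw / 6)
  expect_equal(m$pval[1], stats::pf(f, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("donors with one replicate are dropped with a warning", {
  M <- matrix(rnorm(10 * 5), 10, 5)
  x <- make_expr(M, donors = c("d1", "d1", "d2", "d2", "d3"),
                 platforms = rep("X", 5))
  expect_warning(m <- within_platform_metrics(x, "X"), "d3")
  # meanM still uses all platform samples
  expect_equal(m$meanM, rowMeans(M))
  x2 <- make_expr(M[, 1:3], donors = c("d1", "d1", "d2"),
                  platforms = rep("X", 3))
  expect_warning(expect_error(within_platform_metrics(x2, "X"),
                              ">= 2 donors"), "d2")
})

test_that("one-sample t alternative matches t.test", {
  set.seed(11)
  M <- matrix(rnorm(5 * 6, mean = 0.3), 5, 6)
  x <- make_expr(M, donors = rep(c("d1", "d2", "d3"), each = 2),
                 platforms = rep("X", 6))
  m <- within_platform_metrics(x, "X", pval_method = "ttest")
  for (i in 1:5)
    expect_equal(m$pval[i], stats::t.test(M[i, ])$p.value,
                 tolerance = 1e-10)
})

test_that("cross-platform paired t matches t.test and its conventions", {
  set.seed(12)
  n_probes <- 6
  donors <- sprintf("d%d", 1:8)
  Ma <- matrix(rnorm(n_probes * 8), n_probes, 8)
  Mb <- Ma + matrix(rnorm(n_probes * 8, 0.2, 0.4), n_probes, 8)
  M <- cbind(Ma, Mb)
  x <- make_expr(M, donors = c(donors, donors),
                 platforms = rep(c("A", "B"), each = 8))
  ct <- cross_platform_test(x, "A", "B")
  for (i in 1:n_probes) {
    tt <- stats::t.test(Ma[i, ], Mb[i, ], paired = TRUE)
    expect_equal(ct$pval[i], tt$p.value, tolerance = 1e-10)
    expect_equal(ct$mean_diff[i], unname(tt$estimate), tolerance = 1e-10)
  }

  # identical platforms: every difference zero, p = 1 by convention
  x_id <- make_expr(cbind(Ma, Ma), donors = c(donors, donors),
                    platforms = rep(c("A", "B"), each = 8))
  expect_true(all(cross_platform_test(x_id, "A", "B")$pval == 1))

  # constant nonzero difference: zero variance, p = 0 by convention
  x_c <- make_expr(cbind(Ma, Ma + 0.5), donors = c(donors, donors),
                   platforms = rep(c("A", "B"), each = 8))
  expect_true(all(cross_platform_test(x_c, "A", "B")$pval == 0))

  x_few <- make_expr(M[, c(1, 2, 9, 10)],
                     donors = c("d1", "d2", "d1", "d2"),
                     platforms = c("A", "A", "B", "B"))
  expect_error(cross_platform_test(x_few, "A", "B"), ">= 3")
})

test_that("replicates are averaged per donor before the paired test", {
  # donor means must drive the test, not individual replicates
  M <- rbind(p1 = c(1, 3, 2, 2, 5, 5, 4, 4, 1, 1))
  donors <- c("d1", "d1", "d2", "d3", "d1", "d1", "d2", "d2", "d3", "d3")
  plats <- c(rep("A", 4), rep("B", 6))
  x <- make_expr(M, donors = donors, platforms = plats)
  ct <- cross_platform_test(x, "A", "B")
  diffs <- c(2 - 5, 2 - 4, 2 - 1)  # per-donor A-mean minus B-mean
  tt <- stats::t.test(diffs)
  expect_equal(ct$pval[1], tt$p.value, tolerance = 1e-10)
  expect_equal(ct$mean_diff[1], mean(diffs))
})

test_that("property correlations use the exact t transform", {
  set.seed(13)
  n <- 20
  ann <- simulate_annotation(simulation_config(n_probes = n, seed = 13L))
  metrics <- data.frame(probe_id = ann$probe_id, gene_id = ann$gene_id,
                        platform = "X",
                        Var = 0.5 * scale(ann$GCpercent)[, 1] + rnorm(n),
                        pval = runif(n), FD = abs(rnorm(n)),
                        meanM = rnorm(n), meanA = rnorm(n, 10),
                        stringsAsFactors = FALSE)
  pc <- correlate_with_properties(metrics, ann)
  row <- pc[pc$measure == "Var" & pc$property == "GCpercent", ]
  r <- cor(metrics$Var, ann$GCpercent)
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(row$r, r, tolerance = 1e-12)
  expect_equal(row$p, 2 * stats::pt(-abs(t), n - 2), tolerance = 1e-12)
  # independent check against cor.test
  ct <- stats::cor.test(metrics$Var, ann$GCpercent)
  expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  expect_equal(row$significant, ct$p.value < 0.01)

  # perfectly linear measure: r = 1, p = 0
  metrics$FD <- 2 * ann$GCpercent
  pc2 <- correlate_with_properties(metrics, ann)
  row2 <- pc2[pc2$measure == "FD" & pc2$property == "GCpercent", ]
  expect_equal(row2$r, 1)
  expect_equal(row2$p, 0)

  # constant property: degenerate, flagged missing
  ann$GeneSize <- 1000
  pc3 <- correlate_with_properties(metrics, ann)
  row3 <- pc3[pc3$measure == "Var" & pc3$property == "GeneSize", ]
  expect_true(row3$degenerate)
  expect_true(is.na(row3$r))
  expect_false(row3$significant)
})

test_that("cross-platform p-value columns join the correlation table", {
  cfg <- simulation_config(n_probes = 100L, seed = 14L)
  st <- simulate_study(cfg)
  m <- within_platform_metrics(st$expr, "RNAgard")
  ct <- cross_platform_test(st$expr, "RNAgard", "PAXgene")
  pc <- correlate_with_properties(m, st$annotation,
                                  cross = list(vs_PAXgene = ct))
  expect_setequal(unique(pc$measure), c("Var", "pval", "FD", "vs_PAXgene"))
  expect_equal(sum(pc$measure == "vs_PAXgene"), 7L)  # one per property
})

test_that("variance-vs-GC regression returns the closed-form OLS fit", {
  ann3 <- data.frame(probe_id = c("p1", "p2", "p3"),
                     gene_id = c("g1", "g2", "g3"),
                     Dist3 = 0, Dist5 = 0, TranscriptSize = 100,
                     GeneSize = 100,
                     GCpercent = c(30, 50, 70), stringsAsFactors = FALSE)
  metrics <- data.frame(probe_id = c("p1", "p2", "p3"), platform = "X",
                        Var = c(1, 2, 3), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".png")
  fit <- plot_variance_vs_gc(metrics, ann3, file = path)
  expect_equal(fit$slope, 0.05)   # collinear: exactly 1 Var per 20 GC
  expect_equal(fit$intercept, -0.5)
  expect_true(file.exists(path))

  metrics$Var <- 2
  fit_flat <- plot_variance_vs_gc(metrics, ann3,
                                  file = tempfile(fileext = ".png"))
  expect_equal(fit_flat$slope, 0)
})
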