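test_that("top-variance gene selection counts and ties are deterministic", {
  metrics <- data.frame(probe_id = sprintf("p%03d", 1:100),
                        gene_id = sprintf("g%03d", 1:100),
                        Var = seq(1, 0.01, length.out = 100),
                        stringsAsFactors = FALSE)
  top <- select_top_variance_genes(metrics, fraction = 0.05)
  expect_length(top, 5L)
  expect_equal(top, sprintf("g%03d", 1:5))

  # tie straddling the cut: both orders enumerate to the same answer,
  # the lexicographically smaller gene id
  tied <- data.frame(probe_id = c("p1", "p2", "p3"),
                     gene_id = c("gB", "gA", "gC"),
                     Var = c(1, 1, 0.5), stringsAsFactors = FALSE)
  expect_equal(select_top_variance_genes(tied, fraction = 1 / 3), "gA")
  expect_equal(select_top_variance_genes(tied[c(2, 1, 3), ],
                                         fraction = 1 / 3), "gA")

  allsame <- data.frame(probe_id = paste0("p", 1:4),
                        gene_id = c("gd", "gb", "gc", "ga"),
                        Var = 1, stringsAsFactors = FALSE)
  expect_equal(select_top_variance_genes(allsame, fraction = 0.5),
               c("ga", "gb"))

  # probe-to-gene collapse: max picks the most variable probe per gene
  multi <- data.frame(probe_id = paste0("p", 1:4),
                      gene_id = c("g1", "g1", "g2", "g3"),
                      Var = c(0.1, 3.5, 1, 2), stringsAsFactors = FALSE)
  expect_equal(select_top_variance_genes(multi, fraction = 0.3), "g1")
  expect_equal(select_top_variance_genes(multi, fraction = 0.3,
                                         collapse = "mean"), "g3")
})

test_that("platform-higher selection partitions by sign at the threshold", {
  set.seed(20)
  donors <- sprintf("d%d", 1:8)
  base <- matrix(rnorm(20 * 8, sd = 0.2), 20, 8,
                 dimnames = list(sprintf("p%03d", 1:20), NULL))
  x_id <- make_expr(cbind(base, base), donors = c(donors, donors),
                    platforms = rep(c("A", "B"), each = 8))
  sel <- select_platform_higher_genes(cross_platform_test(x_id, "A", "B"))
  expect_length(sel$higher_in_a, 0L)
  expect_length(sel$higher_in_b, 0L)

  up <- base
  up[1, ] <- base[1, ] + 1  # one probe higher in A for every donor
  x_up <- make_expr(cbind(up, base), donors = c(donors, donors),
                    platforms = rep(c("A", "B"), each = 8))
  sel_up <- select_platform_higher_genes(cross_platform_test(x_up, "A", "B"))
  expect_equal(sel_up$higher_in_a, "g_p001")
  expect_length(sel_up$higher_in_b, 0L)
})

test_that("platform-higher recovery has high sensitivity at delta 1", {
  set.seed(21)
  donors <- sprintf("d%d", 1:8)
  n_genes <- 200
  hit <- 1:50
  sens <- replicate(5, {
    base <- matrix(rnorm(n_genes * 8, sd = 0.3), n_genes, 8,
                   dimnames = list(sprintf("p%03d", 1:n_genes), NULL))
    shifted <- base
    shifted[hit, ] <- shifted[hit, ] + 1 +
      matrix(rnorm(50 * 8, sd = 0.3), 50, 8)
    x <- make_expr(cbind(shifted, base), donors = c(donors, donors),
                   platforms = rep(c("A", "B"), each = 8))
    sel <- select_platform_higher_genes(cross_platform_test(x, "A", "B"),
                                        alpha = 0.05)
    truth <- paste0("g_", rownames(base)[hit])
    length(intersect(sel$higher_in_a, truth)) / length(truth)
  })
  expect_gte(mean(sens), 0.9)
})

test_that("hypergeometric tail equals exhaustive enumeration", {
  universe <- sprintf("G%02d", 1:20)
  sets <- gene_sets(list(s5 = universe[1:5]))
  res <- overrepresentation_test(universe[c(1, 2, 3, 6)], universe, sets)
  expect_equal(res$pval, hyper_tail_enum(3, 5, 20, 4), tolerance = 1e-12)
  expect_equal(res$overlap, 3L)
  expect_equal(res$fold_enrichment, (3 / 4) / (5 / 20))

  # set equal to the universe: overlap is certain, p = 1
  res_all <- overrepresentation_test(universe[1:4], universe,
                                     gene_sets(list(all = universe)))
  expect_equal(res_all$pval, 1)
  # zero overlap: P(X >= 0) = 1
  res_zero <- overrepresentation_test(universe[6:9], universe, sets)
  expect_equal(res_zero$pval, 1)

  expect_error(overrepresentation_test(character(0), universe, sets),
               "empty selection")
  expect_error(overrepresentation_test("missing", universe, sets),
               "not in the universe")
})

test_that("hypergeometric p matches enumeration across random small cases", {
  set.seed(22)
  for (i in 1:30) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n_sel <- sample(1:N, 1)
    universe <- sprintf("g%02d", seq_len(N))
    set <- sample(universe, K)
    selected <- sample(universe, n_sel)
    res <- overrepresentation_test(selected, universe,
                                   gene_sets(list(s = set)))
    k <- length(intersect(set, selected))
    expect_equal(res$pval, hyper_tail_enum(k, K, N, n_sel),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the textbook step-up", {
  set.seed(23)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    universe <- sprintf("g%03d", 1:100)
    sets <- lapply(seq_along(p), function(j) sample(universe, 10))
    names(sets) <- sprintf("s%02d", seq_along(p))
    res <- overrepresentation_test(sample(universe, 15), universe,
                                   gene_sets(sets))
    expect_equal(res$fdr, bh_oracle(res$pval), tolerance = 1e-12)
    expect_true(all(diff(res$pval) >= 0))  # sorted by p
    expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  }
})

test_that("a noise-enriched gene set ranks first in most simulations", {
  # a well-separated noise-prone block: 40 high-GC probes whose GC-linked
  # replicate noise makes them the top-variance genes; the special set is
  # drawn with 5x membership weight on those genes
  n_seeds <- 50
  wins <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(
      n_probes = 800L, duplicate_fraction = 0, n_donors = 8L,
      platform_specs = one_platform(sigma = 0.3, kappa = 0.8), seed = s)
    ann <- simulate_annotation(cfg)
    ann$GCpercent <- c(rep(70, 40), rep(40, 760))
    ex <- simulate_experiment(cfg, ann)
    expr <- normalize_experiment(ex$arrays, ex$sheet)
    m <- within_platform_metrics(expr, "P1")
    top <- select_top_variance_genes(m, fraction = 0.05)
    universe <- sort(unique(expr$genes$gene_id))
    prone_genes <- expr$genes$gene_id[
      expr$genes$probe_id %in% ann$probe_id[1:40]]
    w <- ifelse(universe %in% prone_genes, 5, 1)
    set.seed(1000 + s)
    special <- sample(universe, 80, prob = w)
    others <- simulate_gene_sets(universe, n_sets = 19L, min_size = 30L,
                                 max_size = 50L, seed = s)
    sets <- gene_sets(c(list(SPECIAL = special), others$sets))
    res <- overrepresentation_test(top, universe, sets)
    wins <- wins + (res$set[1] == "SPECIAL")
  }
  expect_gte(wins, 0.9 * n_seeds)
})
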