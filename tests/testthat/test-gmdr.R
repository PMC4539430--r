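test_that("score residuals remove grand and environment means", {
  G <- toy_genotypes(n = 4, p = 2)
  pheno <- tibble::tibble(
    line = rep(line_ids(G), 2), env = rep(1:2, each = 4),
    value = c(1, 3, 5, 7, 2, 2, 2, 2)
  )
  sc <- compute_score_residuals(pheno)
  expect_equal(sc$score[sc$env == 1], c(-3, -1, 1, 3))
  expect_equal(sc$score[sc$env == 2], rep(0, 4))
  expect_lt(max(abs(tapply(sc$score, sc$env, sum))), 1e-9)

  const <- dplyr::mutate(pheno, value = 4)
  expect_true(all(compute_score_residuals(const)$score == 0))
  tiny <- pheno[c(1, 5, 6), ]
  expect_error(compute_score_residuals(tiny), "at least 2")
})

test_that("cells are labeled by the sign of summed training scores", {
  G <- toy_genotypes(n = 4, p = 1)
  scores <- setNames(c(-3, -1, 1, 3), line_ids(G))
  # overwrite codes so genotype matches score sign
  codes <- matrix(c(-1L, -1L, 1L, 1L), 4, 1, dimnames = list(line_ids(G), "M01"))
  G2 <- genotype_matrix(codes, marker_info(G))
  cells <- classify_cells(scores, G2, "M01")
  expect_equal(cells$label[cells$cell == "1"], "HIGH")
  expect_equal(cells$label[cells$cell == "-1"], "LOW")

  all_pos <- classify_cells(abs(scores) + 1, G2, "M01")
  expect_true(all(all_pos$label == "HIGH"))
})

test_that("a perfectly separating marker scores accuracy 1", {
  n <- 40
  codes <- matrix(rep(c(1L, -1L), n / 2), n, 1)
  G <- genotype_matrix(codes, tibble::tibble(marker = "q", chr = 1L, pos_cM = 0))
  pheno <- tibble::tibble(
    line = line_ids(G), env = 1L, value = as.numeric(codes[, 1]) * 2 + 10
  )
  ev <- evaluate_combo(G, pheno, "q", k_folds = 5, seed = 3)
  expect_equal(ev$accuracy, 1)
})

test_that("null-marker accuracy is near one half", {
  accs <- vapply(1:100, function(i) {
    G <- toy_genotypes(n = 200, p = 1, seed = 1000 + i)
    pheno <- toy_phenotypes(G, H = 1, sd = 1, seed = 2000 + i)
    evaluate_combo(G, pheno, "M01", k_folds = 10, seed = i)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("combo evaluation is deterministic given the seed", {
  G <- toy_genotypes(n = 50, p = 3, seed = 4)
  pheno <- toy_phenotypes(G, beta = c(1, 0, 0), seed = 5)
  e1 <- evaluate_combo(G, pheno, c("M01", "M02"), seed = 11)
  e2 <- evaluate_combo(G, pheno, c("M01", "M02"), seed = 11)
  expect_identical(e1$accuracy, e2$accuracy)
})

test_that("the exhaustive search agrees with a brute-force oracle on a toy panel", {
  G <- toy_genotypes(n = 60, p = 6, spacing = 500, seed = 21)
  pheno <- toy_phenotypes(G, beta = c(1.2, 0, 0, 0, 0.8, 0), sd = 1.5, seed = 22)
  k <- 5
  seed <- 31
  scores <- qtsmap:::pooled_scores(pheno, G)
  folds <- screen_folds(length(scores), k, seed)

  # every 1- and 2-locus accuracy from three independent code paths
  mks <- colnames(G)
  for (combo in c(as.list(mks), combn(mks, 2, simplify = FALSE))) {
    oracle <- oracle_combo_accuracy(G, unname(scores), folds, combo)
    pkg <- evaluate_combo(G, pheno, combo, k_folds = k, folds = setNames(folds, names(scores)))
    expect_equal(pkg$accuracy, oracle, tolerance = 1e-12)
  }

  cpp1 <- qtsmap:::.gmdr_search(unclass(G), unname(scores), folds, 1L, 0L)
  oracle1 <- vapply(mks, function(m) oracle_combo_accuracy(G, unname(scores), folds, m), 0)
  expect_equal(cpp1$accuracy, unname(oracle1), tolerance = 1e-12)
  expect_equal(cpp1$n_combos, 6)

  cpp2 <- qtsmap:::.gmdr_search(unclass(G), unname(scores), folds, 2L, 0L)
  prs <- combn(mks, 2, simplify = FALSE)
  oracle2 <- vapply(prs, function(cc) oracle_combo_accuracy(G, unname(scores), folds, cc), 0)
  expect_equal(cpp2$accuracy, oracle2, tolerance = 1e-12)
  expect_equal(cpp2$n_combos, choose(6, 2))

  # the screen retains the oracle's best single-locus model first
  cand <- gmdr_screen(G, pheno,
    max_order = 2, retain = 3, k_folds = k, seed = seed,
    clump_cM = 10, expand_cM = 0, adjust = FALSE
  )
  best1 <- cand$models |> dplyr::filter(order == 1)
  expect_equal(best1$markers[[1]], mks[which.max(oracle1)])
  expect_equal(best1$accuracy[1], max(oracle1), tolerance = 1e-12)
})

test_that("three-locus search returns the top of the full enumeration", {
  G <- toy_genotypes(n = 50, p = 6, seed = 33)
  pheno <- toy_phenotypes(G, beta = c(1, 0, 0, 0, 0, 0), sd = 1, seed = 34)
  scores <- qtsmap:::pooled_scores(pheno, G)
  folds <- screen_folds(length(scores), 5, 35)
  res <- qtsmap:::.gmdr_search(unclass(G), unname(scores), folds, 3L, 4L)
  combos <- combn(colnames(G), 3, simplify = FALSE)
  oracle3 <- vapply(combos, function(cc) oracle_combo_accuracy(G, unname(scores), folds, cc), 0)
  top <- sort(oracle3, decreasing = TRUE)[1:4]
  expect_equal(sort(res$accuracy, decreasing = TRUE), unname(top), tolerance = 1e-12)
})

test_that("the search refuses when the combination budget is exceeded", {
  G <- toy_genotypes(n = 30, p = 20, seed = 2)
  pheno <- toy_phenotypes(G, seed = 3)
  expect_error(
    gmdr_screen(G, pheno, max_order = 3, budget = 100),
    "budget"
  )
})

test_that("screening output is stable under line-order permutation with fixed folds", {
  G <- toy_genotypes(n = 60, p = 8, spacing = 300, seed = 41)
  pheno <- toy_phenotypes(G, beta = c(1, rep(0, 7)), seed = 42)
  c1 <- gmdr_screen(G, pheno, max_order = 1, retain = 4, seed = 7, adjust = FALSE)
  # permute line order in both genotypes and phenotypes: the fold draw is
  # positional, so the partition changes, but a clearly separating marker
  # must stay on top (equality in distribution, checked at the mode)
  set.seed(99)
  ord <- sample(nrow(G))
  Gp <- unclass(G)[ord, , drop = FALSE]
  Gp <- genotype_matrix(Gp, marker_info(G))
  c2 <- gmdr_screen(Gp, pheno, max_order = 1, retain = 4, seed = 7, adjust = FALSE)
  expect_equal(c1$models$markers[[1]], c2$models$markers[[1]])
})

test_that("candidate clusters and nominated pairs are well formed", {
  sc <- qts_scenario(n = 120, h2 = 0.7, truth = "large", reps = 1, seed = 77)
  dat <- qtsmap:::sim_scenario_replicate(sc, 78)
  cand <- gmdr_screen(dat$G, dat$pheno, seed = 78)
  cc <- cand$candidates
  expect_true(all(cc$cluster %in% cc$marker))
  expect_false(any(duplicated(cc$marker)))
  if (!is.null(cand$nominated) && nrow(cand$nominated)) {
    expect_true(all(cand$nominated$c1 != cand$nominated$c2))
    expect_true(all(cand$nominated$c1 %in% cc$cluster))
  }
})
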