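test_that("coincident markers are perfect copies and map validation works", {
  map <- tibble::tibble(
    marker = c("a", "b", "c"), chr = c(1L, 1L, 1L), pos_cM = c(0, 0, 30)
  )
  G <- sim_ril_genotypes(map, n = 200, seed = 5)
  expect_identical(G[, "a"], G[, "b"])
  expect_error(sim_ril_genotypes(map[0, ], 10), "empty")
  expect_error(
    sim_ril_genotypes(tibble::tibble(marker = c("a", "b"), chr = 1L, pos_cM = c(5, 1)), 10),
    "non-decreasing"
  )
})

test_that("cross-chromosome markers are unlinked (R near 0.5)", {
  map <- genetic_map(2, 1, 1)
  n <- 2000
  G <- sim_ril_genotypes(map, n, seed = 42)
  Rhat <- mean(G[, 1] != G[, 2])
  se <- sqrt(0.25 / n)
  expect_lt(abs(Rhat - 0.5), 3 * se)
})

test_that("adjacent-marker switch frequency matches 2r/(1+2r)", {
  map <- genetic_map(1, 2, 1)
  n <- 5000
  G <- sim_ril_genotypes(map, n, seed = 7)
  r <- recombination_fraction(1)
  R <- 2 * r / (1 + 2 * r)
  Rhat <- mean(G[, 1] != G[, 2])
  expect_lt(abs(Rhat - R), 3 * sqrt(R * (1 - R) / n))
})

test_that("genotype columns are balanced with unit variance as n grows", {
  G <- sim_ril_genotypes(genetic_map(1, 30, 5), n = 4000, seed = 9)
  cm <- colMeans(G)
  expect_lt(max(abs(cm)), 3.5 * sqrt(1 / 4000) + 0.02)
  expect_lt(max(abs(apply(G, 2, var) - 1)), 0.05)
})

test_that("fixed seed makes the simulator bit-reproducible", {
  map <- genetic_map(2, 10, 2)
  G1 <- sim_ril_genotypes(map, 50, seed = 123)
  G2 <- sim_ril_genotypes(map, 50, seed = 123)
  expect_identical(unclass(G1), unclass(G2))
  eff <- qts_truth_reference("large")
  eff$sigma2 <- 2
  sc <- qts_scenario(n = 30, h2 = 0.7, truth = "large", reps = 1, seed = 9)
  r1 <- qtsmap:::sim_scenario_replicate(sc, 17)
  r2 <- qtsmap:::sim_scenario_replicate(sc, 17)
  expect_identical(r1$pheno, r2$pheno)
})

test_that("residual variance solves the target heritability", {
  n <- 100
  codes <- matrix(rep(c(1L, -1L), n / 2), n, 1)
  G <- genotype_matrix(codes, tibble::tibble(marker = "q1", chr = 1L, pos_cM = 0))
  eff <- qts_effects(
    mu = 0, env = 0,
    additive = tibble::tibble(marker = "q1", a = 1, ae = list(0))
  )
  expect_equal(resolve_residual_variance(eff, G, 1), 0)
  expect_equal(resolve_residual_variance(eff, G, 0.5), 1, tolerance = 1e-12)
  effz <- qts_effects(mu = 0, env = 0)
  expect_error(resolve_residual_variance(effz, G, 0.5), "zero")
  expect_error(resolve_residual_variance(eff, G, 1.2), "\\(0, 1\\]")
})

test_that("realized heritability tracks the target across replicates", {
  sc <- qts_scenario(n = 150, h2 = 0.7, truth = "large", reps = 1, seed = 400)
  h2hat <- vapply(1:20, function(r) {
    dat <- qtsmap:::sim_scenario_replicate(sc, 400 + r)
    comp <- qtsmap:::genetic_variance_components(dat$truth, dat$G)
    con <- qtsmap:::effect_contributions(dat$truth, dat$G)
    genet <- rowSums(con$contributions)
    resid <- dat$pheno$value - dat$truth$mu -
      rep(dat$truth$env, each = nrow(dat$G)) - genet
    vg <- sum(comp$variance)
    vg / (vg + mean(resid^2))
  }, 0)
  expect_lt(abs(mean(h2hat) - 0.7), 0.03)
})

test_that("phenotype generation is exact in degenerate cases", {
  G <- toy_genotypes(n = 30, p = 3, seed = 3)
  eff0 <- qts_effects(mu = 5, env = c(2, -2), sigma2 = 0)
  y <- sim_phenotypes(G, eff0)
  expect_equal(unique(y$value[y$env == 1]), 7)
  expect_equal(unique(y$value[y$env == 2]), 3)

  eff1 <- qts_effects(
    mu = 10, env = 0,
    additive = tibble::tibble(marker = "M02", a = 1.5, ae = list(0)),
    sigma2 = 0
  )
  y1 <- sim_phenotypes(G, eff1)
  expect_setequal(unique(y1$value), c(8.5, 11.5))
})

test_that("phenotype variance follows the accounting within tolerance", {
  sc <- qts_scenario(n = 150, h2 = 0.7, truth = "large", reps = 1, seed = 880)
  ratio <- vapply(1:20, function(r) {
    dat <- qtsmap:::sim_scenario_replicate(sc, 880 + r)
    comp <- sum(qtsmap:::genetic_variance_components(dat$truth, dat$G)$variance)
    expected <- comp + dat$truth$sigma2 + qtsmap:::pop_var(rep(dat$truth$env, each = nrow(dat$G)))
    var(dat$pheno$value) / expected
  }, 0)
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("reference truth sets carry the benchmark configuration", {
  tl <- qts_truth_reference("large")
  ts <- qts_truth_reference("small")
  expect_equal(tl$additive$a, c(-3.24, -2.65, -1.77))
  expect_equal(ts$epistatic$aa, 0.39)
  expect_equal(vapply(tl$additive$ae, sum, 0), rep(0, 3))
  sc <- qts_scenario(n = 150, h2 = 0.7, truth = "large", reps = 2, seed = 1)
  expect_s3_class(sc, "qts_scenario")
  expect_error(
    qts_scenario(n = 150, h2 = 0.7, truth = tl, map = genetic_map(1, 5, 1), reps = 1),
    "must exist"
  )
})
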