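empty_model <- function() {
  structure(
    list(
      additive = tibble::tibble(marker = character(), chr = integer(), pos_cM = numeric()),
      epistatic = tibble::tibble(marker1 = character(), marker2 = character())
    ),
    class = "qts_model"
  )
}

model_of <- function(markers, G, pairs = NULL) {
  mk <- marker_info(G)
  structure(
    list(
      additive = mk[match(markers, mk$marker), c("marker", "chr", "pos_cM")],
      epistatic = pairs %||%
        tibble::tibble(marker1 = character(), marker2 = character())
    ),
    class = "qts_model"
  )
}

test_that("an intercept-only model recovers the sample mean (conjugate check)", {
  G <- toy_genotypes(n = 200, p = 2, seed = 121)
  set.seed(122)
  pheno <- tibble::tibble(line = line_ids(G), env = 1L, value = rnorm(200, 5, 1))
  fit <- fit_qts_mcmc(G, pheno, empty_model(),
    iterations = 3000, burnin = 500,
    seed = 123
  )
  mu <- fit[fit$effect == "mu", ]
  expect_lt(abs(mu$estimate - mean(pheno$value)), 3 * mu$sd)
  expect_equal(attr(fit, "total_h2"), 0)
})

test_that("chains are identical under a fixed seed", {
  G <- toy_genotypes(n = 60, p = 4, spacing = 300, seed = 131)
  pheno <- toy_phenotypes(G, beta = c(1, 0, 0, 0), seed = 132)
  m <- model_of(c("M01", "M02"), G)
  f1 <- fit_qts_mcmc(G, pheno, m, iterations = 2000, burnin = 200, seed = 7)
  f2 <- fit_qts_mcmc(G, pheno, m, iterations = 2000, burnin = 200, seed = 7)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$sd, f2$sd)
})

test_that("posterior means recover the generating effects", {
  map <- genetic_map(4, 1, 1) # 4 unlinked markers
  G <- sim_ril_genotypes(map, 200, seed = 141)
  truth <- qts_effects(
    mu = 12, env = c(1, -1),
    additive = tibble::tibble(
      marker = c("S1_1", "S2_1"), a = c(1.4, -0.9),
      ae = list(c(0.6, -0.6), c(0, 0))
    ),
    epistatic = tibble::tibble(
      marker1 = "S3_1", marker2 = "S4_1", aa = 0.8, aae = list(c(0.4, -0.4))
    ),
    sigma2 = 1.5
  )
  pheno <- sim_phenotypes(G, truth, seed = 142)
  m <- model_of(c("S1_1", "S2_1", "S3_1", "S4_1"), G,
    pairs = tibble::tibble(marker1 = "S3_1", marker2 = "S4_1")
  )
  fit <- fit_qts_mcmc(G, pheno, m, seed = 143)
  get <- function(term, effect) fit[fit$term == term & fit$effect == effect, ]
  r <- get("S1_1", "a")
  expect_lt(abs(r$estimate - 1.4), 3.5 * r$sd)
  r <- get("S1_1", "ae1")
  expect_lt(abs(r$estimate - 0.6), 3.5 * r$sd)
  r <- get("S3_1 x S4_1", "aa")
  expect_lt(abs(r$estimate - 0.8), 3.5 * r$sd)
  # sum-to-zero convention on the derived environment interactions
  ae <- fit[grepl("^ae", fit$effect) & fit$term == "S1_1", "estimate"]
  expect_lt(abs(sum(ae$estimate)), 1e-9)
  expect_true(attr(fit, "converged"))
  # strong effects are declared significant by the posterior t test
  expect_gt(get("S1_1", "a")$neg_log10_p, 3)
})

test_that("total heritability on the benchmark scenario is near the target", {
  sc <- qts_scenario(n = 150, h2 = 0.7, truth = "large", reps = 1, seed = 151)
  tot <- vapply(1:3, function(r) {
    dat <- qtsmap:::sim_scenario_replicate(sc, 151 + r)
    m <- model_of(
      c("S1_28", "S2_100", "S3_93"), dat$G,
      pairs = tibble::tibble(marker1 = "S2_44", marker2 = "S3_63")
    )
    fit <- fit_qts_mcmc(dat$G, dat$pheno, m, seed = 151 + r)
    attr(fit, "total_h2")
  }, 0)
  expect_lt(abs(mean(tot) - 70), 10)
})

test_that("spurious epistatic terms stay non-significant on additive-only data", {
  map <- genetic_map(4, 1, 1)
  flags <- vapply(1:10, function(r) {
    G <- sim_ril_genotypes(map, 150, seed = 160 + r)
    truth <- qts_effects(
      mu = 5, env = c(1, -1),
      additive = tibble::tibble(
        marker = c("S1_1", "S2_1"), a = c(1.2, -0.8),
        ae = list(c(0.4, -0.4), c(0, 0))
      ),
      sigma2 = 1.5
    )
    pheno <- sim_phenotypes(G, truth, seed = 260 + r)
    m <- model_of(c("S1_1", "S2_1", "S3_1", "S4_1"), G,
      pairs = tibble::tibble(marker1 = "S3_1", marker2 = "S4_1")
    )
    fit <- fit_qts_mcmc(G, pheno, m, iterations = 4000, burnin = 1000, seed = 360 + r)
    fit$neg_log10_p[fit$effect == "aa"] < 2
  }, TRUE)
  expect_gte(sum(flags), 8)
})

test_that("dropping a zero-effect term barely moves the other estimates", {
  map <- genetic_map(3, 1, 1)
  G <- sim_ril_genotypes(map, 150, seed = 171)
  truth <- qts_effects(
    mu = 0, env = c(1, -1),
    additive = tibble::tibble(marker = "S1_1", a = 1.3, ae = list(c(0.5, -0.5))),
    sigma2 = 1
  )
  pheno <- sim_phenotypes(G, truth, seed = 172)
  full <- fit_qts_mcmc(G, pheno, model_of(c("S1_1", "S2_1"), G), seed = 173)
  slim <- fit_qts_mcmc(G, pheno, model_of("S1_1", G), seed = 173)
  a_full <- full[full$term == "S1_1" & full$effect == "a", ]
  a_slim <- slim[slim$term == "S1_1" & slim$effect == "a", ]
  expect_lt(abs(a_full$estimate - a_slim$estimate), a_full$sd)
})

test_that("build_full_model assembles hierarchical terms from the scan", {
  sc0 <- qts_scenario(n = 150, h2 = 0.7, truth = "large", reps = 1, seed = 181)
  dat <- qtsmap:::sim_scenario_replicate(sc0, 182)
  cand <- gmdr_screen(dat$G, dat$pheno, seed = 182)
  scan <- qts_scan(dat$G, dat$pheno, cand, B = 50, seed = 183)
  model <- build_full_model(scan)
  # pair members get additive terms even if not 1D-significant
  if (nrow(model$epistatic)) {
    for (r in seq_len(nrow(model$epistatic))) {
      mk <- marker_info(dat$G)
      for (m in c(model$epistatic$marker1[r], model$epistatic$marker2[r])) {
        i <- match(m, mk$marker)
        covered <- any(model$additive$chr == mk$chr[i] &
          abs(model$additive$pos_cM - mk$pos_cM[i]) <= 20)
        expect_true(covered)
      }
    }
    expect_true(all(model$epistatic$marker1 < model$epistatic$marker2))
  }
  # no two additive terms inside one clump window
  if (nrow(model$additive) > 1) {
    d <- as.matrix(dist(model$additive$pos_cM))
    same <- outer(model$additive$chr, model$additive$chr, "==")
    diag(same) <- FALSE
    expect_false(any(same & d <= 20))
  }
})

test_that("no significant terms yields an intercept + environment model", {
  G <- toy_genotypes(n = 40, p = 4, spacing = 300, seed = 191)
  pheno <- toy_phenotypes(G, seed = 192)
  scan <- qts_scan(G, pheno, colnames(G), B = 100, alpha = 0.01, seed = 193)
  if (!any(scan$significant)) {
    expect_message(model <- build_full_model(scan), "no significant")
    expect_equal(nrow(model$additive), 0)
  } else {
    succeed()
  }
})

test_that("the architecture report carries the expected schema", {
  map <- genetic_map(2, 1, 1)
  G <- sim_ril_genotypes(map, 120, seed = 201)
  truth <- qts_effects(
    mu = 2, env = c(1, -1),
    additive = tibble::tibble(marker = "S1_1", a = 1.5, ae = list(c(0.5, -0.5))),
    sigma2 = 1
  )
  pheno <- sim_phenotypes(G, truth, seed = 202)
  fit <- fit_qts_mcmc(G, pheno, model_of("S1_1", G), seed = 203)
  rep_ <- summarize_architecture(fit, G, trait = "demo")
  expect_named(
    rep_,
    c("trait", "qts", "chr", "allele", "effect", "estimate", "neg_log10_p", "h2", "total_h2")
  )
  expect_true(all(rep_$trait == "demo"))
  expect_equal(rep_$allele[1], "A/B")

  empty_fit <- fit_qts_mcmc(G, pheno, empty_model(),
    iterations = 1500,
    burnin = 200, seed = 204
  )
  expect_equal(nrow(summarize_architecture(empty_fit, G)), 0)
})
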