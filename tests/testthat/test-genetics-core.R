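test_that("Haldane map function matches its closed form and limits", {
  expect_equal(recombination_fraction(0), 0)
  expect_equal(recombination_fraction(50), (1 - exp(-1)) / 2, tolerance = 1e-12)
  expect_lt(abs(recombination_fraction(1e4) - 0.5), 1e-12)
  d <- seq(0, 300, by = 0.5)
  r <- recombination_fraction(d)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < 0.5 + 1e-12))
  expect_error(recombination_fraction(-1), "non-negative")
})

test_that("RIL recombination fraction matches the selfing fixation oracle", {
  expect_equal(ril_recombination_fraction(0), 0)
  expect_equal(ril_recombination_fraction(0.5), 0.5)
  expect_equal(ril_recombination_fraction(0.25), 1 / 3, tolerance = 1e-12)

  # exact Markov-chain oracle: iterate the selfing process on two-locus
  # diplotypes (unordered pairs of haplotypes AB, ab, Ab, aB) until
  # fixation and read off the mass on recombinant homozygotes
  selfing_fixation_R <- function(r) {
    haps <- c("AB", "ab", "Ab", "aB")
    gamete_probs <- function(h1, h2) {
      # gametes of a diplotype h1/h2 with recombination r
      if (h1 == h2) {
        return(setNames(as.numeric(haps == h1), haps))
      }
      a1 <- strsplit(h1, "")[[1]]
      a2 <- strsplit(h2, "")[[1]]
      rec1 <- paste0(a1[1], a2[2])
      rec2 <- paste0(a2[1], a1[2])
      p <- setNames(numeric(4), haps)
      p[h1] <- p[h1] + (1 - r) / 2
      p[h2] <- p[h2] + (1 - r) / 2
      p[rec1] <- p[rec1] + r / 2
      p[rec2] <- p[rec2] + r / 2
      p
    }
    states <- t(combn(c(haps, haps), 2))
    states <- unique(apply(states, 1, function(x) paste(sort(x), collapse = "/")))
    trans <- matrix(0, length(states), length(states),
      dimnames = list(states, states)
    )
    for (s in states) {
      hh <- strsplit(s, "/")[[1]]
      gp <- gamete_probs(hh[1], hh[2])
      for (i in seq_along(haps)) {
        for (j in seq_along(haps)) {
          child <- paste(sort(c(haps[i], haps[j])), collapse = "/")
          trans[s, child] <- trans[s, child] + gp[i] * gp[j]
        }
      }
    }
    v <- setNames(numeric(length(states)), states)
    v["AB/ab"] <- 1
    for (g in 1:500) v <- as.numeric(v %*% trans) |> setNames(states)
    unname(v["Ab/Ab"] + v["aB/aB"])
  }
  for (r in c(0.05, 0.25, 0.4)) {
    expect_equal(ril_recombination_fraction(r), selfing_fixation_R(r),
      tolerance = 1e-8
    )
  }
  rs <- seq(0.01, 0.49, by = 0.02)
  expect_true(all(ril_recombination_fraction(rs) > rs))
  expect_error(ril_recombination_fraction(0.6), "\\[0, 0.5\\]")
})

test_that("genotype coding follows allele frequency with lexicographic ties", {
  calls <- rbind(
    L1 = c(m1 = "GG", m2 = "GA", m3 = "GG"),
    L2 = c("GG", "AA", "AA"),
    L3 = c("GG", "GG", NA),
    L4 = c("AA", "AA", "AA")
  )
  G <- code_genotypes(calls, max_het = 1, max_missing = 1)
  expect_equal(unname(G[, "m1"]), c(1L, 1L, 1L, -1L)) # G is high-frequency
  # m2: A appears 5x vs G 3x -> AA is +1; heterozygote -> 0
  expect_equal(unname(G[, "m2"]), c(0L, 1L, -1L, 1L))
  # m3: G appears 2x, A appears 4x -> A homozygote is +1
  expect_equal(unname(G[, "m3"]), c(-1L, 1L, NA, 1L))

  # exact frequency tie: A < G lexicographically, so AA -> +1
  tie <- rbind(L1 = c(mt = "GG"), L2 = "AA")
  Gt <- code_genotypes(tie)
  expect_equal(unname(Gt[, "mt"]), c(-1L, 1L))

  expect_error(
    code_genotypes(rbind(c(bad = "GG"), "AA", "TT")),
    "bad.*3 alleles|3 alleles.*bad"
  )
  expect_warning(
    Gm <- code_genotypes(cbind(mono = c("GG", "GG"), ok = c("GG", "AA"))),
    "monomorphic"
  )
  expect_equal(colnames(Gm), "ok")
})

test_that("coding then decoding recovers homozygous calls", {
  calls <- rbind(
    L1 = c(m1 = "GG", m2 = "CC"),
    L2 = c("AA", "CC"),
    L3 = c("GG", "TT"),
    L4 = c("AA", "TT"),
    L5 = c("GG", "CC")
  )
  G <- code_genotypes(calls)
  expect_identical(decode_genotypes(G), calls)
})

test_that("genotype matrix validates heterozygosity and missingness ceilings", {
  mk <- tibble::tibble(marker = "m1", chr = 1L, pos_cM = 0)
  expect_error(
    genotype_matrix(matrix(c(1L, 0L, -1L), 3, 1), mk, max_het = 0),
    "heterozygosity"
  )
  expect_error(
    genotype_matrix(matrix(c(1L, NA, NA), 3, 1), mk, max_missing = 0.2),
    "missingness"
  )
  expect_s3_class(
    genotype_matrix(matrix(c(1L, -1L, 1L), 3, 1), mk),
    "genotype_matrix"
  )
})

test_that("heritability partition matches the balanced closed form", {
  n <- 100
  codes <- matrix(rep(c(1L, -1L), n / 2), n, 1)
  G <- genotype_matrix(
    codes,
    tibble::tibble(marker = "q1", chr = 1L, pos_cM = 0)
  )
  a <- 1.5
  s2 <- 4
  eff <- qts_effects(
    mu = 0, env = 0,
    additive = tibble::tibble(marker = "q1", a = a, ae = list(0)),
    sigma2 = s2
  )
  h2 <- partition_heritability(eff, G)
  expect_equal(h2$h2[h2$effect == "a"], 100 * a^2 / (a^2 + s2), tolerance = 1e-12)
})

test_that("component heritabilities sum exactly to the total", {
  G <- toy_genotypes(n = 60, p = 5, seed = 11)
  eff <- qts_effects(
    mu = 3, env = c(1, -1),
    additive = tibble::tibble(
      marker = c("M01", "M03"), a = c(1.2, -0.7),
      ae = list(c(0.5, -0.5), c(-0.2, 0.2))
    ),
    epistatic = tibble::tibble(
      marker1 = "M02", marker2 = "M05", aa = 0.8, aae = list(c(0.3, -0.3))
    ),
    sigma2 = 2.3
  )
  h2 <- partition_heritability(eff, G)
  expect_equal(sum(h2$h2), attr(h2, "total_h2"), tolerance = 1e-9)
  expect_true(attr(h2, "total_h2") <= 100)
  expect_true(attr(h2, "total_h2") >= max(h2$h2))

  # invariance under relabeling of lines
  Gp <- G[sample(nrow(G)), , drop = FALSE]
  attr(Gp, "markers") <- marker_info(G)
  class(Gp) <- class(G)
  h2p <- partition_heritability(eff, Gp)
  expect_equal(h2$h2, h2p$h2, tolerance = 1e-12)
})

test_that("zero genetic effects give zero component heritability", {
  G <- toy_genotypes(n = 20, p = 2)
  eff <- qts_effects(
    mu = 1, env = c(1, -1),
    additive = tibble::tibble(marker = "M01", a = 0, ae = list(c(0, 0))),
    sigma2 = 1
  )
  h2 <- partition_heritability(eff, G)
  expect_true(all(h2$h2 == 0))
  effz <- qts_effects(mu = 1, env = 0, sigma2 = 0)
  expect_error(partition_heritability(effz, G), "zero")
})

test_that("effect sets enforce the sum-to-zero convention unless disabled", {
  expect_error(
    qts_effects(
      env = c(1, -1),
      additive = tibble::tibble(marker = "x", a = 1, ae = list(c(1, 1)))
    ),
    "sum to zero"
  )
  eff <- qts_effects(
    env = c(1, -1),
    additive = tibble::tibble(marker = "x", a = 1, ae = list(c(1, 1))),
    sum_to_zero = FALSE
  )
  expect_s3_class(eff, "qts_effects")
})
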