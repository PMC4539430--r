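#' Simulate recombinant inbred line genotypes
#'
#' Generates `n` independent fully homozygous RILs along a genetic map.
#' Each chromosome is a first-order Markov chain: the first marker's allele
#' is +1/-1 with probability 1/2, and each subsequent marker switches sign
#' with probability \eqn{R = 2r/(1+2r)} where `r` is the Haldane
#' single-meiosis recombination fraction for the inter-marker distance.
#' This is exact for all pairwise RIL expectations under no interference,
#' without simulating whole-gamete crossovers. Chromosomes are independent;
#' no heterozygous or missing calls are produced.
#'
#' @param map A genetic map tibble (see [genetic_map()]).
#' @param n Number of lines.
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()].
#' @examples
#' G <- sim_ril_genotypes(genetic_map(1, 20, 5), n = 10, seed = 1)
#' @export
sim_ril_genotypes <- function(map, n, seed = NULL) {
  validate_map(map)
  if (nrow(map) == 0) abort("`map` is empty.")
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  chrs <- split(seq_len(nrow(map)), map$chr)
  out <- matrix(NA_integer_, n, nrow(map))
  for (ix in chrs) {
    pos <- map$pos_cM[ix]
    m <- length(ix)
    R <- if (m > 1) {
      ril_recombination_fraction(recombination_fraction(diff(pos)))
    } else {
      numeric(0)
    }
    x <- matrix(0L, n, m)
    x[, 1] <- ifelse(runif(n) < 0.5, 1L, -1L)
    if (m > 1) {
      sw <- matrix(runif(n * (m - 1)), n, m - 1) < rep(R, each = n)
      flip <- t(apply(cbind(1L, ifelse(sw, -1L, 1L)), 1, cumprod))
      x <- x[, 1] * flip
    }
    out[, ix] <- x
  }
  mk <- tibble::as_tibble(map)
  mk$allele_high <- "A"
  mk$allele_low <- "B"
  rownames(out) <- sprintf("L%03d", seq_len(n))
  genotype_matrix(out, mk)
}

#' Resolve the residual variance for a target heritability
#'
#' Solves for \eqn{\sigma^2_\epsilon} so that the genetic fraction of
#' modeled phenotypic variance equals `h2_target`:
#' \eqn{V_G / (V_G + \sigma^2_\epsilon) = h^2}, where \eqn{V_G} is the sum
#' of the empirical variances of every genetic term (a, aa, ae, aae) over
#' the realized design (environment main effects excluded, matching
#' [partition_heritability()]).
#'
#' @param effects A [qts_effects()] truth set.
#' @param G A [genotype_matrix()].
#' @param h2_target Target heritability in `(0, 1]`.
#' @return The residual variance (a single number).
#' @export
resolve_residual_variance <- function(effects, G, h2_target) {
  if (!is.numeric(h2_target) || h2_target <= 0 || h2_target > 1) {
    abort("`h2_target` must be in (0, 1].")
  }
  vg <- sum(genetic_variance_components(effects, G)$variance)
  if (vg <= 0) abort("genetic variance of the truth on this population is zero.")
  vg * (1 - h2_target) / h2_target
}

#' Simulate phenotypes from a QTS effect set
#'
#' Draws \eqn{y_{hk} = \mu + \sum_i x_{ik} a_i + \sum_{i<j} x_{ik}x_{jk}
#' aa_{ij} + e_h + \sum x_{ik} ae_{hi} + \sum x_{ik}x_{jk} aae_{hij} +
#' \epsilon_{hk}} with i.i.d. normal residuals of variance
#' `effects$sigma2`. Environment main effects are the fixed values stored
#' in `effects$env` (the default convention; see the methods vignette).
#'
#' @param G A [genotype_matrix()].
#' @param effects A [qts_effects()]; `sigma2 = NA` is treated as 0.
#' @param seed Optional integer seed.
#' @return Phenotype tibble with columns `line`, `env`, `value`, ordered
#'   environment-major.
#' @export
sim_phenotypes <- function(G, effects, seed = NULL) {
  stopifnot(inherits(effects, "qts_effects"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G)
  H <- effects$n_env
  con <- effect_contributions(effects, G)
  genet <- if (ncol(con$contributions)) rowSums(con$contributions) else rep(0, n * H)
  sigma2 <- effects$sigma2
  if (is.na(sigma2)) sigma2 <- 0
  if (sigma2 < 0) abort("sigma2 must be non-negative.")
  eps <- if (sigma2 > 0) rnorm(n * H, 0, sqrt(sigma2)) else rep(0, n * H)
  tibble::tibble(
    line = rep(line_ids(G), times = H),
    env = rep(seq_len(H), each = n),
    value = effects$mu + rep(effects$env, each = n) + genet + eps
  )
}

validate_phenotypes <- function(pheno, G = NULL) {
  stopifnot(is.data.frame(pheno), all(c("line", "env", "value") %in% names(pheno)))
  if (dplyr::n_distinct(pheno$env) < 1) abort("at least one environment is required.")
  dup <- pheno |>
    dplyr::count(.data$line, .data$env) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicated (line, environment) rows: %s",
      paste(sprintf("(%s, %s)", dup$line, dup$env), collapse = ", ")
    ))
  }
  if (!is.null(G)) {
    unknown <- setdiff(unique(pheno$line), line_ids(G))
    if (length(unknown)) {
      abort(paste0("phenotype lines absent from genotypes: ", paste(unknown, collapse = ", ")))
    }
  }
  invisible(pheno)
}

#' Benchmark QTS truth sets
#'
#' The two effect configurations used throughout the package's replicated
#' simulation study on the standard 3 x 175 marker map: three additive QTSs
#' (chr1 marker 28, chr2 marker 100, chr3 marker 93) with
#' additive-by-environment effects, and one epistatic pair
#' (chr2 marker 44 x chr3 marker 63) with epistasis-by-environment effects,
#' in two environments. `"large"` is the strong-effect configuration
#' (additive effects around -1.8 to -3.2 trait units); `"small"` the
#' weak-effect one (around -0.4 to -0.8). Residual variance is left
#' unresolved; use [resolve_residual_variance()] with a target
#' heritability.
#'
#' @param scale `"large"` or `"small"`.
#' @param mu Population mean.
#' @param env Environment main effects (fixed, sum to zero by default).
#' @return A [qts_effects()].
#' @export
qts_truth_reference <- function(scale = c("large", "small"), mu = 20, env = c(1, -1)) {
  scale <- match.arg(scale)
  if (scale == "large") {
    additive <- tibble::tibble(
      marker = c("S1_28", "S2_100", "S3_93"),
      a = c(-3.24, -2.65, -1.77),
      ae = list(c(2.65, -2.65), c(4.05, -4.05), c(3.24, -3.24))
    )
    epistatic <- tibble::tibble(
      marker1 = "S2_44", marker2 = "S3_63",
      aa = 3.86, aae = list(c(4.47, -4.47))
    )
  } else {
    additive <- tibble::tibble(
      marker = c("S1_28", "S2_100", "S3_93"),
      a = c(-0.79, -0.67, -0.40),
      ae = list(c(0.63, -0.63), c(0.39, -0.39), c(0.32, -0.32))
    )
    epistatic <- tibble::tibble(
      marker1 = "S2_44", marker2 = "S3_63",
      aa = 0.39, aae = list(c(0.17, -0.17))
    )
  }
  qts_effects(mu = mu, env = env, additive = additive, epistatic = epistatic)
}

#' Define a simulation scenario
#'
#' Bundles everything needed for a replicated power study: the map, the
#' truth, the population size, the target heritability (the residual
#' variance is re-solved on each replicate's realized genotypes), and the
#' base seed from which per-replicate seeds are derived as
#' `seed + replicate`.
#'
#' @param n Population size (lines).
#' @param h2 Target heritability in `(0, 1]`.
#' @param truth A [qts_effects()] truth set (without `sigma2`), or the
#'   character scale passed to [qts_truth_reference()].
#' @param map Genetic map; defaults to the standard 3 x 175, 1 cM layout.
#' @param reps Number of replicates.
#' @param seed Base seed.
#' @param sigma2 Optional fixed residual variance; when supplied it is used
#'   directly instead of being solved from `h2` on each replicate's
#'   genotypes (required for null scenarios, whose genetic variance is 0).
#' @return Object of class `qts_scenario`.
#' @examples
#' sc <- qts_scenario(n = 150, h2 = 0.7, truth = "large", reps = 5, seed = 1)
#' @export
qts_scenario <- function(n, h2, truth = "large", map = genetic_map(),
                         reps = 200, seed = 1L, sigma2 = NULL) {
  if (is.character(truth)) truth <- qts_truth_reference(truth)
  stopifnot(inherits(truth, "qts_effects"), n >= 2, reps >= 1)
  if (h2 <= 0 || h2 > 1) abort("`h2` must be in (0, 1].")
  validate_map(map)
  need <- c(truth$additive$marker, truth$epistatic$marker1, truth$epistatic$marker2)
  if (!all(need %in% map$marker)) abort("truth markers must exist on the map.")
  structure(
    list(
      n = n, h2 = h2, truth = truth, map = map, reps = reps,
      seed = as.integer(seed), sigma2 = sigma2
    ),
    class = "qts_scenario"
  )
}

#' @export
print.qts_scenario <- function(x, ...) {
  cat(sprintf(
    "<qts_scenario> n = %d, h2 = %.2f, %d markers, %d reps, seed = %d\n",
    x$n, x$h2, nrow(x$map), x$reps, x$seed
  ))
  invisible(x)
}

#' Simulate one replicate of a scenario
#'
#' Generates one dataset under a [qts_scenario()]: RIL genotypes, the
#' residual variance solved for the scenario's target heritability on the
#' realized genotypes, and phenotypes. The power driver calls this once
#' per replicate with seed `base_seed + replicate`.
#'
#' @param scenario A [qts_scenario()].
#' @param rep_seed Integer seed for this replicate.
#' @return List with elements `G` (genotypes), `truth` (the effect set
#'   with `sigma2` resolved) and `pheno` (phenotype tibble).
#' @export
sim_scenario_replicate <- function(scenario, rep_seed) {
  set.seed(rep_seed)
  G <- sim_ril_genotypes(scenario$map, scenario$n)
  truth <- scenario$truth
  truth$sigma2 <- scenario$sigma2 %||%
    resolve_residual_variance(truth, G, scenario$h2)
  pheno <- sim_phenotypes(G, truth)
  list(G = G, truth = truth, pheno = pheno)
}
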