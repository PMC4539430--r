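#' Haldane map function
#'
#' Converts a map distance in centiMorgans to a single-meiosis recombination
#' fraction assuming no crossover interference:
#' \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param d Numeric vector of non-negative map distances (cM).
#' @return Recombination fractions in `[0, 0.5)`.
#' @examples
#' recombination_fraction(c(0, 1, 50))
#' @export
recombination_fraction <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0)) {
    abort("`d` must be a non-negative numeric map distance in cM.")
  }
  (1 - exp(-2 * d / 100)) / 2
}

#' RIL recombination fraction at fixation
#'
#' Expected proportion of recombinant lines between two loci in a
#' recombinant inbred line population derived by repeated selfing to
#' fixation, given the single-meiosis recombination fraction `r`:
#' \eqn{R = 2r / (1 + 2r)}.
#'
#' @param r Numeric vector of single-meiosis recombination fractions in
#'   `[0, 0.5]`.
#' @return RIL-level recombination fractions in `[0, 0.5]`.
#' @examples
#' ril_recombination_fraction(recombination_fraction(1))
#' @export
ril_recombination_fraction <- function(r) {
  if (!is.numeric(r) || any(is.na(r)) || any(r < 0) || any(r > 0.5)) {
    abort("`r` must be a recombination fraction in [0, 0.5].")
  }
  2 * r / (1 + 2 * r)
}

#' Construct a genetic map
#'
#' A genetic map is a tibble with one row per marker and columns `marker`,
#' `chr`, `pos_cM`. Positions within a chromosome must be non-decreasing
#' and marker ids unique genome-wide. The default lays out evenly spaced
#' markers, the layout used throughout the simulation study (3 chromosomes
#' of 175 markers, 1 cM apart).
#'
#' @param n_chr Number of chromosomes.
#' @param markers_per_chr Markers per chromosome.
#' @param spacing_cM Inter-marker distance in cM.
#' @return A tibble with columns `marker`, `chr`, `pos_cM`.
#' @examples
#' genetic_map(2, 5, 10)
#' @export
genetic_map <- function(n_chr = 3, markers_per_chr = 175, spacing_cM = 1) {
  stopifnot(n_chr >= 1, markers_per_chr >= 1, spacing_cM >= 0)
  tibble::tibble(
    chr = rep(seq_len(n_chr), each = markers_per_chr),
    idx = rep(seq_len(markers_per_chr), times = n_chr)
  ) |>
    dplyr::mutate(
      marker = sprintf("S%d_%d", .data$chr, .data$idx),
      pos_cM = (.data$idx - 1) * spacing_cM
    ) |>
    dplyr::select("marker", "chr", "pos_cM")
}

validate_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("marker", "chr", "pos_cM") %in% names(map)))
  if (anyDuplicated(map$marker)) abort("marker ids must be unique genome-wide.")
  if (any(map$pos_cM < 0)) abort("map positions must be non-negative.")
  ok <- map |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(sorted = !is.unsorted(.data$pos_cM)) |>
    dplyr::pull(.data$sorted)
  if (!all(ok)) abort("positions within a chromosome must be non-decreasing.")
  invisible(map)
}

#' Build a genotype matrix object
#'
#' Thin container for coded RIL genotypes: an integer matrix of
#' `lines x markers` with values +1 (homozygote of the high-frequency
#' allele), -1 (homozygote of the low-frequency allele), 0 (heterozygote)
#' or `NA` (missing), plus a marker metadata tibble.
#'
#' @param codes Integer matrix, lines in rows, markers in columns.
#' @param markers Tibble with columns `marker`, `chr`, `pos_cM`,
#'   `allele_high`, `allele_low` (one row per column of `codes`).
#' @param max_het Maximum tolerated fraction of heterozygote codes per
#'   marker (RILs are fully inbred, so the default is 0).
#' @param max_missing Maximum tolerated fraction of missing codes per marker.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, markers, max_het = 0, max_missing = 0.2) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  stopifnot(is.data.frame(markers), nrow(markers) == ncol(codes))
  if (!all(c("marker", "chr", "pos_cM") %in% names(markers))) {
    abort("`markers` needs columns marker, chr, pos_cM.")
  }
  if (!"allele_high" %in% names(markers)) markers$allele_high <- "A"
  if (!"allele_low" %in% names(markers)) markers$allele_low <- "B"
  bad <- codes[!is.na(codes)]
  if (length(bad) && !all(bad %in% c(-1L, 0L, 1L))) {
    abort("coded genotypes must be in {-1, 0, +1, NA}.")
  }
  het <- colMeans(codes == 0L, na.rm = TRUE)
  het[is.nan(het)] <- 0
  if (any(het > max_het + 1e-12)) {
    abort(sprintf(
      "marker %s exceeds the heterozygosity ceiling (%.3f > %.3f).",
      markers$marker[which.max(het)], max(het), max_het
    ))
  }
  miss <- colMeans(is.na(codes))
  if (any(miss > max_missing + 1e-12)) {
    abort(sprintf(
      "marker %s exceeds the missingness ceiling (%.3f > %.3f).",
      markers$marker[which.max(miss)], max(miss), max_missing
    ))
  }
  colnames(codes) <- markers$marker
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("L%03d", seq_len(nrow(codes)))
  }
  structure(
    codes,
    markers = tibble::as_tibble(markers),
    class = c("genotype_matrix", "matrix", "array")
  )
}

#' Marker metadata of a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Tibble of marker metadata.
#' @export
marker_info <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  attr(G, "markers")
}

#' Line ids of a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Character vector of line identifiers.
#' @export
line_ids <- function(G) rownames(G)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d lines x %d markers (%d chromosomes)\n",
    nrow(x), ncol(x), dplyr::n_distinct(marker_info(x)$chr)
  ))
  invisible(x)
}

#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "line")
}

# Markers with unknown chromosome/position are treated as unlinked: each
# gets its own pseudo-chromosome at position 0, so distance-based windows
# (clumping, cofactor exclusion) never merge or exclude them.
fill_marker_positions <- function(mk) {
  miss <- is.na(mk$chr) | is.na(mk$pos_cM)
  if (any(miss)) {
    mk$chr <- as.character(mk$chr)
    mk$chr[miss] <- paste0("u", seq_len(sum(miss)))
    mk$pos_cM[miss] <- 0
  }
  mk
}

parse_call <- function(call) {
  # "GG", "G/A", "G|A" -> two allele characters
  s <- gsub("[/|]", "", call)
  ifelse(nchar(s) == 2, s, NA_character_)
}

#' Code biallelic calls as +1 / -1 / 0
#'
#' Converts raw biallelic genotype calls for inbred lines into the coded
#' form used by the mapping model: the homozygote of the higher-frequency
#' allele is coded +1, the homozygote of the lower-frequency allele -1,
#' heterozygotes 0, missing stays missing. Allele-frequency ties are broken
#' lexicographically (the alphabetically first allele is treated as the
#' high-frequency allele), so coding is deterministic. Markers with more
#' than two alleles raise an error naming the marker; monomorphic markers
#' are dropped with a warning.
#'
#' @param calls Character matrix (lines x markers) of calls such as `"GG"`,
#'   `"G/A"`, `NA`.
#' @param map Optional genetic map tibble (`marker`, `chr`, `pos_cM`)
#'   supplying marker metadata; matched by column name.
#' @param max_het,max_missing Passed to [genotype_matrix()].
#' @return A [genotype_matrix()].
#' @examples
#' calls <- rbind(L1 = c(m1 = "GG"), L2 = "GG", L3 = "GG", L4 = "AA")
#' code_genotypes(calls)
#' @export
code_genotypes <- function(calls, map = NULL, max_het = 1, max_missing = 1) {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("M%d", seq_len(ncol(calls)))
  }
  p <- ncol(calls)
  codes <- matrix(NA_integer_, nrow(calls), p, dimnames = dimnames(calls))
  high <- low <- character(p)
  keep <- rep(TRUE, p)
  for (j in seq_len(p)) {
    cl <- parse_call(calls[, j])
    a1 <- substr(cl, 1, 1)
    a2 <- substr(cl, 2, 2)
    alle <- c(a1, a2)
    alle <- alle[!is.na(alle)]
    tab <- sort(table(alle), decreasing = TRUE)
    if (length(tab) > 2) {
      abort(sprintf(
        "marker %s has %d alleles (%s); only biallelic markers are supported.",
        colnames(calls)[j], length(tab), paste(names(tab), collapse = ",")
      ))
    }
    if (length(tab) < 2) {
      warn(sprintf("marker %s is monomorphic; excluded.", colnames(calls)[j]))
      keep[j] <- FALSE
      next
    }
    als <- names(tab)
    if (tab[1] == tab[2]) als <- sort(als) # tie: lexicographic order
    high[j] <- als[1]
    low[j] <- als[2]
    codes[, j] <- dplyr::case_when(
      is.na(cl) ~ NA_integer_,
      a1 == high[j] & a2 == high[j] ~ 1L,
      a1 == low[j] & a2 == low[j] ~ -1L,
      TRUE ~ 0L
    )
  }
  codes <- codes[, keep, drop = FALSE]
  mk <- tibble::tibble(
    marker = colnames(codes),
    allele_high = high[keep], allele_low = low[keep]
  )
  if (!is.null(map)) {
    mk <- dplyr::left_join(mk, map, by = "marker")
  } else {
    mk$chr <- NA_integer_
    mk$pos_cM <- NA_real_
  }
  genotype_matrix(codes, mk[, c("marker", "chr", "pos_cM", "allele_high", "allele_low")],
    max_het = max_het, max_missing = max_missing
  )
}

#' Decode a genotype matrix back to allele calls
#'
#' Inverse of [code_genotypes()] for homozygous calls: +1 becomes the
#' high-frequency allele homozygote, -1 the low-frequency one, 0 the
#' heterozygote written high-then-low.
#'
#' @param G A `genotype_matrix`.
#' @return Character matrix of calls.
#' @export
decode_genotypes <- function(G) {
  mk <- marker_info(G)
  out <- matrix(NA_character_, nrow(G), ncol(G), dimnames = dimnames(G))
  for (j in seq_len(ncol(G))) {
    hi <- mk$allele_high[j]
    lo <- mk$allele_low[j]
    out[, j] <- dplyr::case_when(
      is.na(G[, j]) ~ NA_character_,
      G[, j] == 1L ~ paste0(hi, hi),
      G[, j] == -1L ~ paste0(lo, lo),
      TRUE ~ paste0(hi, lo)
    )
  }
  out
}

normalise_interaction <- function(x, n_env, what) {
  # accept list-column of length-H vectors or wide columns <what>1..<what>H
  if (is.list(x)) {
    if (!all(lengths(x) == n_env)) {
      abort(sprintf("each `%s` vector must have length n_env = %d.", what, n_env))
    }
    return(x)
  }
  abort(sprintf("`%s` must be a list-column of length-%d numeric vectors.", what, n_env))
}

#' Quantitative-trait-SNP effect set
#'
#' Container for the full parameter set of the multi-environment QTS model
#' \deqn{y_{hk} = \mu + \sum_i x_{ik} a_i + \sum_{i<j} x_{ik}x_{jk} aa_{ij}
#'   + e_h + \sum_i x_{ik} ae_{hi} + \sum_{i<j} x_{ik}x_{jk} aae_{hij}
#'   + \epsilon_{hk},}
#' used both as simulation truth and as an estimate container. Environment
#' interaction vectors follow a sum-to-zero convention by default
#' (\eqn{\sum_h ae_{hi} = 0}).
#'
#' @param mu Population mean (trait units).
#' @param env Numeric vector of environment main effects `e_h`; its length
#'   sets the number of environments.
#' @param additive Tibble with columns `marker`, `a` and a list-column `ae`
#'   of length-H numeric vectors (may be empty/NULL).
#' @param epistatic Tibble with columns `marker1`, `marker2`, `aa` and a
#'   list-column `aae` (may be empty/NULL).
#' @param sigma2 Residual variance \eqn{\sigma^2_\epsilon} (trait units
#'   squared); `NA` when not yet resolved.
#' @param sum_to_zero Enforce \eqn{\sum_h ae_{hi} = 0} and
#'   \eqn{\sum_h aae_{hij} = 0} (error if violated). Set `FALSE` to disable.
#' @return Object of class `qts_effects`.
#' @examples
#' qts_effects(
#'   mu = 10, env = c(1, -1),
#'   additive = tibble::tibble(marker = "S1_28", a = -3.24, ae = list(c(2.65, -2.65)))
#' )
#' @export
qts_effects <- function(mu = 0, env = c(1, -1), additive = NULL, epistatic = NULL,
                        sigma2 = NA_real_, sum_to_zero = TRUE) {
  n_env <- length(env)
  if (n_env < 1) abort("at least one environment is required.")
  if (is.null(additive)) {
    additive <- tibble::tibble(
      marker = character(), a = numeric(), ae = list()
    )
  }
  additive <- tibble::as_tibble(additive)
  if (nrow(additive)) {
    additive$ae <- normalise_interaction(additive$ae, n_env, "ae")
  }
  if (is.null(epistatic)) {
    epistatic <- tibble::tibble(
      marker1 = character(), marker2 = character(), aa = numeric(), aae = list()
    )
  }
  epistatic <- tibble::as_tibble(epistatic)
  if (nrow(epistatic)) {
    epistatic$aae <- normalise_interaction(epistatic$aae, n_env, "aae")
    swap <- epistatic$marker1 > epistatic$marker2
    if (any(swap)) { # canonical order i < j
      tmp <- epistatic$marker1[swap]
      epistatic$marker1[swap] <- epistatic$marker2[swap]
      epistatic$marker2[swap] <- tmp
    }
  }
  if (sum_to_zero) {
    sums <- c(
      vapply(additive$ae, sum, 0),
      vapply(epistatic$aae, sum, 0)
    )
    if (length(sums) && any(abs(sums) > 1e-8)) {
      abort("environment-interaction effects must sum to zero across environments (or set sum_to_zero = FALSE).")
    }
  }
  structure(
    list(
      mu = mu, env = env, additive = additive, epistatic = epistatic,
      sigma2 = sigma2, n_env = n_env, sum_to_zero = sum_to_zero
    ),
    class = "qts_effects"
  )
}

#' @export
print.qts_effects <- function(x, ...) {
  cat(sprintf(
    "<qts_effects> mu = %.3g, %d environments, %d additive, %d epistatic, sigma2 = %s\n",
    x$mu, x$n_env, nrow(x$additive), nrow(x$epistatic),
    ifelse(is.na(x$sigma2), "unresolved", format(x$sigma2, digits = 4))
  ))
  invisible(x)
}

# One column per model effect, evaluated over the realized (line x env)
# design. Rows are ordered env-major (all lines of env 1, then env 2, ...),
# the ordering used by all long-format phenotype tables in the package.
effect_contributions <- function(effects, G) {
  stopifnot(inherits(effects, "qts_effects"), inherits(G, "genotype_matrix"))
  n <- nrow(G)
  H <- effects$n_env
  need <- c(
    effects$additive$marker,
    effects$epistatic$marker1, effects$epistatic$marker2
  )
  missing <- setdiff(need, colnames(G))
  if (length(missing)) {
    abort(paste0("markers not in genotype matrix: ", paste(missing, collapse = ", ")))
  }
  cols <- list()
  meta <- list()
  envrow <- rep(seq_len(H), each = n)
  for (i in seq_len(nrow(effects$additive))) {
    m <- effects$additive$marker[i]
    x <- rep(as.numeric(G[, m]), times = H)
    cols[[length(cols) + 1]] <- effects$additive$a[i] * x
    meta[[length(meta) + 1]] <- tibble::tibble(term = m, effect = "a")
    ae <- effects$additive$ae[[i]]
    for (h in seq_len(H)) {
      cols[[length(cols) + 1]] <- ifelse(envrow == h, ae[h] * x, 0)
      meta[[length(meta) + 1]] <- tibble::tibble(term = m, effect = paste0("ae", h))
    }
  }
  for (i in seq_len(nrow(effects$epistatic))) {
    m1 <- effects$epistatic$marker1[i]
    m2 <- effects$epistatic$marker2[i]
    xx <- rep(as.numeric(G[, m1]) * as.numeric(G[, m2]), times = H)
    pair <- paste(m1, m2, sep = " x ")
    cols[[length(cols) + 1]] <- effects$epistatic$aa[i] * xx
    meta[[length(meta) + 1]] <- tibble::tibble(term = pair, effect = "aa")
    aae <- effects$epistatic$aae[[i]]
    for (h in seq_len(H)) {
      cols[[length(cols) + 1]] <- ifelse(envrow == h, aae[h] * xx, 0)
      meta[[length(meta) + 1]] <- tibble::tibble(term = pair, effect = paste0("aae", h))
    }
  }
  list(
    contributions = if (length(cols)) do.call(cbind, cols) else matrix(0, n * H, 0),
    meta = if (length(meta)) dplyr::bind_rows(meta) else tibble::tibble(term = character(), effect = character())
  )
}

pop_var <- function(x) mean((x - mean(x))^2)

# Sum of per-term empirical variances over the realized design;
# the genetic variance used by the heritability accounting and by
# resolve_residual_variance. Environment main effects are excluded.
genetic_variance_components <- function(effects, G) {
  con <- effect_contributions(effects, G)
  v <- if (ncol(con$contributions)) apply(con$contributions, 2, pop_var) else numeric(0)
  dplyr::bind_cols(con$meta, tibble::tibble(variance = v))
}

#' Partition heritability over model effects
#'
#' Computes, for every effect in a [qts_effects()] set, the percentage of
#' modeled phenotypic variance it explains over the realized design:
#' each effect's empirical variance (its fitted contribution evaluated
#' across all lines and environments) divided by the total modeled variance
#' (sum of all genetic component variances plus the residual variance),
#' times 100. The environment main effect is excluded from both numerator
#' and total. The reported total heritability is by construction the sum of
#' the component values, so the accounting identity holds exactly.
#'
#' @param effects A [qts_effects()] with `sigma2` set (NA treated as 0).
#' @param G A [genotype_matrix()] containing every marker in `effects`.
#' @return Tibble with columns `term`, `effect`, `variance`, `h2` and
#'   attributes `total_h2` and `sigma2`; class `qts_h2`.
#' @export
partition_heritability <- function(effects, G) {
  comp <- genetic_variance_components(effects, G)
  sigma2 <- effects$sigma2
  if (is.na(sigma2)) sigma2 <- 0
  total_var <- sum(comp$variance) + sigma2
  if (total_var <= 0) abort("total modeled phenotypic variance is zero; cannot partition.")
  comp$h2 <- 100 * comp$variance / total_var
  structure(
    comp,
    total_h2 = sum(comp$h2),
    sigma2 = sigma2,
    class = c("qts_h2", class(comp))
  )
}

#' @export
print.qts_h2 <- function(x, ...) {
  NextMethod()
  cat(sprintf("total h2 = %.2f%% (sigma2 = %.4g)\n", attr(x, "total_h2"), attr(x, "sigma2")))
  invisible(x)
}
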