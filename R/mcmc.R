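# Effective sample size of a chain via Geyer's initial positive sequence:
# n / (1 + 2 * sum of autocorrelations), truncated where consecutive
# autocorrelation pairs turn negative.
ess <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(rho) - 1) {
    g <- rho[k] + rho[k + 1]
    if (g < 0) break
    s <- s + g
    k <- k + 2
  }
  max(1, min(n, n / (1 + 2 * s)))
}

clump_by_F <- function(tbl, exclusion_cM) {
  # greedy suppression of lower-F terms whose markers fall within the
  # window of an already accepted term (per marker for pairs)
  tbl <- tbl[order(-tbl$F), , drop = FALSE]
  acc <- list()
  keep <- logical(nrow(tbl))
  near_any <- function(chr, pos) {
    for (a in acc) {
      if (any(a$chr == chr & abs(a$pos - pos) <= exclusion_cM)) return(TRUE)
    }
    FALSE
  }
  for (r in seq_len(nrow(tbl))) {
    chrs <- c(tbl$chr1[r], tbl$chr2[r])
    poss <- c(tbl$pos1[r], tbl$pos2[r])
    ok <- !is.na(chrs)
    if (any(vapply(which(ok), function(i) near_any(chrs[i], poss[i]), TRUE))) next
    keep[r] <- TRUE
    acc[[length(acc) + 1]] <- list(chr = chrs[ok], pos = poss[ok])
  }
  tbl[keep, , drop = FALSE]
}

#' Assemble the full model from scan results
#'
#' Collects every significant 1D marker as an additive term and every
#' significant 2D pair as an epistatic term; markers appearing only inside
#' a significant pair also receive additive terms (the model is
#' hierarchical: `a` and `aa` are both present). Because screen candidates
#' arrive in tight linkage clusters, significant terms are first clumped:
#' within `exclusion_cM`, only the highest-F representative of a cluster
#' enters the model. Each genetic term is paired with its environment
#' interaction effects when fitted.
#'
#' @param scan A `qts_scan` result.
#' @param exclusion_cM Clump window (cM), defaulting to the scan's own.
#' @return Object of class `qts_model`: list with `additive` (tibble
#'   `marker`, `chr`, `pos_cM`) and `epistatic` (tibble `marker1`,
#'   `marker2`).
#' @export
build_full_model <- function(scan, exclusion_cM = NULL) {
  stopifnot(inherits(scan, "qts_scan"))
  exclusion_cM <- exclusion_cM %||% attr(scan, "exclusion_cM") %||% 10
  sig <- dplyr::filter(tibble::as_tibble(scan), .data$significant)
  if (!nrow(sig)) {
    inform("no significant terms; returning an intercept + environment model.")
  }
  add <- clump_by_F(dplyr::filter(sig, .data$family == "1d"), exclusion_cM)
  pairs <- clump_by_F(dplyr::filter(sig, .data$family == "2d"), exclusion_cM)
  additive <- tibble::tibble(
    marker = add$marker1, chr = add$chr1, pos_cM = add$pos1
  )
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      for (side in 1:2) {
        mk <- pairs[[paste0("marker", side)]][r]
        chr <- pairs[[paste0("chr", side)]][r]
        pos <- pairs[[paste0("pos", side)]][r]
        covered <- any(additive$chr == chr & abs(additive$pos_cM - pos) <= exclusion_cM)
        if (!covered) {
          additive <- dplyr::bind_rows(
            additive,
            tibble::tibble(marker = mk, chr = chr, pos_cM = pos)
          )
        }
      }
    }
  }
  epi <- tibble::tibble(marker1 = pairs$marker1, marker2 = pairs$marker2)
  swap <- epi$marker1 > epi$marker2 # canonical order, as in qts_effects()
  if (any(swap)) {
    tmp <- epi$marker1[swap]
    epi$marker1[swap] <- epi$marker2[swap]
    epi$marker2[swap] <- tmp
  }
  structure(
    list(additive = additive, epistatic = epi),
    class = "qts_model"
  )
}

#' @export
print.qts_model <- function(x, ...) {
  cat(sprintf(
    "<qts_model> %d additive terms, %d epistatic pairs\n",
    nrow(x$additive), nrow(x$epistatic)
  ))
  invisible(x)
}

#' Posterior estimation of all QTS effects by MCMC
#'
#' Stage 2b: fits the full hierarchical model containing every term of a
#' [build_full_model()] specification by Gibbs sampling. The population
#' mean and the additive/epistatic main effects are fixed effects with
#' vague normal priors; environment main effects, additive-by-environment
#' and epistasis-by-environment effects are random, with one
#' inverse-gamma-distributed variance component per family, as is the
#' residual. Each effect is estimated by its posterior mean, tested by
#' `t = mean / SD` with degrees of freedom `effective sample size - 1`,
#' and reported with `-log10(P)` and its heritability (via
#' [partition_heritability()] applied to the posterior-mean effect set).
#'
#' @param G A [genotype_matrix()].
#' @param pheno Phenotype tibble.
#' @param model A `qts_model` (or a `qts_scan`, converted automatically).
#' @param iterations Total Gibbs iterations.
#' @param burnin Burn-in iterations discarded.
#' @param thin Thinning interval.
#' @param seed Seed (chains are reproducible given the seed).
#' @param tau2_fixed Prior variance of fixed effects, on the scale of the
#'   phenotype variance (default `1e6 * var(y)`).
#' @param a0,b0 Inverse-gamma hyperparameters for all variance components.
#' @param min_ess Effective-sample-size threshold below which the summary
#'   is flagged as unconverged.
#' @return Object of class `qts_mcmc`: tibble of per-effect posterior
#'   summaries (`term`, `effect`, `estimate`, `sd`, `t`, `df`,
#'   `neg_log10_p`, `h2`, `ess`) with attributes `total_h2`, `sigma2`,
#'   `converged`, `effects` (the posterior-mean [qts_effects()]).
#' @export
fit_qts_mcmc <- function(G, pheno, model, iterations = 12000, burnin = 2000,
                         thin = 2, seed = 1L, tau2_fixed = NULL,
                         a0 = 0.01, b0 = 0.01, min_ess = 100) {
  if (inherits(model, "qts_scan")) model <- build_full_model(model)
  stopifnot(inherits(model, "qts_model"))
  sd_ <- scan_data(G, pheno)
  n <- sd_$n
  H <- sd_$H
  y <- sd_$y
  tau2_fixed <- tau2_fixed %||% (1e6 * max(var(y), 1e-8))

  # Environment-interaction families are sampled on sum-to-zero contrasts
  # (gamma_h = effect in environment h, h < H; effect in environment H is
  # -sum(gamma)): the pooled main-effect column and its H per-environment
  # columns are exactly collinear, so sampling all of them mixes
  # arbitrarily badly, while the contrast basis is full rank and the
  # derived effects satisfy the sum-to-zero convention of the effect set.
  contrast_cols <- function(x) {
    vapply(seq_len(H - 1), function(h) x * (sd_$E[, h] - sd_$E[, H]), numeric(n * H))
  }
  cols <- list(rep(1, n * H))
  group <- 0L
  labels <- tibble::tibble(term = "(intercept)", effect = "mu")
  # transformation rows: derived effect = draws %*% t(Tmat)
  tm <- list(mu = NULL) # filled below once P known
  push <- function(xcols, grp, term, effs) {
    for (j in seq_len(ncol(xcols))) {
      cols[[length(cols) + 1]] <<- xcols[, j]
      group <<- c(group, grp)
    }
    labels <<- dplyr::bind_rows(labels, tibble::tibble(term = term, effect = effs))
  }
  if (H > 1) {
    push(contrast_cols(rep(1, n * H)), 1L, "(env)", paste0("ec", seq_len(H - 1)))
  }
  add_x <- function(mk) rep(as.numeric(G[sd_$lines, mk]), times = H)
  for (mk in model$additive$marker) {
    x <- add_x(mk)
    push(matrix(x, ncol = 1), 0L, mk, "a")
    if (H > 1) push(contrast_cols(x), 2L, mk, paste0("aec", seq_len(H - 1)))
  }
  if (nrow(model$epistatic)) {
    for (r in seq_len(nrow(model$epistatic))) {
      m1 <- model$epistatic$marker1[r]
      m2 <- model$epistatic$marker2[r]
      xx <- add_x(m1) * add_x(m2)
      pair <- paste(m1, m2, sep = " x ")
      push(matrix(xx, ncol = 1), 0L, pair, "aa")
      if (H > 1) push(contrast_cols(xx), 3L, pair, paste0("aaec", seq_len(H - 1)))
    }
  }
  X <- do.call(cbind, cols)
  set.seed(seed)
  fit <- .gibbs_qts(X, y, group, tau2_fixed, a0, b0,
    as.integer(iterations), as.integer(burnin), as.integer(thin)
  )
  raw_draws <- fit$beta
  sigma2_draws <- fit$variances[, ncol(fit$variances)]

  # expand contrast coefficients into per-environment effects, draw-wise
  expand_one <- function(prefix, out_prefix, term_rows) {
    idx <- which(labels$term == term_rows & startsWith(labels$effect, prefix))
    g <- raw_draws[, idx, drop = FALSE]
    d <- cbind(g, -rowSums(g))
    colnames(d) <- paste0(out_prefix, seq_len(H))
    d
  }
  draw_list <- list()
  lab_list <- list()
  for (r in seq_len(nrow(labels))) {
    eff <- labels$effect[r]
    if (eff %in% c("mu", "a", "aa")) {
      draw_list[[length(draw_list) + 1]] <- raw_draws[, r, drop = FALSE]
      lab_list[[length(lab_list) + 1]] <- labels[r, ]
    } else if (grepl("^(ec|aec|aaec)1$", eff)) {
      prefix <- sub("1$", "", eff)
      out_prefix <- c(ec = "e", aec = "ae", aaec = "aae")[[prefix]]
      d <- expand_one(prefix, out_prefix, labels$term[r])
      draw_list[[length(draw_list) + 1]] <- d
      lab_list[[length(lab_list) + 1]] <- tibble::tibble(
        term = labels$term[r], effect = colnames(d)
      )
    } # higher contrast indices are folded into the expansion above
  }
  draws <- do.call(cbind, draw_list)
  labels <- dplyr::bind_rows(lab_list)

  est <- colMeans(draws)
  psd <- apply(draws, 2, sd)
  ess_v <- apply(draws, 2, ess)
  tval <- ifelse(psd > 0, est / psd, NA_real_)
  dfree <- pmax(1, ess_v - 1)
  pval <- 2 * pt(-abs(tval), df = dfree)

  out <- labels
  out$estimate <- est
  out$sd <- psd
  out$t <- tval
  out$df <- dfree
  out$neg_log10_p <- -log10(pmax(pval, 1e-300))
  out$ess <- ess_v

  # posterior-mean effect set for the heritability partition
  geno_terms <- out$effect %in% c("a", "aa") |
    grepl("^ae[0-9]+$", out$effect) | grepl("^aae[0-9]+$", out$effect)
  mkinfo <- marker_info(G)
  additive <- NULL
  if (nrow(model$additive)) {
    additive <- purrr::map_dfr(model$additive$marker, function(mk) {
      rows <- out[out$term == mk, ]
      tibble::tibble(
        marker = mk,
        a = rows$estimate[rows$effect == "a"],
        ae = list(rows$estimate[grepl("^ae", rows$effect)])
      )
    })
  }
  epistatic <- NULL
  if (nrow(model$epistatic)) {
    epistatic <- purrr::map_dfr(seq_len(nrow(model$epistatic)), function(r) {
      pair <- paste(model$epistatic$marker1[r], model$epistatic$marker2[r], sep = " x ")
      rows <- out[out$term == pair, ]
      tibble::tibble(
        marker1 = model$epistatic$marker1[r],
        marker2 = model$epistatic$marker2[r],
        aa = rows$estimate[rows$effect == "aa"],
        aae = list(rows$estimate[grepl("^aae", rows$effect)])
      )
    })
  }
  env_est <- out$estimate[grepl("^e[0-9]+$", out$effect)]
  if (!length(env_est)) env_est <- rep(0, H)
  eff <- qts_effects(
    mu = out$estimate[out$effect == "mu"],
    env = env_est,
    additive = additive, epistatic = epistatic,
    sigma2 = mean(sigma2_draws), sum_to_zero = FALSE
  )
  h2 <- if (nrow(eff$additive) || nrow(eff$epistatic)) {
    partition_heritability(eff, G)
  } else {
    NULL
  }
  out$h2 <- NA_real_
  if (!is.null(h2)) {
    key_out <- paste(out$term, out$effect)
    key_h2 <- paste(h2$term, h2$effect)
    hit <- match(key_h2, key_out)
    out$h2[hit[!is.na(hit)]] <- h2$h2[!is.na(hit)]
  }
  converged <- all(ess_v[geno_terms] >= min_ess)
  if (!converged) {
    warn(sprintf(
      "minimum effective sample size %.0f below %d; treat posterior summaries with caution.",
      min(ess_v[geno_terms]), min_ess
    ))
  }
  structure(
    out,
    total_h2 = if (is.null(h2)) 0 else attr(h2, "total_h2"),
    sigma2 = mean(sigma2_draws),
    variance_draws = fit$variances,
    effects = eff,
    converged = converged,
    chain = list(iterations = iterations, burnin = burnin, thin = thin, seed = seed),
    class = c("qts_mcmc", class(out))
  )
}

#' @export
print.qts_mcmc <- function(x, ...) {
  cat(sprintf(
    "<qts_mcmc> %d effects, total h2 = %.2f%%, sigma2 = %.4g%s\n",
    nrow(x), attr(x, "total_h2"), attr(x, "sigma2"),
    if (attr(x, "converged")) "" else "  [NOT CONVERGED]"
  ))
  NextMethod()
  invisible(x)
}

#' @export
tidy.qts_mcmc <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.qts_mcmc <- function(x, ...) {
  tibble::tibble(
    n_effects = nrow(x),
    total_h2 = attr(x, "total_h2"),
    sigma2 = attr(x, "sigma2"),
    min_ess = min(x$ess),
    converged = attr(x, "converged")
  )
}

#' Genetic-architecture report
#'
#' Formats a fitted [fit_qts_mcmc()] summary as a per-effect architecture
#' table: one row per genetic effect with allele labels, the effect
#' estimate, `-log10(P)` and per-effect heritability, followed by the
#' model's total heritability, ordered by trait, marker and effect kind.
#'
#' @param fit A `qts_mcmc` object.
#' @param G The [genotype_matrix()] used in the fit (for allele labels).
#' @param trait Trait label for the report.
#' @return Tibble with columns `trait`, `qts`, `chr`, `allele`, `effect`,
#'   `estimate`, `neg_log10_p`, `h2`, `total_h2`.
#' @export
summarize_architecture <- function(fit, G, trait = "trait") {
  stopifnot(inherits(fit, "qts_mcmc"))
  mkinfo <- marker_info(G)
  rows <- tibble::as_tibble(fit) |>
    dplyr::filter(.data$effect %in% c("a", "aa") |
      grepl("^aae", .data$effect) | grepl("^ae", .data$effect))
  if (!nrow(rows)) {
    return(tibble::tibble(
      trait = trait, qts = character(0), chr = integer(0), allele = character(0),
      effect = character(0), estimate = numeric(0), neg_log10_p = numeric(0),
      h2 = numeric(0), total_h2 = numeric(0)
    ))
  }
  first_marker <- vapply(strsplit(rows$term, " x "), `[`, "", 1)
  i <- match(first_marker, mkinfo$marker)
  rows |>
    dplyr::transmute(
      trait = trait,
      qts = .data$term,
      chr = mkinfo$chr[i],
      allele = paste0(mkinfo$allele_high[i], "/", mkinfo$allele_low[i]),
      effect = .data$effect,
      estimate = .data$estimate,
      neg_log10_p = .data$neg_log10_p,
      h2 = .data$h2,
      total_h2 = attr(fit, "total_h2")
    ) |>
    dplyr::arrange(.data$qts, .data$effect)
}
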