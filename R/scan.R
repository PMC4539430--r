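# Long-format response and design pieces shared by the scan functions.
# Rows are env-major (all lines of env 1, then env 2, ...). Lines with any
# missing phenotype are dropped so that permutations of whole line
# profiles stay balanced.
scan_data <- function(G, pheno) {
  validate_phenotypes(pheno, G)
  envs <- sort(unique(pheno$env))
  wide <- pheno |>
    tidyr::pivot_wider(names_from = "env", values_from = "value") |>
    dplyr::filter(!dplyr::if_any(dplyr::everything(), is.na))
  lines <- intersect(line_ids(G), wide$line)
  if (length(lines) < length(unique(pheno$line))) {
    inform(sprintf(
      "%d line(s) with missing phenotypes excluded from the scan.",
      length(unique(pheno$line)) - length(lines)
    ))
  }
  wide <- wide[match(lines, wide$line), ]
  H <- length(envs)
  y <- unlist(wide[, as.character(envs)], use.names = FALSE)
  n <- length(lines)
  E <- matrix(0, n * H, H)
  for (h in seq_len(H)) E[(h - 1) * n + seq_len(n), h] <- 1
  list(y = y, E = E, lines = lines, envs = envs, n = n, H = H)
}

rss_from_Q <- function(Q, y) sum(y^2) - colSums(crossprod(Q, y)^2)

term_F <- function(Qf, rank_f, Qr, rank_r, Y, N) {
  df1 <- rank_f - rank_r
  if (df1 <= 0) {
    return(list(F = rep(NA_real_, ncol(Y)), df1 = NA_integer_, df2 = NA_integer_))
  }
  df2 <- N - rank_f
  ssy <- colSums(Y^2)
  rss_f <- ssy - colSums(crossprod(Qf, Y)^2)
  rss_r <- ssy - colSums(crossprod(Qr, Y)^2)
  Fv <- pmax(0, (rss_r - rss_f) / df1) / (rss_f / df2)
  list(F = Fv, df1 = df1, df2 = df2)
}

thin_Q <- function(X) {
  d <- qr(X)
  list(Q = qr.Q(d)[, seq_len(d$rank), drop = FALSE], rank = d$rank)
}

#' Fit and test a single QTS term
#'
#' Tests one marker (or one marker pair) for association across
#' environments, with a set of additive cofactor markers controlling
#' background genetic effects. The model has per-environment intercepts
#' (absorbing the population mean and environment main effects), one
#' pooled additive column per cofactor, and environment-specific slope
#' columns for the tested term, so that the F statistic jointly tests the
#' term's main effect together with its environment interactions
#' (`a` and all `ae_h`; for a pair, `aa` and all `aae_h` with the two
#' markers' own per-environment additive slopes retained in both models).
#' With one environment this reduces exactly to the classical partial F of
#' adding the marker to the cofactor regression.
#'
#' @param G A [genotype_matrix()].
#' @param pheno Phenotype tibble.
#' @param term Character vector: one marker id, or two for an epistatic pair.
#' @param cofactors Character vector of additive cofactor marker ids
#'   (automatically purged of the term's own markers).
#' @return Object of class `qts_fit`: list with `F`, `df1`, `df2`, `p`,
#'   `term`, `cofactors`, `rss_full`, `rss_reduced`.
#' @export
fit_qts_term <- function(G, pheno, term, cofactors = character(0)) {
  stopifnot(length(term) %in% 1:2, all(term %in% colnames(G)))
  cofactors <- setdiff(cofactors, term)
  sd_ <- scan_data(G, pheno)
  Xc <- if (length(cofactors)) {
    apply(G[sd_$lines, cofactors, drop = FALSE], 2, rep, times = sd_$H)
  } else {
    NULL
  }
  base <- cbind(sd_$E, Xc)
  per_env <- function(x) sd_$E * rep(x, times = sd_$H)
  if (length(term) == 1) {
    x <- as.numeric(G[sd_$lines, term])
    Xr <- base
    Xf <- cbind(base, per_env(x))
  } else {
    x1 <- as.numeric(G[sd_$lines, term[1]])
    x2 <- as.numeric(G[sd_$lines, term[2]])
    add <- cbind(per_env(x1), per_env(x2))
    Xr <- cbind(base, add)
    Xf <- cbind(Xr, per_env(x1 * x2))
  }
  qf <- thin_Q(Xf)
  qr_ <- thin_Q(Xr)
  Y <- matrix(sd_$y, ncol = 1)
  res <- term_F(qf$Q, qf$rank, qr_$Q, qr_$rank, Y, length(sd_$y))
  if (is.na(res$df1)) {
    warn(sprintf("term %s is collinear with the reduced model; skipped.", paste(term, collapse = " x ")))
  }
  structure(
    list(
      F = res$F[1], df1 = res$df1, df2 = res$df2,
      p = if (!is.na(res$df1)) pf(res$F[1], res$df1, res$df2, lower.tail = FALSE) else NA_real_,
      term = term, cofactors = cofactors,
      rss_full = rss_from_Q(qf$Q, sd_$y),
      rss_reduced = rss_from_Q(qr_$Q, sd_$y)
    ),
    class = "qts_fit"
  )
}

#' @export
print.qts_fit <- function(x, ...) {
  cat(sprintf(
    "<qts_fit> %s: F(%s, %s) = %.4g, p = %.3g (%d cofactors)\n",
    paste(x$term, collapse = " x "), x$df1, x$df2, x$F, x$p, length(x$cofactors)
  ))
  invisible(x)
}

#' @export
tidy.qts_fit <- function(x, ...) {
  tibble::tibble(
    term = paste(x$term, collapse = " x "),
    statistic = x$F, df1 = x$df1, df2 = x$df2, p.value = x$p
  )
}

# Normalize the candidate input into (marker, chr, pos_cM, cluster).
# A bare character vector makes every marker its own cluster.
normalise_candidates <- function(candidates, mkinfo) {
  if (inherits(candidates, "qts_candidates")) {
    cand <- candidates$candidates
    if (is.null(cand$cluster)) cand$cluster <- cand$marker
  } else {
    candidates <- unique(candidates)
    if (!all(candidates %in% mkinfo$marker)) abort("unknown candidate markers.")
    cand <- mkinfo[match(candidates, mkinfo$marker), c("marker", "chr", "pos_cM")]
    cand$cluster <- cand$marker
  }
  if (!nrow(cand)) abort("no candidate markers to scan.")
  cand
}

# Per-environment score residuals (lines x envs) from the long response.
env_scores <- function(y, n, H) {
  S <- matrix(y, n, H)
  sweep(S, 2, colMeans(S))
}

# Cheap interaction statistic over the member grid of two clusters:
# sum over environments of the squared score-weighted cross product of
# the coded genotypes. Used only to center the tested 2D term on the
# local epistatic peak; the F test itself is model-based.
refine_pair <- function(S, X1, X2) {
  stat <- 0
  for (h in seq_len(ncol(S))) {
    C <- crossprod(X1, X2 * S[, h])
    stat <- stat + C^2
  }
  which(stat == max(stat), arr.ind = TRUE)[1, ]
}

#' One- and two-dimensional QTS scan with permutation thresholds
#'
#' Stage 2a of the two-step strategy. Every candidate marker is tested in
#' a one-dimensional scan (see [fit_qts_term()] for the per-term model);
#' the additive cofactors are the representatives of the other candidate
#' clusters, excluding representatives within `exclusion_cM` of the tested
#' marker (a composite-interval-mapping-style window: tightly linked
#' markers are statistical proxies of the tested locus and must not be
#' conditioned on). Nominated epistatic pairs additionally serve as
#' interaction cofactors under the same windows. For every cluster pair
#' nominated by a retained multi-locus model (all cluster pairs, when
#' candidates are supplied as a bare marker vector) that sits on different
#' chromosomes or farther apart than `exclusion_cM`, a two-dimensional
#' term is tested after centering it on the local epistatic peak: the
#' marker pair maximizing a score-weighted cross-product statistic over
#' the `refine_cM` grid around the nominating anchors. The same
#' refinement is repeated inside every permutation so the 2D threshold
#' accounts for the local selection.
#'
#' Experiment-wise thresholds are computed separately for the 1D and 2D
#' families by permuting whole line phenotype profiles (a line's values
#' travel together across environments), recording the maximum F over
#' each family per permutation, and taking the
#' `ceiling((B+1)(1-alpha))`-th largest of the `B` maxima.
#'
#' @param G A [genotype_matrix()].
#' @param pheno Phenotype tibble.
#' @param candidates A `qts_candidates` object from [gmdr_screen()], or a
#'   character vector of marker ids (each then forms its own cluster).
#' @param B Number of permutations (>= 19); ignored when `thresholds` are
#'   supplied.
#' @param alpha Experiment-wise error rate.
#' @param seed Seed for the permutations.
#' @param exclusion_cM Cofactor exclusion window around the tested term
#'   (also the minimum separation for a tested pair).
#' @param refine_cM Half-width of the local grid on which a 2D term is
#'   centered (members within this distance of the cluster
#'   representative); small values keep the implicit 2D search, and hence
#'   the permutation threshold, comparable to a scan over the nominated
#'   pairs themselves.
#' @param thresholds Optional precomputed thresholds, a named list
#'   `list("1d" = ..., "2d" = ...)` (e.g. from a calibration dataset of
#'   the same scenario), skipping the permutations.
#' @param families Which scan families to run.
#' @return A tibble of class `qts_scan` with per-term `F`, `df1`, `df2`,
#'   `p`, `threshold`, `significant`, plus attributes `thresholds`,
#'   `alpha`, `B`.
#' @export
qts_scan <- function(G, pheno, candidates, B = 1000, alpha = 0.05, seed = 1L,
                     exclusion_cM = 30, refine_cM = 10, thresholds = NULL,
                     families = c("1d", "2d")) {
  mkinfo <- fill_marker_positions(marker_info(G))
  cand <- normalise_candidates(candidates, mkinfo)
  sd_ <- scan_data(G, pheno)
  N <- length(sd_$y)
  H <- sd_$H
  X <- apply(G[sd_$lines, cand$marker, drop = FALSE], 2, as.numeric)
  colnames(X) <- cand$marker
  per_env <- function(x) sd_$E * rep(x, times = H)
  # cofactors enter with environment-specific slopes so that background
  # additive-by-environment variance does not sit in the residual
  cof_cols <- function(cof) {
    if (!length(cof)) return(matrix(0, N, 0))
    do.call(cbind, lapply(cof, function(m) per_env(X[, m])))
  }

  # one representative row per cluster: the eponymous marker when present
  # (hand-built inputs may lack it; then the first member stands in)
  reps <- purrr::map_dfr(unique(cand$cluster), function(cl) {
    rows <- cand[cand$cluster == cl, ]
    rows[match(cl, rows$marker, nomatch = 1L), ]
  })

  run_1d <- "1d" %in% families
  run_2d <- "2d" %in% families && nrow(reps) >= 2

  # ---- nominated cluster pairs ----
  # When the screen supplies nominated pairs (cluster pairs spanned by a
  # retained multi-locus model), only those form 2D terms: the two-step
  # strategy exists to shrink the 2D search to what the screen supports,
  # and the permutation threshold is computed over the same family. With
  # hand-supplied candidates every cluster pair is tested.
  nominated <- if (inherits(candidates, "qts_candidates")) candidates$nominated else NULL
  pair_tbl <- NULL
  if (nrow(reps) >= 2) {
    if (!is.null(nominated)) {
      if (nrow(nominated)) {
        pos_of <- function(mk) mkinfo$pos_cM[match(mk, mkinfo$marker)]
        # remap each nominating marker to its cluster label as realized in
        # the candidate table (overlapping cluster expansions can swallow
        # a nominal cluster's own label)
        nominated$c1 <- cand$cluster[match(nominated$m1, cand$marker)]
        nominated$c2 <- cand$cluster[match(nominated$m2, cand$marker)]
        nominated <- nominated |>
          dplyr::filter(!is.na(.data$c1), !is.na(.data$c2), .data$c1 != .data$c2)
        sw <- nominated$c1 > nominated$c2
        if (any(sw)) {
          tmp <- nominated$c1[sw]
          nominated$c1[sw] <- nominated$c2[sw]
          nominated$c2[sw] <- tmp
          tmp <- nominated$m1[sw]
          nominated$m1[sw] <- nominated$m2[sw]
          nominated$m2[sw] <- tmp
        }
        if (nrow(nominated)) {
          pair_tbl <- nominated |>
            dplyr::group_by(.data$c1, .data$c2) |>
            dplyr::summarise(
              am1 = .data$m1[1], am2 = .data$m2[1],
              anchors1 = list(unique(pos_of(.data$m1))),
              anchors2 = list(unique(pos_of(.data$m2))),
              .groups = "drop"
            )
        }
      }
    } else {
      pr <- t(combn(nrow(reps), 2))
      if (nrow(pr)) {
        pair_tbl <- tibble::tibble(
          c1 = reps$cluster[pr[, 1]], c2 = reps$cluster[pr[, 2]],
          am1 = reps$marker[pr[, 1]], am2 = reps$marker[pr[, 2]],
          anchors1 = as.list(reps$pos_cM[pr[, 1]]),
          anchors2 = as.list(reps$pos_cM[pr[, 2]])
        )
      }
    }
    if (!is.null(pair_tbl) && nrow(pair_tbl)) {
      i1 <- match(pair_tbl$c1, reps$cluster)
      i2 <- match(pair_tbl$c2, reps$cluster)
      sep <- reps$chr[i1] != reps$chr[i2] |
        abs(reps$pos_cM[i1] - reps$pos_cM[i2]) > exclusion_cM
      sep[is.na(sep)] <- FALSE
      pair_tbl <- pair_tbl[sep, , drop = FALSE]
    }
    if (is.null(pair_tbl) || !nrow(pair_tbl)) pair_tbl <- NULL
  }

  # Nominated epistatic terms also serve as background cofactors (with
  # environment-specific slopes), anchored on the nominating markers, so
  # that background epistatic variance does not sit in the residual of
  # other tests. Only screen-nominated pairs are used this way.
  pc_cols <- list()
  pc_meta <- NULL
  if (!is.null(nominated) && !is.null(pair_tbl)) {
    pc_meta <- pair_tbl
    pc_cols <- lapply(seq_len(nrow(pair_tbl)), function(i) {
      x1 <- as.numeric(G[sd_$lines, pair_tbl$am1[i]])
      x2 <- as.numeric(G[sd_$lines, pair_tbl$am2[i]])
      per_env(x1 * x2)
    })
  }

  base_for <- function(chrs, poss, clusters) {
    ok <- !(reps$cluster %in% clusters)
    for (i in seq_along(chrs)) {
      ok <- ok & !(reps$chr == chrs[i] & abs(reps$pos_cM - poss[i]) <= exclusion_cM)
    }
    out <- cbind(sd_$E, cof_cols(reps$marker[ok]))
    if (length(pc_cols)) {
      pok <- !(pc_meta$c1 %in% clusters) & !(pc_meta$c2 %in% clusters)
      r1 <- match(pc_meta$c1, reps$cluster)
      r2 <- match(pc_meta$c2, reps$cluster)
      for (i in seq_along(chrs)) {
        pok <- pok &
          !(reps$chr[r1] == chrs[i] & abs(reps$pos_cM[r1] - poss[i]) <= exclusion_cM) &
          !(reps$chr[r2] == chrs[i] & abs(reps$pos_cM[r2] - poss[i]) <= exclusion_cM)
      }
      if (any(pok)) out <- cbind(out, do.call(cbind, pc_cols[pok]))
    }
    out
  }

  # ---- 1D family: cached QR factors, batched permutation RSS ----
  q1 <- list()
  if (run_1d) {
    q1 <- vector("list", nrow(cand))
    for (t in seq_len(nrow(cand))) {
      base <- base_for(cand$chr[t], cand$pos_cM[t], cand$cluster[t])
      Xr <- base
      Xf <- cbind(base, per_env(X[, cand$marker[t]]))
      q1[[t]] <- c(thin_Q(Xf), setNames(thin_Q(Xr), c("Qr", "rank_r")))
    }
  }

  # ---- 2D family: refinement grids ----
  # Grid members are all map markers within refine_cM of the nominating
  # anchors on the cluster's chromosome (not just candidates carrying the
  # cluster's label): the local epistatic peak may sit at the edge of, or
  # just beyond, the expanded candidate set.
  run_2d <- run_2d && !is.null(pair_tbl)
  if (run_2d) {
    members_near <- function(cl, poss) {
      chr <- reps$chr[match(cl, reps$cluster)]
      which(mkinfo$chr == chr &
        vapply(mkinfo$pos_cM, function(p) any(abs(p - poss) <= refine_cM), TRUE))
    }
    pair_tbl$members1 <- purrr::map2(pair_tbl$c1, pair_tbl$anchors1, members_near)
    pair_tbl$members2 <- purrr::map2(pair_tbl$c2, pair_tbl$anchors2, members_near)
    keep <- lengths(pair_tbl$members1) > 0 & lengths(pair_tbl$members2) > 0
    pair_tbl <- pair_tbl[keep, , drop = FALSE]
    if (!nrow(pair_tbl)) run_2d <- FALSE
  }
  if (run_2d) {
    pool <- sort(unique(unlist(c(pair_tbl$members1, pair_tbl$members2))))
    Xm <- apply(G[sd_$lines, mkinfo$marker[pool], drop = FALSE], 2, as.numeric)
    colnames(Xm) <- mkinfo$marker[pool]
  }

  fit_pair <- function(yvec, i1, i2, cl1, cl2) {
    base <- base_for(
      c(mkinfo$chr[i1], mkinfo$chr[i2]), c(mkinfo$pos_cM[i1], mkinfo$pos_cM[i2]),
      c(cl1, cl2)
    )
    x1 <- Xm[, mkinfo$marker[i1]]
    x2 <- Xm[, mkinfo$marker[i2]]
    Xr <- cbind(base, per_env(x1), per_env(x2))
    Xf <- cbind(Xr, per_env(x1 * x2))
    qf <- thin_Q(Xf)
    qr_ <- thin_Q(Xr)
    term_F(qf$Q, qf$rank, qr_$Q, qr_$rank, matrix(yvec, ncol = 1), N)
  }

  scan_2d <- function(yvec) {
    S <- env_scores(yvec, sd_$n, H)
    purrr::map_dfr(seq_len(nrow(pair_tbl)), function(pi) {
      m1 <- pair_tbl$members1[[pi]]
      m2 <- pair_tbl$members2[[pi]]
      at <- refine_pair(
        S,
        Xm[, mkinfo$marker[m1], drop = FALSE],
        Xm[, mkinfo$marker[m2], drop = FALSE]
      )
      i1 <- m1[at[1]]
      i2 <- m2[at[2]]
      f <- fit_pair(yvec, i1, i2, pair_tbl$c1[pi], pair_tbl$c2[pi])
      tibble::tibble(
        i1 = i1, i2 = i2, F = f$F[1],
        df1 = as.integer(f$df1), df2 = as.integer(f$df2)
      )
    })
  }

  # observed statistics
  out1 <- NULL
  if (run_1d) {
    Yobs <- matrix(sd_$y, ncol = 1)
    o <- purrr::map(q1, function(qq) term_F(qq$Q, qq$rank, qq$Qr, qq$rank_r, Yobs, N))
    out1 <- tibble::tibble(
      family = "1d",
      marker1 = cand$marker, chr1 = cand$chr, pos1 = cand$pos_cM,
      marker2 = NA_character_, chr2 = NA_integer_, pos2 = NA_real_,
      F = vapply(o, function(x) x$F[1], 0),
      df1 = vapply(o, function(x) as.integer(x$df1 %||% NA_integer_), 1L),
      df2 = vapply(o, function(x) as.integer(x$df2 %||% NA_integer_), 1L)
    )
    if (anyNA(out1$F)) {
      warn(sprintf(
        "%d 1D term(s) skipped (collinear or zero-variance); F recorded missing.",
        sum(is.na(out1$F))
      ))
    }
  }
  out2 <- NULL
  if (run_2d) {
    o2 <- scan_2d(sd_$y)
    out2 <- tibble::tibble(
      family = "2d",
      marker1 = mkinfo$marker[o2$i1], chr1 = mkinfo$chr[o2$i1], pos1 = mkinfo$pos_cM[o2$i1],
      marker2 = mkinfo$marker[o2$i2], chr2 = mkinfo$chr[o2$i2], pos2 = mkinfo$pos_cM[o2$i2],
      F = o2$F, df1 = o2$df1, df2 = o2$df2
    )
  }

  # permutation thresholds
  if (is.null(thresholds)) {
    if (B < 19) abort("B must be at least 19 for alpha = 0.05 order statistics.")
    set.seed(seed)
    perm_idx <- replicate(B, {
      pm <- sample.int(sd_$n)
      rep((seq_len(H) - 1) * sd_$n, each = sd_$n) + pm
    })
    thresholds <- list()
    if (run_1d) {
      Yperm <- matrix(sd_$y[perm_idx], N, B)
      mx <- rep(-Inf, B)
      for (t in seq_len(nrow(cand))) {
        qq <- q1[[t]]
        Fv <- term_F(qq$Q, qq$rank, qq$Qr, qq$rank_r, Yperm, N)$F
        if (!anyNA(Fv)) mx <- pmax(mx, Fv)
      }
      thresholds[["1d"]] <- sort(mx)[min(ceiling((B + 1) * (1 - alpha)), B)]
    }
    if (run_2d) {
      mx2 <- vapply(seq_len(B), function(b) {
        max(scan_2d(sd_$y[perm_idx[, b]])$F, na.rm = TRUE)
      }, 0)
      thresholds[["2d"]] <- sort(mx2)[min(ceiling((B + 1) * (1 - alpha)), B)]
    }
  }

  out <- dplyr::bind_rows(out1, out2)
  out$p <- pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  out$threshold <- vapply(out$family, function(f) thresholds[[f]] %||% NA_real_, 0)
  out$significant <- !is.na(out$F) & !is.na(out$threshold) & out$F >= out$threshold
  structure(
    out,
    thresholds = thresholds, alpha = alpha, B = B,
    candidates = cand, exclusion_cM = exclusion_cM,
    class = c("qts_scan", class(out))
  )
}

#' Permutation threshold for a scan family
#'
#' Convenience wrapper running only the permutation part of [qts_scan()]
#' on a dataset and returning the experiment-wise thresholds, for re-use
#' across replicates of the same scenario.
#'
#' @inheritParams qts_scan
#' @return Named list of thresholds by family.
#' @export
permutation_threshold <- function(G, pheno, candidates, B = 1000, alpha = 0.05,
                                  seed = 1L, exclusion_cM = 30, refine_cM = 10,
                                  families = c("1d", "2d")) {
  sc <- qts_scan(G, pheno, candidates,
    B = B, alpha = alpha, seed = seed,
    exclusion_cM = exclusion_cM, refine_cM = refine_cM, families = families
  )
  attr(sc, "thresholds")
}

#' @export
tidy.qts_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.qts_scan <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_terms = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    alpha = attr(x, "alpha"),
    threshold_1d = th[["1d"]] %||% NA_real_,
    threshold_2d = th[["2d"]] %||% NA_real_
  )
}
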