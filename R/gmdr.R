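#' GMDR score residuals
#'
#' The quantitative-trait score used by the GMDR screen under an identity
#' link: the phenotype residual after removing the grand mean and the
#' environment means (the null covariate model),
#' \eqn{s_{hk} = y_{hk} - \hat\mu - \hat e_h}. Scores sum to zero within
#' each environment.
#'
#' @param pheno Phenotype tibble (`line`, `env`, `value`).
#' @return Tibble `line`, `env`, `score`.
#' @export
compute_score_residuals <- function(pheno) {
  validate_phenotypes(pheno)
  counts <- pheno |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::count(.data$env)
  if (nrow(counts) == 0 || any(counts$n < 2)) {
    abort("every environment needs at least 2 non-missing observations.")
  }
  pheno |>
    dplyr::group_by(.data$env) |>
    dplyr::mutate(score = .data$value - mean(.data$value, na.rm = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::select("line", "env", "score")
}

# Per-line pooled score (summed over environments); lines with any missing
# value are dropped with a message.
pooled_scores <- function(pheno, G) {
  validate_phenotypes(pheno, G)
  sc <- compute_score_residuals(pheno)
  agg <- sc |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(score = sum(.data$score), any_na = anyNA(.data$score))
  if (any(agg$any_na)) {
    inform(sprintf("%d line(s) with missing phenotypes excluded from screening.", sum(agg$any_na)))
    agg <- dplyr::filter(agg, !.data$any_na)
  }
  agg <- agg[match(intersect(line_ids(G), agg$line), agg$line), ]
  setNames(agg$score, agg$line)
}

#' Classify genotype cells as high or low score
#'
#' Bins lines by their joint genotype at a 1-3 marker combination and
#' labels each cell by the sign of the summed scores of the lines it
#' contains: HIGH if positive, LOW if negative, UNCLASSIFIED if the cell
#' is empty or sums to exactly zero.
#'
#' @param scores Named numeric vector of per-line scores (names = line ids).
#' @param G A [genotype_matrix()].
#' @param combo Character vector of 1-3 marker ids.
#' @return Tibble with columns `cell`, `n`, `score_sum`, `label`.
#' @export
classify_cells <- function(scores, G, combo) {
  stopifnot(length(combo) %in% 1:3, all(combo %in% colnames(G)))
  lines <- intersect(line_ids(G), names(scores))
  g <- G[lines, combo, drop = FALSE]
  cell <- apply(g, 1, paste, collapse = "/")
  complete <- !apply(g, 1, anyNA)
  tab <- tibble::tibble(cell = cell[complete], score = scores[lines][complete]) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(n = dplyr::n(), score_sum = sum(.data$score)) |>
    dplyr::mutate(label = dplyr::case_when(
      .data$score_sum > 1e-12 ~ "HIGH",
      .data$score_sum < -1e-12 ~ "LOW",
      TRUE ~ "UNCLASSIFIED"
    ))
  tab
}

balanced_accuracy <- function(pos, pred) {
  has_pos <- any(pos)
  has_neg <- any(!pos)
  if (!has_pos && !has_neg) return(NA_real_)
  sens <- if (has_pos) mean(pred[pos]) else NA_real_
  spec <- if (has_neg) mean(!pred[!pos]) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

#' Cross-validated accuracy of one marker combination
#'
#' Evaluates a single 1-3 locus model by k-fold cross-validation: cells are
#' labeled on the training folds ([classify_cells()] logic) and testing
#' balanced accuracy is computed on the held-out fold, skipping test lines
#' whose cell is unclassified. Folds in which no test line is classifiable
#' are excluded from the mean with a warning. Pure R reference
#' implementation of the combination evaluation also performed (in bulk) by
#' [gmdr_screen()].
#'
#' @param G A [genotype_matrix()].
#' @param pheno Phenotype tibble.
#' @param combo Character vector of marker ids (length 1-3).
#' @param k_folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param folds Optional explicit fold assignment (named integer vector by
#'   line id); overrides `seed`.
#' @return Tibble with one row: `order`, `markers` (list), `accuracy`
#'   (mean testing balanced accuracy), `fold_accuracy` (list of per-fold
#'   values).
#' @export
evaluate_combo <- function(G, pheno, combo, k_folds = 10, seed = 1L, folds = NULL) {
  stopifnot(k_folds >= 2, nrow(G) >= k_folds)
  scores <- pooled_scores(pheno, G)
  lines <- names(scores)
  if (is.null(folds)) {
    set.seed(seed)
    folds <- setNames(sample(rep_len(seq_len(k_folds), length(lines))), lines)
  } else {
    folds <- folds[lines]
  }
  g <- G[lines, combo, drop = FALSE]
  cell <- apply(g, 1, paste, collapse = "/")
  complete <- !apply(g, 1, anyNA)
  fold_acc <- rep(NA_real_, k_folds)
  for (f in seq_len(k_folds)) {
    train <- folds != f & complete
    test <- folds == f & complete
    sums <- tapply(scores[train], cell[train], sum)
    lab <- ifelse(sums > 1e-12, "HIGH", ifelse(sums < -1e-12, "LOW", "UNCLASSIFIED"))
    tcell <- cell[test]
    known <- tcell %in% names(lab)[lab != "UNCLASSIFIED"]
    if (!any(known)) {
      warn(sprintf("fold %d has no classifiable test line; excluded.", f))
      next
    }
    pred <- lab[tcell[known]] == "HIGH"
    pos <- scores[test][known] > 0
    fold_acc[f] <- balanced_accuracy(pos, unname(pred))
  }
  tibble::tibble(
    order = length(combo),
    markers = list(combo),
    accuracy = mean(fold_acc, na.rm = TRUE),
    fold_accuracy = list(fold_acc)
  )
}

# Greedy locus-signature deduplication of ranked models. Loci are anchored
# on the markers of the strongest models seen so far: a marker joins an
# existing anchor when within clump_cM of it on the same chromosome,
# otherwise it founds a new anchor. A model is skipped when its markers
# collapse onto fewer loci than its order (a tightly linked pair is a
# 1-locus model in disguise) or when its locus signature is already
# represented by a stronger model.
dedup_models <- function(models, mkinfo, retain, clump_cM) {
  seen <- character(0)
  keep <- integer(0)
  anchors <- list()
  anchor_id <- function(mk) {
    i <- match(mk, mkinfo$marker)
    chr <- mkinfo$chr[i]
    pos <- mkinfo$pos_cM[i]
    for (aid in seq_along(anchors)) {
      a <- anchors[[aid]]
      if (identical(a$chr, chr) && abs(a$pos - pos) <= clump_cM) return(aid)
    }
    anchors[[length(anchors) + 1]] <<- list(chr = chr, pos = pos)
    length(anchors)
  }
  for (r in seq_len(nrow(models))) {
    ids <- vapply(models$markers[[r]], anchor_id, 1L)
    if (anyDuplicated(ids)) next
    sig <- paste(sort(ids), collapse = "-")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    keep <- c(keep, r)
    if (length(keep) >= retain) break
  }
  models[keep, , drop = FALSE]
}

# Cluster the retained markers themselves: the highest-ranked marker of a
# cluster is its representative; markers within clump_cM join it.
cluster_markers <- function(markers_ranked, mkinfo, clump_cM) {
  reps <- mkinfo[0, c("marker", "chr", "pos_cM")] # inherit column types
  assign <- character(length(markers_ranked))
  for (i in seq_along(markers_ranked)) {
    mk <- markers_ranked[i]
    j <- match(mk, mkinfo$marker)
    hit <- which(reps$chr == mkinfo$chr[j] & abs(reps$pos_cM - mkinfo$pos_cM[j]) <= clump_cM)
    if (length(hit)) {
      assign[i] <- reps$marker[hit[1]]
    } else {
      reps <- dplyr::bind_rows(reps, tibble::tibble(
        marker = mk, chr = mkinfo$chr[j], pos_cM = mkinfo$pos_cM[j]
      ))
      assign[i] <- mk
    }
  }
  setNames(assign, markers_ranked)
}

unrank_combo <- function(idx, p, order) {
  # linear index (1-based, lexicographic) -> marker column indices
  t(combn(p, order))[idx, , drop = FALSE]
}

#' GMDR multilocus screen
#'
#' Stage 1 of the two-step mapping strategy: exhaustively evaluates every
#' 1-, 2- (and optionally 3-) locus model by seeded k-fold cross-validated
#' balanced accuracy of the score-residual classification, ranks models by
#' (mean testing accuracy, cross-validation consistency, lexicographic
#' marker order), deduplicates models that re-use the same loci (markers
#' within `clump_cM` on a chromosome count as one locus), retains the top
#' `retain` models per order, and returns the union of their markers as
#' the candidate SNP set for the mixed-model scan.
#'
#' Because adjacent markers on a dense map are near-copies of each other,
#' the retained models are reported as distinct loci, and each retained
#' locus is expanded into a candidate cluster: every map marker within
#' `expand_cM` of the locus enters the candidate set, labeled with its
#' cluster. The scan then tests each cluster member directly, so a true
#' QTS is tested itself rather than through whichever neighbour happened
#' to win the cross-validation ranking.
#'
#' @param G A [genotype_matrix()].
#' @param pheno Phenotype tibble (`line`, `env`, `value`).
#' @param max_order Highest combination order to search (1-3).
#' @param retain Models retained per order after deduplication (the
#'   default keeps enough distinct loci that weak true QTSs are not
#'   crowded out by linkage shadows of strong ones on dense maps).
#' @param k_folds CV folds.
#' @param seed Seed for fold assignment.
#' @param clump_cM Locus-deduplication window (cM): markers closer than
#'   this on a chromosome count as the same locus (at the RIL linkage of
#'   the default map, 20 cM corresponds to a genotype correlation of
#'   about 0.45).
#' @param expand_cM Cluster half-width (cM) around each retained locus.
#' @param budget Maximum number of combination evaluations; the search
#'   refuses (with an error) rather than exceed it.
#' @param adjust Screen orders 2-3 on scores residualized for the retained
#'   single-locus candidates (one representative per cluster), so the
#'   multi-locus search targets interaction signal rather than re-finding
#'   strong additive loci. `FALSE` uses the raw scores at every order.
#' @param top_raw_3 Heap size for the 3-locus search.
#' @return Object of class `qts_candidates`: a list with `candidates`
#'   (tibble `marker`, `chr`, `pos_cM`, `cluster`) and `models` (tibble
#'   `order`, `markers`, `accuracy`, `consistency`).
#' @export
gmdr_screen <- function(G, pheno, max_order = 2, retain = 20, k_folds = 10,
                        seed = 1L, clump_cM = 20, expand_cM = 15, budget = 5e7,
                        adjust = TRUE, top_raw_3 = 5000) {
  stopifnot(max_order %in% 1:3, retain >= 1, k_folds >= 2)
  p <- ncol(G)
  n_eval <- sum(vapply(1:max_order, function(o) choose(p, o), 0))
  if (n_eval > budget) {
    abort(sprintf(
      paste0(
        "search space (%.3g combination evaluations) exceeds the budget (%.3g); ",
        "lower max_order or pre-filter the markers."
      ), n_eval, budget
    ))
  }
  scores <- pooled_scores(pheno, G)
  lines <- names(scores)
  n <- length(lines)
  if (n < k_folds) abort("fewer lines than folds.")
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k_folds), n))
  codes <- unclass(G)[lines, , drop = FALSE]
  mkinfo <- fill_marker_positions(marker_info(G))

  pair_index <- function(i, j) (i - 1) * p - i * (i - 1) / 2 + (j - i)
  # best accuracy among a model's sub-models: a higher-order model that
  # fails to beat its best sub-model carries a free-riding marker and is
  # dropped (parsimony)
  best_sub <- function(midx, acc1, acc2) {
    s <- max(acc1[midx], na.rm = TRUE)
    if (length(midx) == 3 && !is.null(acc2)) {
      pidx <- c(
        pair_index(midx[1], midx[2]), pair_index(midx[1], midx[3]),
        pair_index(midx[2], midx[3])
      )
      s <- max(s, acc2[pidx], na.rm = TRUE)
    }
    s
  }

  retained <- list()
  acc1 <- acc2 <- NULL
  ord_scores <- unname(scores)
  for (ord in seq_len(max_order)) {
    if (ord == 2 && adjust && length(retained) && nrow(retained[[1]])) {
      # Screen higher orders on scores residualized for the nominated
      # single-locus candidates: strong additive loci otherwise dominate
      # the multi-locus accuracy landscape and mask epistatic pairs.
      # One representative marker per retained single-locus cluster.
      top1 <- unique(unlist(retained[[1]]$markers))
      reps1 <- unique(unname(cluster_markers(top1, mkinfo, clump_cM)))
      Z <- cbind(1, codes[, reps1, drop = FALSE])
      Z[is.na(Z)] <- 0
      ord_scores <- unname(stats::lm.fit(Z, unname(scores))$residuals)
      # single-locus accuracies on the adjusted scores are the parsimony
      # baseline for the adjusted pair search
      acc1 <- .gmdr_search(codes, ord_scores, folds, 1L, 0L)$accuracy
    }
    top_k <- if (ord == 3) top_raw_3 else 0L
    res <- .gmdr_search(codes, ord_scores, folds, ord, top_k)
    if (ord == 3) {
      combos <- res$combos
      acc <- res$accuracy
    } else {
      acc <- res$accuracy
      combos <- NULL
      if (ord == 1) acc1 <- acc else acc2 <- acc
    }
    fold_best <- res$fold_best
    if (ord == 3) {
      # consistency for heap results: count folds whose best linear index
      # maps to a retained combo
      cvc_tab <- table(fold_best[!is.na(fold_best)])
      mk_rows <- combos
      model_tbl <- tibble::tibble(
        order = ord,
        midx = lapply(seq_len(nrow(mk_rows)), function(r) sort(mk_rows[r, ])),
        accuracy = acc
      )
      best_combos <- unrank_combo(as.integer(names(cvc_tab)), p, ord)
      best_key <- apply(best_combos, 1, paste, collapse = "-")
      model_key <- vapply(model_tbl$midx, paste, "", collapse = "-")
      model_tbl$consistency <- as.integer(cvc_tab[match(model_key, best_key)])
      model_tbl$consistency[is.na(model_tbl$consistency)] <- 0L
    } else {
      n_top <- min(length(acc), max(retain * 50L, 500L))
      ok <- which(!is.na(acc))
      if (ord == 2) {
        # parsimony on the full search: a pair must beat its best single
        # sub-model, otherwise it is a passenger pair; filtering before
        # ranking matters because passenger pairs of a strong marker can
        # occupy the entire top of the raw accuracy ranking
        ij <- combn(p, 2)
        sub <- pmax(acc1[ij[1, ]], acc1[ij[2, ]])
        ok <- ok[acc[ok] > sub[ok] + 1e-9]
      }
      ordix <- ok[order(-acc[ok], ok)][seq_len(min(n_top, length(ok)))]
      mk_rows <- unrank_combo(ordix, p, ord)
      cvc_tab <- table(fold_best[!is.na(fold_best)])
      cvc <- as.integer(cvc_tab[as.character(ordix)])
      cvc[is.na(cvc)] <- 0L
      model_tbl <- tibble::tibble(
        order = ord,
        midx = lapply(seq_len(nrow(mk_rows)), function(r) sort(mk_rows[r, ])),
        accuracy = acc[ordix],
        consistency = cvc
      )
    }
    if (ord == 3) {
      sub <- vapply(model_tbl$midx, best_sub, 0, acc1 = acc1, acc2 = acc2)
      model_tbl <- model_tbl[model_tbl$accuracy > sub + 1e-9, , drop = FALSE]
    }
    model_tbl$markers <- lapply(model_tbl$midx, function(ii) colnames(codes)[ii])
    model_tbl$key <- vapply(model_tbl$markers, paste, "", collapse = ",")
    model_tbl <- model_tbl |>
      dplyr::arrange(dplyr::desc(.data$accuracy), dplyr::desc(.data$consistency), .data$key)
    retained[[ord]] <- dedup_models(model_tbl, mkinfo, retain, clump_cM) |>
      dplyr::select("order", "markers", "accuracy", "consistency")
  }
  models <- dplyr::bind_rows(retained)
  # retained markers ranked by their best model's accuracy, clustered into
  # loci, then expanded into candidate clusters of nearby map markers
  ranked <- models[order(-models$accuracy), ]
  ranked_markers <- unique(unlist(ranked$markers))
  clus <- cluster_markers(ranked_markers, mkinfo, clump_cM)
  rep_markers <- unique(unname(clus))
  cand_list <- lapply(rep_markers, function(rk) {
    j <- match(rk, mkinfo$marker)
    members <- mkinfo |>
      dplyr::filter(
        .data$chr == mkinfo$chr[j],
        abs(.data$pos_cM - mkinfo$pos_cM[j]) <= expand_cM
      ) |>
      dplyr::select("marker", "chr", "pos_cM")
    members$cluster <- rk
    members
  })
  candidates <- dplyr::bind_rows(cand_list) |>
    dplyr::distinct(.data$marker, .keep_all = TRUE)
  # cluster pairs nominated by the retained multi-locus models: the pairs
  # the 2D scan will test, each anchored on the nominating markers
  nominated <- NULL
  multi <- models[models$order >= 2, ]
  if (nrow(multi)) {
    prs <- purrr::map_dfr(seq_len(nrow(multi)), function(r) {
      cb <- t(combn(multi$markers[[r]], 2))
      tibble::tibble(m1 = cb[, 1], m2 = cb[, 2])
    })
    prs$c1 <- unname(clus[prs$m1])
    prs$c2 <- unname(clus[prs$m2])
    sw <- prs$c1 > prs$c2
    if (any(sw)) {
      tmp <- prs$c1[sw]
      prs$c1[sw] <- prs$c2[sw]
      prs$c2[sw] <- tmp
      tmp <- prs$m1[sw]
      prs$m1[sw] <- prs$m2[sw]
      prs$m2[sw] <- tmp
    }
    nominated <- prs |>
      dplyr::filter(.data$c1 != .data$c2) |>
      dplyr::distinct(.data$c1, .data$c2, .data$m1, .data$m2)
  }
  structure(
    list(candidates = candidates, models = models, nominated = nominated,
         k_folds = k_folds, seed = seed,
         clump_cM = clump_cM, expand_cM = expand_cM),
    class = "qts_candidates"
  )
}

#' @export
print.qts_candidates <- function(x, ...) {
  cat(sprintf(
    "<qts_candidates> %d candidate markers from %d retained models (orders %s)\n",
    nrow(x$candidates), nrow(x$models), paste(sort(unique(x$models$order)), collapse = ",")
  ))
  invisible(x)
}

#' @export
tidy.qts_candidates <- function(x, ...) {
  x$models |>
    dplyr::mutate(markers = vapply(.data$markers, paste, "", collapse = ",")) |>
    tibble::as_tibble()
}
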