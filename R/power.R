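match_1d <- function(scan_tbl, chr, pos, window_cM) {
  scan_tbl$family == "1d" & scan_tbl$significant &
    scan_tbl$chr1 == chr & abs(scan_tbl$pos1 - pos) <= window_cM
}

match_2d <- function(scan_tbl, chr1, pos1, chr2, pos2, window_cM) {
  hit <- function(ca, pa, cb, pb) {
    scan_tbl$chr1 == ca & abs(scan_tbl$pos1 - pa) <= window_cM &
      scan_tbl$chr2 == cb & abs(scan_tbl$pos2 - pb) <= window_cM
  }
  scan_tbl$family == "2d" & scan_tbl$significant &
    (hit(chr1, pos1, chr2, pos2) | hit(chr2, pos2, chr1, pos1))
}

truth_table <- function(truth, map) {
  pos_of <- function(mk) map$pos_cM[match(mk, map$marker)]
  chr_of <- function(mk) map$chr[match(mk, map$marker)]
  add <- NULL
  if (nrow(truth$additive)) {
    add <- tibble::tibble(
      type = "additive",
      marker1 = truth$additive$marker,
      chr1 = chr_of(truth$additive$marker),
      pos1 = pos_of(truth$additive$marker),
      marker2 = NA_character_, chr2 = NA_integer_, pos2 = NA_real_,
      par = truth$additive$a,
      par_ie = truth$additive$ae
    )
  }
  epi <- NULL
  if (nrow(truth$epistatic)) {
    epi <- tibble::tibble(
      type = "epistatic",
      marker1 = truth$epistatic$marker1,
      chr1 = chr_of(truth$epistatic$marker1),
      pos1 = pos_of(truth$epistatic$marker1),
      marker2 = truth$epistatic$marker2,
      chr2 = chr_of(truth$epistatic$marker2),
      pos2 = pos_of(truth$epistatic$marker2),
      par = truth$epistatic$aa,
      par_ie = truth$epistatic$aae
    )
  }
  dplyr::bind_rows(add, epi)
}

extract_estimates <- function(eff, tt_row, window_cM, mkinfo) {
  pos_of <- function(mk) mkinfo$pos_cM[match(mk, mkinfo$marker)]
  chr_of <- function(mk) mkinfo$chr[match(mk, mkinfo$marker)]
  if (tt_row$type == "additive") {
    if (!nrow(eff$additive)) return(NULL)
    d <- abs(pos_of(eff$additive$marker) - tt_row$pos1)
    ok <- which(chr_of(eff$additive$marker) == tt_row$chr1 & d <= window_cM)
    if (!length(ok)) return(NULL)
    i <- ok[which.min(d[ok])]
    list(main = eff$additive$a[i], ie = eff$additive$ae[[i]])
  } else {
    if (!nrow(eff$epistatic)) return(NULL)
    c1 <- chr_of(eff$epistatic$marker1)
    p1 <- pos_of(eff$epistatic$marker1)
    c2 <- chr_of(eff$epistatic$marker2)
    p2 <- pos_of(eff$epistatic$marker2)
    ok <- which(
      (c1 == tt_row$chr1 & abs(p1 - tt_row$pos1) <= window_cM &
        c2 == tt_row$chr2 & abs(p2 - tt_row$pos2) <= window_cM) |
        (c1 == tt_row$chr2 & abs(p1 - tt_row$pos2) <= window_cM &
          c2 == tt_row$chr1 & abs(p2 - tt_row$pos1) <= window_cM)
    )
    if (!length(ok)) return(NULL)
    i <- ok[1]
    list(main = eff$epistatic$aa[i], ie = eff$epistatic$aae[[i]])
  }
}

#' Replicated power study of the two-step pipeline
#'
#' Runs the full screen -> scan (-> MCMC) pipeline on `reps` independently
#' simulated replicates of a scenario and summarizes, per true QTS term,
#' the empirical power (percentage of replicates in which a significant
#' scan term fell within `detect_window_cM` of the true marker(s)) and,
#' when `estimate = TRUE`, the mean posterior-mean effect estimates over
#' the detecting replicates. Per-replicate seeds are `seed + replicate`.
#' The experiment-wise permutation threshold is, by default, calibrated
#' once per scenario on an extra calibration replicate (seed `seed`) and
#' reused, which matches how a single real dataset is analyzed and keeps
#' replicated studies affordable; `threshold_mode = "replicate"`
#' recomputes it per replicate.
#'
#' @param scenario A [qts_scenario()].
#' @param reps Number of replicates (defaults to the scenario's).
#' @param max_order,retain,k_folds GMDR screen settings (see
#'   [gmdr_screen()]).
#' @param B,alpha Permutation settings (see [qts_scan()]).
#' @param threshold_mode `"scenario"` (calibrate once) or `"replicate"`.
#' @param clump_cM Locus clump window for the screen and for assembling
#'   the full model (see [gmdr_screen()]).
#' @param exclusion_cM Cofactor exclusion window for the scan (see
#'   [qts_scan()]).
#' @param detect_window_cM Declaration window around a true QTS: a
#'   significant term within this distance counts as a detection. With
#'   densely spaced markers tightly linked neighbours of the true marker
#'   are statistically interchangeable, so the default accepts +-2 cM
#'   (two markers on the standard map); 0 requires an exact hit.
#' @param estimate Run the MCMC full-model stage per replicate and average
#'   effect estimates over detecting replicates.
#' @param mcmc List of overrides for [fit_qts_mcmc()] (iterations, burnin,
#'   thin).
#' @param seed Base seed (defaults to the scenario's).
#' @param progress Print one line per replicate.
#' @return Tibble of class `qts_power`: one row per true term with
#'   `power` (%), `n_detected`, `reps_used`, `par`, and (with
#'   `estimate = TRUE`) `est` and per-environment interaction estimate
#'   columns; attributes `thresholds`, `false_positive_rate`.
#' @export
run_power_study <- function(scenario, reps = NULL,
                            max_order = 2, retain = 20, k_folds = 10,
                            B = 200, alpha = 0.05,
                            threshold_mode = c("scenario", "replicate"),
                            clump_cM = 20, exclusion_cM = 30,
                            detect_window_cM = 2,
                            estimate = FALSE, mcmc = list(),
                            seed = NULL, progress = FALSE) {
  stopifnot(inherits(scenario, "qts_scenario"))
  threshold_mode <- match.arg(threshold_mode)
  reps <- reps %||% scenario$reps
  seed <- seed %||% scenario$seed
  tt <- truth_table(scenario$truth, scenario$map)
  H <- scenario$truth$n_env

  thresholds <- NULL
  if (threshold_mode == "scenario") {
    calib <- sim_scenario_replicate(scenario, seed)
    cand <- gmdr_screen(calib$G, calib$pheno,
      max_order = max_order, retain = retain,
      k_folds = k_folds, seed = seed, clump_cM = clump_cM
    )
    thresholds <- permutation_threshold(calib$G, calib$pheno, cand,
      B = B, alpha = alpha, seed = seed, exclusion_cM = exclusion_cM
    )
  }

  n_truth <- if (is.null(tt)) 0 else nrow(tt)
  detected <- matrix(FALSE, reps, max(n_truth, 1))
  est_main <- matrix(NA_real_, reps, max(n_truth, 1))
  est_ie <- array(NA_real_, c(reps, max(n_truth, 1), H))
  any_false <- rep(NA, reps)
  failed <- logical(reps)

  for (r in seq_len(reps)) {
    rep_seed <- seed + r
    res <- tryCatch(
      {
        dat <- sim_scenario_replicate(scenario, rep_seed)
        cand <- gmdr_screen(dat$G, dat$pheno,
          max_order = max_order, retain = retain,
          k_folds = k_folds, seed = rep_seed, clump_cM = clump_cM
        )
        scan <- qts_scan(dat$G, dat$pheno, cand,
          B = B, alpha = alpha, seed = rep_seed,
          exclusion_cM = exclusion_cM, thresholds = thresholds
        )
        list(dat = dat, scan = scan)
      },
      error = function(e) {
        warn(sprintf("replicate %d failed and was excluded: %s", r, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      failed[r] <- TRUE
      next
    }
    stbl <- tibble::as_tibble(res$scan)
    true_hit <- rep(FALSE, nrow(stbl))
    if (n_truth) {
      for (ti in seq_len(n_truth)) {
        hit <- if (tt$type[ti] == "additive") {
          match_1d(stbl, tt$chr1[ti], tt$pos1[ti], detect_window_cM)
        } else {
          match_2d(stbl, tt$chr1[ti], tt$pos1[ti], tt$chr2[ti], tt$pos2[ti], detect_window_cM)
        }
        detected[r, ti] <- any(hit, na.rm = TRUE)
        true_hit <- true_hit | hit
      }
    }
    any_false[r] <- any(stbl$significant & !true_hit, na.rm = TRUE)
    if (estimate && any(stbl$significant, na.rm = TRUE)) {
      margs <- modifyList(
        list(
          G = res$dat$G, pheno = res$dat$pheno,
          model = build_full_model(res$scan, exclusion_cM = clump_cM),
          seed = rep_seed
        ),
        mcmc
      )
      fit <- do.call(fit_qts_mcmc, margs)
      eff <- attr(fit, "effects")
      mkinfo <- marker_info(res$dat$G)
      for (ti in seq_len(n_truth)) {
        if (!detected[r, ti]) next
        ex <- extract_estimates(eff, tt[ti, ], detect_window_cM, mkinfo)
        if (is.null(ex)) next
        est_main[r, ti] <- ex$main
        est_ie[r, ti, ] <- ex$ie
      }
    }
    if (progress) {
      inform(sprintf(
        "replicate %d/%d: %d significant terms, detected %s",
        r, reps, sum(stbl$significant, na.rm = TRUE),
        paste(as.integer(detected[r, seq_len(max(n_truth, 1))]), collapse = "")
      ))
    }
  }

  used <- !failed
  out <- if (n_truth) {
    purrr::map_dfr(seq_len(n_truth), function(ti) {
      det <- detected[used, ti]
      row <- tibble::tibble(
        type = tt$type[ti],
        marker1 = tt$marker1[ti], chr1 = tt$chr1[ti],
        marker2 = tt$marker2[ti], chr2 = tt$chr2[ti],
        par = tt$par[ti],
        power = 100 * mean(det),
        n_detected = sum(det),
        reps_used = sum(used)
      )
      if (estimate) {
        row$est <- mean(est_main[used, ti][det], na.rm = TRUE)
        for (h in seq_len(H)) {
          row[[paste0("par_ie", h)]] <- tt$par_ie[[ti]][h]
          row[[paste0("est_ie", h)]] <- mean(est_ie[used, ti, h][det], na.rm = TRUE)
        }
      }
      row
    })
  } else {
    tibble::tibble(
      type = character(0), marker1 = character(0), chr1 = integer(0),
      marker2 = character(0), chr2 = integer(0), par = numeric(0),
      power = numeric(0), n_detected = integer(0), reps_used = integer(0)
    )
  }
  structure(
    out,
    thresholds = thresholds,
    detected = detected[used, , drop = FALSE],
    false_positive_rate = mean(any_false[used]),
    reps = reps, failed = sum(failed),
    detect_window_cM = detect_window_cM,
    class = c("qts_power", class(out))
  )
}

#' @export
print.qts_power <- function(x, ...) {
  cat(sprintf(
    "<qts_power> %d true terms, %d replicates (%d failed), window +-%.0f cM\n",
    nrow(x), attr(x, "reps"), attr(x, "failed"), attr(x, "detect_window_cM")
  ))
  NextMethod()
  invisible(x)
}

#' @export
tidy.qts_power <- function(x, ...) tibble::as_tibble(x)
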