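#' Plot a QTS scan
#'
#' Manhattan-style plot of the 1D scan F statistics against map position,
#' faceted by chromosome, with the experiment-wise permutation threshold
#' as a dashed line; significant terms are highlighted.
#'
#' @param object A `qts_scan` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qts_scan <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(.data$family == "1d", !is.na(.data$F))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos1, y = .data$F)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::geom_hline(
      yintercept = attr(object, "thresholds")[["1d"]] %||% NA_real_,
      linetype = "dashed"
    ) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr1), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "position (cM)", y = "F statistic",
      colour = "significant",
      title = "1D QTS scan over screened candidates"
    ) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.qts_scan
#' @param x A `qts_scan` result.
#' @export
plot_scan <- function(x, ...) autoplot.qts_scan(x, ...)

#' Plot a power study
#'
#' Bar chart of empirical power per true QTS term.
#'
#' @param object A `qts_power` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qts_power <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(term = ifelse(is.na(.data$marker2), .data$marker1,
      paste(.data$marker1, .data$marker2, sep = " x ")
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$power, fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(
      x = NULL, y = "power (% of replicates)",
      title = sprintf("Empirical power over %d replicates", attr(object, "reps"))
    ) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.qts_power
#' @param x A `qts_power` result.
#' @export
plot_power <- function(x, ...) autoplot.qts_power(x, ...)

#' Plot posterior effect estimates
#'
#' Point-and-interval plot of posterior means with +-1 posterior SD for
#' every genetic effect in a fitted full model.
#'
#' @param object A `qts_mcmc` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qts_mcmc <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$effect %in% c("mu") & !grepl("^e[0-9]+$", .data$effect)) |>
    dplyr::mutate(label = paste(.data$term, .data$effect))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - .data$sd,
      xmax = .data$estimate + .data$sd
    )) +
    ggplot2::labs(
      x = "posterior mean +- SD (trait units)", y = NULL,
      title = "Full-model posterior effect estimates"
    ) +
    ggplot2::theme_bw()
}
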