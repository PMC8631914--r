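# ggplot2 displays for the main result types.

#' Plot a cohort trace
#'
#' Survival curve (default) or stacked state occupancy over time.
#'
#' @param object An `hf_trace`.
#' @param type `"survival"` or `"occupancy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hf_trace
#' @export
autoplot.hf_trace <- function(object, type = c("survival", "occupancy"), ...) {
  type <- match.arg(type)
  if (type == "survival") {
    sc <- survival_curve(object)
    return(
      ggplot2::ggplot(sc, ggplot2::aes(x = .data$time, y = .data$alive)) +
        ggplot2::geom_step() +
        ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
        ggplot2::labs(
          x = "Time (years)", y = "Fraction alive",
          title = paste("Survival:", attr(object, "strategy"))
        ) +
        ggplot2::ylim(0, 1)
    )
  }
  long <- tidyr::pivot_longer(
    dplyr::select(
      as_tibble(object), "time_end", dplyr::starts_with("end_")
    ),
    dplyr::starts_with("end_"),
    names_to = "state", names_prefix = "end_", values_to = "fraction"
  )
  long$state <- factor(long$state, levels = HF_STATES)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_end, y = .data$fraction, fill = .data$state
  )) +
    ggplot2::geom_area() +
    ggplot2::labs(
      x = "Time (years)", y = "State occupancy",
      title = paste("Occupancy:", attr(object, "strategy"))
    )
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars span the ICER obtained at each parameter's low and high
#' bound; the dashed line marks the base-case ICER. Invalid or dominance-
#' tagged entries are dropped from the display.
#'
#' @param object An `hf_owsa` from [owsa()].
#' @param top Number of parameters to show (default all numeric entries).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hf_owsa
#' @export
autoplot.hf_owsa <- function(object, top = Inf, ...) {
  df <- dplyr::filter(
    as_tibble(object),
    is.finite(.data$icer_low), is.finite(.data$icer_high)
  )
  df <- utils::head(df, top)
  df$path <- factor(df$path, levels = rev(df$path))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$path)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high, yend = .data$path),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(
      xintercept = attr(object, "base_icer"), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "ICER ($ per QALY)", y = NULL,
      title = paste(attr(object, "pair"), collapse = " vs ")
    )
}

#' Incremental cost-effectiveness plane of a PSA
#'
#' Scatter of incremental QALY / incremental cost pairs with the WTP
#' threshold line through the origin.
#'
#' @param object An `hf_psa` from [run_psa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hf_psa
#' @export
autoplot.hf_psa <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$dqaly, y = .data$dcost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost ($)",
      title = paste(object$pair, collapse = " vs "),
      subtitle = sprintf("WTP line at $%.2f per QALY", object$wtp)
    )
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_tbl Tibble from [ceac()].
#' @param wtp Optional WTP threshold to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tbl, wtp = NULL) {
  p <- ggplot2::ggplot(
    ceac_tbl, ggplot2::aes(x = .data$wtp, y = .data$probability)
  ) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "Willingness to pay ($ per QALY)",
      y = "Probability cost-effective"
    )
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = "dashed")
  }
  p
}
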