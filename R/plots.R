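#' Cost-effectiveness plane scatter
#'
#' PSA cloud of (QALY difference, cost difference) for a reference strategy
#' versus each comparator, with the willingness-to-pay threshold drawn as a
#' dashed line through the origin.
#'
#' @param psa A [run_psa()] result.
#' @param reference Reference strategy label.
#' @param wtp Threshold for the dashed line; defaults to the PSA's configured
#'   threshold.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, reference = "polypill", wtp = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  wtp <- wtp %||% psa$wtp
  comps <- setdiff(psa$strategies, reference)
  df <- do.call(rbind, lapply(comps, function(s) data.frame(
    comparator = s,
    dqaly = psa$qalys[, reference] - psa$qalys[, s],
    dcost = psa$cost[, reference] - psa$cost[, s])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dqaly, y = .data$dcost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~comparator) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = paste(reference, "vs comparators"),
                  subtitle = sprintf("dashed line: WTP %s USD/QALY",
                                     format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' @param bars A [tornado()] result.
#' @param top Number of largest bars to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(bars, top = 15) {
  stopifnot(is.data.frame(bars), all(c("parameter", "low", "high") %in% names(bars)))
  base <- attr(bars, "base") %||% 0
  df <- utils::head(bars, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low, xend = .data$high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = switch(attr(bars, "outcome") %||% "nmb",
                             nmb = "Incremental net monetary benefit (USD)",
                             icer = "ICER (USD/QALY)"),
                  y = NULL,
                  title = paste(attr(bars, "comparison"), collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param curves A [ceac()] result.
#' @param wtp Optional threshold marked with a dashed vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curves, wtp = NULL) {
  stopifnot(is.data.frame(curves),
            all(c("wtp", "strategy", "probability") %in% names(curves)))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                            colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp,
                                                  linetype = "dashed")
  p
}
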