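#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qalys`, with the two degenerate geometries flagged
#' instead of returning a misleading number: a strategy that saves money and
#' gains QALYs is `"dominant"`, one that costs more and loses QALYs is
#' `"dominated"`, and a zero QALY difference gives an undefined ratio.
#'
#' @param delta_cost Cost difference, USD.
#' @param delta_qalys QALY difference.
#' @return The ratio (USD/QALY), or the character flag `"dominant"`,
#'   `"dominated"` or `"undefined"`.
#' @export
#' @examples
#' icer(1000, 0.5)   # 2000
#' icer(-100, 0.5)   # "dominant"
icer <- function(delta_cost, delta_qalys) {
  if (delta_qalys == 0) return("undefined")
  if (delta_cost < 0 && delta_qalys > 0) return("dominant")
  if (delta_cost > 0 && delta_qalys < 0) return("dominated")
  delta_cost / delta_qalys
}

#' Net monetary benefit
#'
#' `wtp * qalys - cost`: the strategy with the highest net monetary benefit
#' at a willingness-to-pay threshold is the preferred one; this is the
#' decision rule behind the acceptability curve.
#'
#' @param cost Total discounted cost, USD.
#' @param qalys Total discounted QALYs.
#' @param wtp Willingness-to-pay threshold, USD/QALY, `>= 0`.
#' @return Net monetary benefit in USD. Vectorised.
#' @export
#' @examples
#' net_monetary_benefit(871, 14.55, 21768)  # 315853.4
net_monetary_benefit <- function(cost, qalys, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative")
  wtp * qalys - cost
}

#' Incremental analysis with dominance classification
#'
#' Sorts the strategy arms by cost, removes strictly dominated arms (another
#' arm is no worse on both dimensions and better on one) and extendedly
#' dominated arms (excluded by a convex combination of two others, detected
#' as a non-increasing ICER sequence along the cost-sorted frontier), and
#' computes pairwise ICERs along the remaining frontier. Ties in cost or
#' QALYs keep the alphabetically earlier label. The output is invariant to
#' input order. An arm that is strictly cheaper and more effective than every
#' other arm is labelled `dominant`.
#'
#' @param results Data.frame with columns `strategy`, `cost`, `qalys`
#'   (e.g. from [run_strategies()]), or a list of `strategy_result`s.
#' @return Data.frame sorted by cost: `strategy`, `cost`, `qalys`,
#'   `delta_cost`, `delta_qalys`, `icer` (character; number or flag), and
#'   `status` in `{dominant, on-frontier, dominated, extended-dominated}`.
#' @export
#' @examples
#' incremental_analysis(data.frame(strategy = c("A", "B"),
#'                                 cost = c(100, 90), qalys = c(1, 2)))
incremental_analysis <- function(results) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "strategy_result"))) {
    results <- data.frame(
      strategy = vapply(results, `[[`, character(1), "strategy"),
      cost = vapply(results, `[[`, numeric(1), "cost"),
      qalys = vapply(results, `[[`, numeric(1), "qalys"))
  }
  stopifnot(is.data.frame(results),
            all(c("strategy", "cost", "qalys") %in% names(results)))
  if (anyDuplicated(results$strategy)) stop("duplicate strategy labels")
  df <- results[order(results$cost, -results$qalys, results$strategy), ]
  n <- nrow(df)
  if (n < 2) stop("incremental analysis needs at least 2 strategies")
  status <- rep("on-frontier", n)

  # strict dominance: some other arm is <= cost and >= qalys, better somewhere
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      no_worse <- df$cost[j] <= df$cost[i] && df$qalys[j] >= df$qalys[i]
      better <- df$cost[j] < df$cost[i] || df$qalys[j] > df$qalys[i]
      tie <- df$cost[j] == df$cost[i] && df$qalys[j] == df$qalys[i]
      if ((no_worse && better) ||
          (tie && df$strategy[j] < df$strategy[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance: repeat until ICERs along the frontier increase
  repeat {
    keep <- which(status == "on-frontier")
    if (length(keep) < 3) break
    ic <- diff(df$cost[keep]) / diff(df$qalys[keep])
    drop <- which(diff(ic) <= 0)  # ICER not increasing => middle arm excluded
    if (!length(drop)) break
    status[keep[drop[1] + 1]] <- "extended-dominated"
  }

  front <- which(status == "on-frontier")
  df$delta_cost <- NA_real_; df$delta_qalys <- NA_real_
  df$icer <- NA_character_
  if (length(front)) {
    df$icer[front[1]] <- "-"
    for (k in seq_along(front)[-1]) {
      i <- front[k]; p <- front[k - 1]
      df$delta_cost[i] <- df$cost[i] - df$cost[p]
      df$delta_qalys[i] <- df$qalys[i] - df$qalys[p]
      ic <- icer(df$delta_cost[i], df$delta_qalys[i])
      df$icer[i] <- if (is.character(ic)) ic else format(ic, digits = 6)
    }
  }
  # an arm strictly cheapest and most effective dominates the whole field
  for (i in seq_len(n)) {
    if (all(df$cost[i] < df$cost[-i]) && all(df$qalys[i] > df$qalys[-i]))
      status[i] <- "dominant"
  }
  df$status <- status
  rownames(df) <- NULL
  df
}
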