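#' One-way (tornado) sensitivity analysis
#'
#' Varies each scalar uncertain parameter to `mean * (1 - delta)` and
#' `mean * (1 + delta)` (probabilities and utilities clamped to `[0, 1]`),
#' holding all others at their base-case values, and records the resulting
#' outcome for a pairwise comparison of two arms. The outcome is either the
#' incremental net monetary benefit at the configured willingness-to-pay
#' threshold (default) or the pairwise ICER. Bars are sorted by absolute
#' spread, largest first.
#'
#' @param params A [load_parameters()] result.
#' @param comparison Character vector of two strategy labels, intervention
#'   first. Default: polypill versus its strongest competitor (the comparator
#'   arm with the highest base-case net monetary benefit).
#' @param delta Relative variation (default 0.2, i.e. +/-20 percent).
#' @param outcome `"nmb"` (incremental NMB, USD) or `"icer"` (USD/QALY).
#' @param sides `"both"` for symmetric +/-delta bars, `"increase"` for the
#'   one-sided +delta variant.
#' @return Data.frame with columns `parameter`, `low` (outcome at -delta, or
#'   the base-case outcome when `sides = "increase"`), `high` (outcome at
#'   +delta), and `spread = high - low`, sorted by `abs(spread)` descending.
#'   The base-case outcome is in attribute `"base"`; the comparison pair in
#'   attribute `"comparison"`.
#' @export
tornado <- function(params, comparison = NULL, delta = 0.2,
                    outcome = c("nmb", "icer"), sides = c("both", "increase")) {
  stopifnot(inherits(params, "parameter_set"))
  outcome <- match.arg(outcome)
  sides <- match.arg(sides)
  if (delta < 0) stop("delta must be non-negative")
  wtp <- params$settings$wtp

  if (is.null(comparison)) {
    base <- run_strategies(params)
    nmb <- net_monetary_benefit(base$cost, base$qalys, wtp)
    comp <- base$strategy[base$strategy != "polypill"]
    best <- comp[which.max(nmb[base$strategy != "polypill"])]
    comparison <- c("polypill", best)
  }
  comparison <- match.arg(comparison, strategy_labels(), several.ok = TRUE)
  if (length(comparison) != 2) stop("comparison must name exactly two strategies")

  eval_outcome <- function(overrides) {
    rv <- realize_parameters(params, overrides = overrides)
    r1 <- run_cohort(params, comparison[1], rv = rv)
    r2 <- run_cohort(params, comparison[2], rv = rv)
    if (outcome == "nmb") {
      net_monetary_benefit(r1$cost, r1$qalys, wtp) -
        net_monetary_benefit(r2$cost, r2$qalys, wtp)
    } else {
      (r1$cost - r2$cost) / (r1$qalys - r2$qalys)
    }
  }

  reg <- param_registry(params)
  if (!length(reg)) stop("no uncertain parameters to vary")
  base_out <- eval_outcome(NULL)
  rows <- lapply(names(reg), function(id) {
    m <- reg[[id]]$spec$mean
    hi <- eval_outcome(stats::setNames(list(m * (1 + delta)), id))
    lo <- if (sides == "both")
      eval_outcome(stats::setNames(list(m * (1 - delta)), id))
    else base_out
    data.frame(parameter = id, low = lo, high = hi, spread = hi - lo)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$spread)), ]
  rownames(out) <- NULL
  attr(out, "base") <- base_out
  attr(out, "comparison") <- comparison
  attr(out, "outcome") <- outcome
  out
}

#' Probabilistic sensitivity analysis (Monte-Carlo)
#'
#' Draws `n` joint realizations of every uncertain parameter from its fitted
#' distribution (independently across parameters; the same draw is shared by
#' all strategy arms within an iteration) and runs the full cohort model per
#' arm per draw. Iterations whose draw violates a structural constraint (an
#' inverted ranged pair) are resampled, up to 100 retries each, and the
#' retry count is recorded.
#'
#' @param params A [load_parameters()] result.
#' @param n Number of iterations, `>= 1`.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param strategies Arms to run; default all six.
#' @return A `psa_result`: list with `samples` (data.frame: `iteration`,
#'   `strategy`, `cost`, `qalys`), `draws` (matrix of sampled parameter
#'   values, one row per iteration), `n`, `seed`, `resampled` (count of
#'   redrawn iterations), and `wtp`.
#' @export
run_psa <- function(params, n, seed, strategies = NULL) {
  stopifnot(inherits(params, "parameter_set"), n >= 1)
  strategies <- strategies %||% strategy_labels()
  strategies <- match.arg(strategies, strategy_labels(), several.ok = TRUE)
  set.seed(as.integer(seed))

  reg <- param_registry(params)
  draws <- matrix(NA_real_, nrow = n, ncol = length(reg),
                  dimnames = list(NULL, names(reg)))
  k <- length(strategies)
  cost <- matrix(NA_real_, n, k, dimnames = list(NULL, strategies))
  qalys <- matrix(NA_real_, n, k, dimnames = list(NULL, strategies))
  resampled <- 0L

  for (i in seq_len(n)) {
    done <- FALSE
    for (try in seq_len(100L)) {
      rv <- realize_parameters(params, draw = TRUE)
      if (!rv_is_valid(rv)) { resampled <- resampled + 1L; next }
      # a draw can also fail structurally (competing risks past 1 at old
      # ages); such iterations are resampled too
      run <- tryCatch(
        lapply(strategies, function(s) run_cohort(params, s, rv = rv)),
        error = function(e) NULL)
      if (is.null(run)) { resampled <- resampled + 1L; next }
      draws[i, ] <- rv$values
      for (j in seq_along(strategies)) {
        cost[i, j] <- run[[j]]$cost
        qalys[i, j] <- run[[j]]$qalys
      }
      done <- TRUE
      break
    }
    if (!done) stop("iteration ", i, ": no valid draw in 100 retries")
  }

  samples <- data.frame(
    iteration = rep(seq_len(n), each = k),
    strategy = rep(strategies, times = n),
    cost = as.vector(t(cost)),
    qalys = as.vector(t(qalys)))
  structure(list(samples = samples, draws = draws, n = n,
                 seed = as.integer(seed), resampled = resampled,
                 strategies = strategies, cost = cost, qalys = qalys,
                 wtp = params$settings$wtp),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations x %d strategies (seed %d, %d redraws)\n",
              x$n, length(x$strategies), x$seed, x$resampled))
  m <- data.frame(strategy = x$strategies,
                  mean_cost = colMeans(x$cost),
                  mean_qalys = colMeans(x$qalys))
  print(m, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that each strategy is
#' the cost-effective choice: the fraction of PSA iterations in which it has
#' the strictly maximal net monetary benefit, with exact ties split equally.
#' Probabilities sum to 1 across strategies at every threshold.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Vector of thresholds (USD/QALY); the default spans 0 to
#'   60,000 in steps of 2,000 and always includes the configured threshold.
#' @return Data.frame with columns `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  wtp_grid <- wtp_grid %||% sort(unique(c(seq(0, 60000, by = 2000), psa$wtp)))
  if (!length(wtp_grid)) stop("empty wtp grid")
  k <- length(psa$strategies)
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * psa$qalys - psa$cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)      # ties split equally
    data.frame(wtp = w, strategy = psa$strategies,
               probability = colMeans(share))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cost-effectiveness-plane quadrant occupancy
#'
#' For a reference strategy versus each comparator, the fraction of PSA
#' iterations falling in each quadrant of the cost-effectiveness plane
#' (x = QALY difference, y = cost difference, reference minus comparator).
#' The southeast quadrant (more QALYs at lower cost) is where a dominant
#' intervention's cloud concentrates.
#'
#' @param psa A [run_psa()] result.
#' @param reference Reference strategy label (default `"polypill"`).
#' @return Data.frame with one row per comparator and columns `ne`, `se`,
#'   `sw`, `nw` summing to 1.
#' @export
quadrant_summary <- function(psa, reference = "polypill") {
  stopifnot(inherits(psa, "psa_result"))
  if (!reference %in% psa$strategies) stop("reference strategy not in the PSA")
  comps <- setdiff(psa$strategies, reference)
  rows <- lapply(comps, function(s) {
    dq <- psa$qalys[, reference] - psa$qalys[, s]
    dc <- psa$cost[, reference] - psa$cost[, s]
    data.frame(comparator = s,
               ne = mean(dq >= 0 & dc >= 0),
               se = mean(dq >= 0 & dc < 0),
               sw = mean(dq < 0 & dc < 0),
               nw = mean(dq < 0 & dc >= 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
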