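#' Present-value weight for a cycle
#'
#' @param rate Annual discount rate (e.g. 0.058 for costs, 0.03 for QALYs).
#' @param cycle Zero-based cycle index.
#' @return `(1 + rate)^(-cycle)`.
#' @export
#' @examples
#' discount_factor(0.058, 1)  # 0.94518
discount_factor <- function(rate, cycle) {
  if (any(rate < 0)) stop("discount rate must be non-negative")
  if (any(cycle < 0)) stop("cycle must be non-negative")
  (1 + rate)^(-cycle)
}

#' Linear age interpolation of a ranged input
#'
#' Inputs printed as a range over the adult age span (event risks, MI case
#' fatality) are interpolated linearly between their endpoints and clamped
#' outside `[age_lo, age_hi]`.
#'
#' @param age Age(s) in years; vectorised.
#' @param low,high Values at `age_lo` and `age_hi`; `low <= high` required.
#' @param age_lo,age_hi Span endpoints.
#' @return Interpolated value(s), clamped to `[low, high]`.
#' @export
#' @examples
#' interpolate_risk(60, 0.011, 0.094, 35, 85)  # 0.0525
interpolate_risk <- function(age, low, high, age_lo, age_hi) {
  if (low > high) stop("inverted range: low > high")
  if (age_lo >= age_hi) stop("inverted age span")
  f <- pmin(pmax((age - age_lo) / (age_hi - age_lo), 0), 1)
  low + f * (high - low)
}

#' Apply a relative treatment effect to an annual probability
#'
#' Both risk ratios and hazard ratios are applied on the constant-rate scale,
#' `1 - (1 - p)^effect`: exact for hazard ratios, and numerically close to a
#' multiplicative risk ratio at the small annual probabilities involved.
#'
#' @param p Annual event probability, in `[0, 1)` (1 allowed only with a null
#'   effect).
#' @param effect Relative effect (RR or HR), `> 0`.
#' @return Adjusted probability.
#' @export
#' @examples
#' apply_relative_effect(0.005, 0.43)  # 0.0021531
apply_relative_effect <- function(p, effect) {
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]")
  if (any(effect <= 0)) stop("effect must be positive")
  if (any(p == 1 & effect != 1)) stop("p = 1 is degenerate under a non-null effect")
  1 - (1 - p)^effect
}

#' Background mortality with a standardized mortality ratio
#'
#' Life-table annual death probability raised on the rate scale by the SMR of
#' a chronic disease state: `1 - (1 - qx)^smr` (never above 1).
#'
#' @param lt A [life_table][generate_life_table()].
#' @param age Age in years; must be covered by the table. Vectorised.
#' @param smr Standardized mortality ratio, `> 0`.
#' @return Annual death probability.
#' @export
#' @examples
#' lt <- generate_life_table(gompertz_spec(h35 = 0.01005034))  # qx(35) ~ 0.01
#' other_cause_mortality(lt, 35, 2.72)
other_cause_mortality <- function(lt, age, smr) {
  if (any(smr <= 0)) stop("smr must be positive")
  idx <- match(age, lt$age)
  if (anyNA(idx)) stop("age outside the life table: ",
                       paste(age[is.na(idx)], collapse = ", "))
  pmin(1 - (1 - lt$qx[idx])^smr, 1)
}

#' Case fatality of an incident event
#'
#' Probability that a first stroke, MI or heart-failure event is immediately
#' fatal (applied in the cycle of the event; the fatal share moves straight
#' to Dead). MI fatality is printed as sex-specific age ranges and is
#' interpolated over the configured age span; `sex = "blend"` mixes the two
#' sexes by the configured male fraction.
#'
#' @param event `"stroke"`, `"mi"` or `"hf"`.
#' @param age Age in years (vectorised; only MI fatality varies with age).
#' @param sex `"blend"` (default), `"male"` or `"female"`.
#' @param params A [load_parameters()] result.
#' @param rv Internal: a realized parameter list; defaults to base-case means.
#' @return Fatality probability (recycled to `length(age)`).
#' @export
#' @examples
#' ps <- load_parameters()
#' event_fatality("stroke", 50, params = ps)  # 0.19 at any age
#' event_fatality("mi", 60, sex = "male", params = ps)  # 0.275
event_fatality <- function(event, age, sex = c("blend", "male", "female"),
                           params, rv = NULL) {
  event <- match.arg(event, c("stroke", "mi", "hf"))
  sex <- match.arg(sex)
  if (is.null(rv)) rv <- realize_parameters(params)
  st <- params$settings
  if (event == "stroke") return(rep(rv$fatal_stroke, length(age)))
  if (event == "hf") return(rep(rv$fatal_hf, length(age)))
  span <- st$risk_age_span
  f_m <- interpolate_risk(age, rv$fatal_mi$men[1], rv$fatal_mi$men[2],
                          span[1], span[2])
  f_w <- interpolate_risk(age, rv$fatal_mi$women[1], rv$fatal_mi$women[2],
                          span[1], span[2])
  switch(sex,
         male = f_m, female = f_w,
         blend = st$sex_mix_male * f_m + (1 - st$sex_mix_male) * f_w)
}

# Transition array for all cycles of one strategy: 9 x 9 x T, T = number of
# annual cycles (ages start_age .. max_age). Structural topology: EventFree
# competes among the five first events (fatal/nonfatal split for stroke, HF,
# MI), other-cause death (SMR 1) and the treated disease-specific death;
# acute MI/angina are one-cycle tunnels feeding their post states; chronic
# states transition only to themselves or Dead; Dead absorbs.
transition_array <- function(rv, strategy, params) {
  st <- params$settings
  lt <- params$life_table
  ages <- st$start_age:st$max_age
  T <- length(ages)
  idx <- match(ages, lt$age)
  if (anyNA(idx)) stop("life table does not cover ages ",
                       paste(range(ages[is.na(idx)]), collapse = "-"))
  qx <- lt$qx[idx]
  span <- st$risk_age_span

  eff <- rv$eff[strategy, ]
  p_ev <- sapply(model_events(), function(e) {
    base <- interpolate_risk(ages, rv$risk["low", e], rv$risk["high", e],
                             span[1], span[2])
    1 - (1 - base)^eff[[e]]
  })
  f_mi <- event_fatality("mi", ages, "blend", params, rv)
  dd <- 1 - (1 - rv$disease_death)^rv$composite[[strategy]]

  to_dead_ef <- qx + dd +
    p_ev[, "stroke"] * rv$fatal_stroke +
    p_ev[, "hf"] * rv$fatal_hf +
    p_ev[, "mi"] * f_mi
  nonfatal <- cbind(stroke = p_ev[, "stroke"] * (1 - rv$fatal_stroke),
                    hf = p_ev[, "hf"] * (1 - rv$fatal_hf),
                    mi = p_ev[, "mi"] * (1 - f_mi),
                    angina = p_ev[, "angina"],
                    pvd = p_ev[, "pvd"])
  stay_ef <- 1 - to_dead_ef - rowSums(nonfatal)
  closed <- qx >= 1   # forced closure at the terminal age: certain death
  bad <- which(stay_ef < -1e-12 & !closed)
  if (length(bad))
    stop("competing risks exceed 1 in state EventFree at age ", ages[bad[1]])

  d_state <- sapply(model_events(), function(e)
    pmin(1 - (1 - qx)^rv$smr[[e]], 1))

  S <- health_states()
  P <- array(0, dim = c(9, 9, T), dimnames = list(S, S, ages))
  P["EventFree", "Stroke", ] <- nonfatal[, "stroke"]
  P["EventFree", "HF", ] <- nonfatal[, "hf"]
  P["EventFree", "AcuteMI", ] <- nonfatal[, "mi"]
  P["EventFree", "AcuteAngina", ] <- nonfatal[, "angina"]
  P["EventFree", "PVD", ] <- nonfatal[, "pvd"]
  P["EventFree", "Dead", ] <- to_dead_ef
  P["EventFree", "EventFree", ] <- stay_ef
  if (any(closed)) {
    P["EventFree", , closed] <- 0
    P["EventFree", "Dead", closed] <- 1
  }
  chronic <- c(Stroke = "stroke", HF = "hf", PostMI = "mi",
               PostAngina = "angina", PVD = "pvd")
  for (s in names(chronic)) {
    P[s, "Dead", ] <- d_state[, chronic[[s]]]
    P[s, s, ] <- 1 - d_state[, chronic[[s]]]
  }
  P["AcuteMI", "Dead", ] <- d_state[, "mi"]
  P["AcuteMI", "PostMI", ] <- 1 - d_state[, "mi"]
  P["AcuteAngina", "Dead", ] <- d_state[, "angina"]
  P["AcuteAngina", "PostAngina", ] <- 1 - d_state[, "angina"]
  P["Dead", "Dead", ] <- 1
  P
}

#' One-cycle transition matrix
#'
#' The row-stochastic transition matrix over the nine health states for one
#' age, one strategy arm, and one realized parameter set (base-case means by
#' default). Event probabilities are baseline risks under the strategy's
#' relative effects, split into fatal and nonfatal shares; the event-free
#' residual is whatever mass the competing transitions leave (rows are never
#' rescaled).
#'
#' @param age Age in years.
#' @param strategy Strategy label (see [strategy_labels()]).
#' @param params A [load_parameters()] result.
#' @param rv Internal: realized parameter list (e.g. one PSA draw).
#' @return A 9 x 9 matrix with rows summing to 1.
#' @export
#' @examples
#' P <- build_transition_matrix(35, "polypill", load_parameters())
#' rowSums(P)
build_transition_matrix <- function(age, strategy, params, rv = NULL) {
  strategy <- match.arg(strategy, strategy_labels())
  if (is.null(rv)) rv <- realize_parameters(params)
  st <- params$settings
  if (age < st$start_age || age > st$max_age)
    stop("age outside the model horizon")
  P <- transition_array(rv, strategy, params)
  P[, , as.character(age)]
}

#' Run the cohort model for one strategy arm
#'
#' Propagates a cohort entering 100 percent event-free at the start age
#' through annual cycles to the maximum age, applying the age-specific
#' transition matrices, and accumulates per-person discounted costs (state
#' costs plus annual medication cost in all alive states, discounted at the
#' cost rate) and QALYs (state utilities, discounted at the QALY rate).
#' Rewards use half-cycle correction by default: the average of start- and
#' end-of-cycle occupancy. Totals are per person; the configured cohort size
#' is a reporting multiplier only.
#'
#' @param params A [load_parameters()] result.
#' @param strategy Strategy label.
#' @param lt Optional life table overriding the one in `params`.
#' @param rv Internal: realized parameter list (one PSA draw).
#' @param half_cycle Override the config's half-cycle-correction switch.
#' @return A `strategy_result`: list with `strategy`, `cost` (USD/person),
#'   `qalys`, and the per-cycle `trace` data.frame.
#' @export
#' @examples
#' res <- run_cohort(load_parameters(), "polypill")
#' c(res$cost, res$qalys)
run_cohort <- function(params, strategy, lt = NULL, rv = NULL,
                       half_cycle = NULL) {
  strategy <- match.arg(strategy, strategy_labels())
  stopifnot(inherits(params, "parameter_set"))
  if (!is.null(lt)) params$life_table <- validate_life_table(lt)
  if (is.null(rv)) rv <- realize_parameters(params)
  st <- params$settings
  hcc <- if (is.null(half_cycle)) isTRUE(st$half_cycle_correction) else isTRUE(half_cycle)

  P <- transition_array(rv, strategy, params)
  T <- dim(P)[3]
  X <- matrix(0, nrow = T + 1, ncol = 9)
  X[1, 1] <- 1
  for (t in seq_len(T)) X[t + 1, ] <- X[t, ] %*% P[, , t]
  if (anyNA(X)) stop("occupancy produced NaN; invalid inputs")

  basis <- if (hcc) (X[1:T, , drop = FALSE] + X[2:(T + 1), , drop = FALSE]) / 2
           else X[1:T, , drop = FALSE]
  alive <- c(rep(1, 8), 0)
  cvec <- rv$state_cost + rv$drug_annual[[strategy]] * alive
  cycle_qaly <- as.vector(basis %*% rv$util)
  cycle_cost <- as.vector(basis %*% cvec)
  wq <- discount_factor(st$discount_qaly, 0:(T - 1))
  wc <- discount_factor(st$discount_cost, 0:(T - 1))

  occ <- X[1:T, , drop = FALSE]
  colnames(occ) <- health_states()
  trace <- data.frame(cycle = 0:(T - 1), age = st$start_age:st$max_age, occ,
                      cost = cycle_cost, cost_disc = cycle_cost * wc,
                      qaly = cycle_qaly, qaly_disc = cycle_qaly * wq,
                      check.names = FALSE)
  structure(list(strategy = strategy,
                 cost = sum(cycle_cost * wc),
                 qalys = sum(cycle_qaly * wq),
                 trace = trace),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: %.2f USD, %.4f QALYs (discounted, per person)\n",
              x$strategy, x$cost, x$qalys))
  invisible(x)
}

#' Run all (or selected) strategy arms on one parameter realization
#'
#' @param params A [load_parameters()] result.
#' @param strategies Character vector of arm labels; default all six.
#' @param rv Internal: realized parameter list shared across arms.
#' @param half_cycle Override the half-cycle-correction switch.
#' @return Data.frame with one row per arm: `strategy`, `cost`, `qalys`;
#'   the full `strategy_result` objects are in attribute `"results"`.
#' @export
run_strategies <- function(params, strategies = NULL, rv = NULL,
                           half_cycle = NULL) {
  strategies <- strategies %||% strategy_labels()
  strategies <- match.arg(strategies, strategy_labels(), several.ok = TRUE)
  if (anyDuplicated(strategies)) stop("duplicate strategy labels")
  if (is.null(rv)) rv <- realize_parameters(params)
  res <- lapply(strategies, function(s)
    run_cohort(params, s, rv = rv, half_cycle = half_cycle))
  out <- data.frame(strategy = strategies,
                    cost = vapply(res, `[[`, numeric(1), "cost"),
                    qalys = vapply(res, `[[`, numeric(1), "qalys"))
  attr(out, "results") <- stats::setNames(res, strategies)
  out
}
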