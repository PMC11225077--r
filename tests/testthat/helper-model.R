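# Shared fixtures, built in code.

# report every expectation; never abort the run early
testthat::set_max_fails(Inf)

# one shared base-case parameter set per test run
PSET <- polypillcea::load_parameters()

# flat life table: constant annual death probability q from age `start`,
# closing with qx = 1 at the terminal age
flat_life_table <- function(q, start = 35, years = 300) {
  ages <- start:(start + years)
  data.frame(age = ages, qx = c(rep(q, years), 1))
}

# strip the disease layer: no events, no disease-specific death, free drugs.
# What remains is a two-state alive/dead chain driven purely by the life table.
degenerate_pset <- function(q = 0.1, years = 300) {
  ps <- PSET
  for (e in polypillcea:::model_events()) {
    ps$baseline_risks[[e]]$low$mean <- 0
    ps$baseline_risks[[e]]$high$mean <- 0
  }
  ps$mortality$disease_specific_death$mean <- 0
  ps$settings$drug_cost_factor <- 0
  lt <- flat_life_table(q, years = years)
  ps$life_table <- polypillcea:::validate_life_table(lt)
  ps$settings$max_age <- max(lt$age)
  ps
}

# three-state chain (EventFree -> Stroke -> Dead) with constant inputs
three_state_pset <- function(p_stroke = 0.05, fatal = 0.2, smr = 2,
                             q = 0.02, eff = 0.5, years = 120) {
  ps <- degenerate_pset(q = q, years = years)
  ps$baseline_risks$stroke$low$mean <- p_stroke
  ps$baseline_risks$stroke$high$mean <- p_stroke
  ps$mortality$fatal_stroke$mean <- fatal
  ps$mortality$smr$stroke$mean <- smr
  for (s in names(ps$effects))
    for (e in polypillcea:::model_events()) {
      ps$effects[[s]][[e]]$mean <- 1
      ps$effects[[s]][[e]]$sd <- 0
    }
  ps$effects$aspirin$stroke$mean <- eff
  ps$settings$drug_cost_factor <- 1
  ps
}

# all uncertainty switched off: every spec becomes a point mass at its mean
point_mass_pset <- function() {
  ps <- PSET
  zero_sd <- function(x) {
    if (polypillcea:::is_dist_spec(x)) { x$sd <- 0; return(x) }
    if (is.list(x)) return(lapply(x, zero_sd))
    x
  }
  for (f in c("baseline_risks", "utilities", "state_costs", "drug_prices",
              "effects", "mortality"))
    ps[[f]] <- zero_sd(ps[[f]])
  ps
}

# brute-force cost-effectiveness frontier: a point survives iff no single
# other point nor any convex combination of two others is at least as
# effective for at most the same cost (strict somewhere)
oracle_frontier <- function(cost, qalys) {
  n <- length(cost)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (cost[j] <= cost[i] && qalys[j] >= qalys[i] &&
          (cost[j] < cost[i] || qalys[j] > qalys[i])) keep[i] <- FALSE
    }
    if (!keep[i]) next
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      if (qalys[j] <= qalys[i] && qalys[i] <= qalys[k] && qalys[j] < qalys[k]) {
        lam <- (qalys[k] - qalys[i]) / (qalys[k] - qalys[j])
        mix_cost <- lam * cost[j] + (1 - lam) * cost[k]
        if (mix_cost < cost[i]) keep[i] <- FALSE
      }
    }
  }
  which(keep)
}
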