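#' Load the full model input set from a config file
#'
#' Reads a YAML config mirroring the model's input table — baseline event
#' risks, state utilities, state costs, drug prices, relative treatment
#' effects, and mortality inputs — each paired with its uncertainty
#' distribution, plus the run settings (discount rates, willingness-to-pay
#' threshold, cohort settings, cost model). All invariants are checked at
#' load time: probabilities and utilities within `[0, 1]`, ranged inputs with
#' `low <= high`, positive costs. Effects a strategy does not list (printed
#' as a dash in the source table) default to a fixed ratio of 1.0 and are
#' recorded as notices, as are Beta inputs whose printed sd exceeds the
#' feasibility bound and will be capped at sampling time.
#'
#' @param config Path to the YAML config. The packaged base case is at
#'   `system.file("extdata", "basecase.yaml", package = "polypillcea")`.
#' @param life_table Optional [life_table] data.frame overriding the config's
#'   life-table choice.
#' @return An object of class `parameter_set`.
#' @export
#' @examples
#' ps <- load_parameters()
#' ps$baseline_risks$stroke$mean  # 0.005
load_parameters <- function(config = default_config_path(), life_table = NULL) {
  if (!file.exists(config)) stop("config file not found: ", config)
  raw <- yaml::read_yaml(config)
  required <- c("settings", "baseline_risks", "utilities", "state_costs",
                "drug_prices", "doses", "effects", "mortality", "life_table")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("config is missing required section(s): ", paste(missing, collapse = ", "))

  st <- raw$settings
  for (f in c("discount_cost", "discount_qaly", "wtp", "start_age", "max_age"))
    if (is.null(st[[f]])) stop("settings is missing required field: ", f)
  defaults <- list(cohort_size = 10000, cycle_length = 1,
                   risk_age_span = c(st$start_age, 85),
                   half_cycle_correction = TRUE, cost_model = "per_tablet_daily",
                   drug_cost_factor = 1, polypill_variant = "V",
                   lognormal_mean_is = "arithmetic", sex_mix_male = 0.5)
  for (f in names(defaults)) if (is.null(st[[f]])) st[[f]] <- defaults[[f]]
  st$risk_age_span <- as.numeric(unlist(st$risk_age_span))
  if (st$discount_cost < 0 || st$discount_qaly < 0)
    stop("discount rates must be non-negative")
  if (!st$cost_model %in% c("per_tablet_daily", "per_pack_monthly", "calibrated"))
    stop("unknown cost_model: ", st$cost_model)
  if (!st$polypill_variant %in% c("V", "E"))
    stop("polypill_variant must be 'V' or 'E'")

  mean_is <- st$lognormal_mean_is
  as_spec <- function(node, what) {
    if (is.null(node)) stop("missing input: ", what)
    for (f in c("mean", "sd")) if (is.null(node[[f]])) stop(what, " is missing field: ", f)
    sp <- tryCatch(
      dist_spec(node$dist, node$mean, node$sd, mean_is = mean_is),
      error = function(e) stop("invalid spec for ", what, ": ", conditionMessage(e)))
    if (!is.null(node$kind)) attr(sp, "kind") <- node$kind
    sp
  }
  ranged <- function(node, what) {
    if (!is.null(node$mean)) {
      sp <- as_spec(node, what)
      return(list(low = sp, high = sp))
    }
    out <- list(low = as_spec(node$low, paste0(what, ".low")),
                high = as_spec(node$high, paste0(what, ".high")))
    if (out$low$mean > out$high$mean)
      stop(what, ": ranged input has low > high (", out$low$mean, " > ", out$high$mean, ")")
    out
  }

  risks <- lapply(stats::setNames(model_events(), model_events()), function(e)
    ranged(raw$baseline_risks[[e]], paste0("baseline_risks.", e)))

  util_names <- c("stroke", "hf", "acute_mi", "post_mi", "acute_angina",
                  "post_angina", "pvd", "event_free")
  utilities <- lapply(stats::setNames(util_names, util_names), function(u) {
    sp <- as_spec(raw$utilities[[u]], paste0("utilities.", u))
    if (sp$mean < 0 || sp$mean > 1)
      stop("utilities.", u, " outside [0, 1]: ", sp$mean)
    sp
  })

  cost_names <- c("stroke", "hf", "acute_mi", "acute_angina", "pvd")
  state_costs <- lapply(stats::setNames(cost_names, cost_names), function(s)
    as_spec(raw$state_costs[[s]], paste0("state_costs.", s)))

  drug_prices <- lapply(raw$drug_prices, function(by_dose)
    lapply(by_dose, function(node) as_spec(node, "drug_prices")))

  notices <- character(0)
  effects <- list()
  for (s in setdiff(strategy_labels(), "valsartan")) {
    blk <- raw$effects[[s]]
    if (is.null(blk)) stop("effects block missing for strategy: ", s)
    effects[[s]] <- list()
    for (e in model_events()) {
      if (is.null(blk[[e]])) {
        sp <- dist_spec("fixed", 1, 0)
        attr(sp, "defaulted") <- TRUE
        notices <- c(notices, sprintf(
          "effect %s/%s not specified; defaulted to 1.0 (no effect)", s, e))
        effects[[s]][[e]] <- sp
      } else {
        effects[[s]][[e]] <- as_spec(blk[[e]], paste(s, e, sep = "."))
      }
    }
  }

  mt <- raw$mortality
  mortality <- list(
    fatal_stroke = as_spec(mt$fatal_stroke, "mortality.fatal_stroke"),
    fatal_hf = as_spec(mt$fatal_hf, "mortality.fatal_hf"),
    fatal_mi = list(men = ranged(mt$fatal_mi$men, "mortality.fatal_mi.men"),
                    women = ranged(mt$fatal_mi$women, "mortality.fatal_mi.women")),
    smr = lapply(stats::setNames(model_events(), model_events()), function(e)
      as_spec(mt$smr[[e]], paste0("mortality.smr.", e))),
    disease_specific_death = as_spec(mt$disease_specific_death,
                                     "mortality.disease_specific_death"))
  for (p in c("fatal_stroke", "fatal_hf"))
    if (mortality[[p]]$mean < 0 || mortality[[p]]$mean > 1)
      stop("mortality.", p, " outside [0, 1]")

  pset <- structure(list(
    settings = st,
    baseline_risks = risks, utilities = utilities, state_costs = state_costs,
    cost_components = raw$cost_components,
    drug_prices = drug_prices, doses = raw$doses,
    dose_fraction = raw$dose_fraction %||% list(),
    effects = effects, mortality = mortality,
    source = normalizePath(config)), class = "parameter_set")

  # life table: explicit argument > config file > synthetic Gompertz stand-in
  if (!is.null(life_table)) {
    pset$life_table <- validate_life_table(life_table)
  } else if (!is.null(raw$life_table$file)) {
    path <- raw$life_table$file
    if (!file.exists(path))
      path <- file.path(dirname(config), raw$life_table$file)
    pset$life_table <- read_life_table(path)
  } else {
    g <- raw$life_table$gompertz
    pset$life_table <- generate_life_table(gompertz_spec(
      le35 = g$le35 %||% 42,
      doubling_years = g$doubling_years %||% 8,
      terminal_age = g$terminal_age %||% st$max_age))
  }
  if (max(pset$life_table$age) < st$max_age)
    stop("life table ends at age ", max(pset$life_table$age),
         " but max_age is ", st$max_age)

  for (en in names(param_registry(pset))) {
    entry <- param_registry(pset)[[en]]
    if (entry$spec$family == "beta" && spec_is_capped(entry$spec))
      notices <- c(notices, sprintf(
        "parameter %s: printed sd %g infeasible for Beta(mean %g); sd capped at %g for sampling",
        en, entry$spec$sd, entry$spec$mean,
        attr(beta_from_moments(entry$spec$mean, entry$spec$sd), "sd_used")))
  }
  attr(pset, "notices") <- notices
  pset
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path of the packaged base-case config
#' @return File path of the YAML config shipped with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "basecase.yaml", package = "polypillcea")
}

#' @export
print.parameter_set <- function(x, ...) {
  st <- x$settings
  cat("<parameter_set>\n")
  cat(sprintf("  cohort: enters event-free at age %d, annual cycles to age %d\n",
              st$start_age, st$max_age))
  cat(sprintf("  discounting: %.1f%% (costs), %.1f%% (QALYs); WTP %s USD/QALY\n",
              100 * st$discount_cost, 100 * st$discount_qaly,
              format(st$wtp, big.mark = ",")))
  cat(sprintf("  cost model: %s; polypill variant %s\n", st$cost_model,
              st$polypill_variant))
  cat(sprintf("  %d scalar uncertain parameters; %d load notices\n",
              length(param_registry(x)), length(attr(x, "notices"))))
  invisible(x)
}

#' Plain-text validation report for a loaded parameter set
#'
#' Lists every notice recorded at load time: defaulted treatment effects and
#' Beta inputs whose printed sd exceeds the feasibility bound (capped at
#' sampling time), so divergences from the printed inputs are auditable.
#'
#' @param pset A [load_parameters()] result.
#' @param file Optional path; when given the report is also written there.
#' @return Character vector of report lines, invisibly when `file` is given.
#' @export
validation_report <- function(pset, file = NULL) {
  stopifnot(inherits(pset, "parameter_set"))
  lines <- c(sprintf("parameter set loaded from: %s", pset$source),
             sprintf("scalar uncertain parameters: %d", length(param_registry(pset))),
             "notices:",
             if (length(attr(pset, "notices"))) paste(" -", attr(pset, "notices"))
             else " - none")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

# Flat registry of every scalar uncertain parameter: id -> list(spec, type,
# and a poke() closure that writes a realized value into the rv skeleton).
# The registry order is fixed; PSA draws follow it, so runs are reproducible.
param_registry <- function(pset) {
  reg <- list()
  add <- function(id, spec, type) reg[[id]] <<- list(spec = spec, type = type)

  for (e in model_events()) {
    r <- pset$baseline_risks[[e]]
    if (identical(r$low, r$high)) {
      add(paste0("risk.", e), r$low, "prob")
    } else {
      add(paste0("risk.", e, ".low"), r$low, "prob")
      add(paste0("risk.", e, ".high"), r$high, "prob")
    }
  }
  for (u in setdiff(names(pset$utilities), "event_free"))
    add(paste0("utility.", u), pset$utilities[[u]], "prob")
  for (s in names(pset$state_costs))
    add(paste0("cost.", s), pset$state_costs[[s]], "cost")
  for (d in names(drug_selection(pset)))
    add(paste0("price.", d), drug_selection(pset)[[d]], "cost")
  for (s in names(pset$effects))
    for (e in model_events()) {
      sp <- pset$effects[[s]][[e]]
      if (!isTRUE(attr(sp, "defaulted")))
        add(paste0("effect.", s, ".", e), sp, "ratio")
    }
  add("fatal.stroke", pset$mortality$fatal_stroke, "prob")
  add("fatal.hf", pset$mortality$fatal_hf, "prob")
  add("fatal.mi.men.low", pset$mortality$fatal_mi$men$low, "prob")
  add("fatal.mi.men.high", pset$mortality$fatal_mi$men$high, "prob")
  add("fatal.mi.women.low", pset$mortality$fatal_mi$women$low, "prob")
  add("fatal.mi.women.high", pset$mortality$fatal_mi$women$high, "prob")
  for (e in model_events())
    add(paste0("smr.", e), pset$mortality$smr[[e]], "ratio")
  add("disease_death", pset$mortality$disease_specific_death, "prob")
  reg
}

# The price spec actually used by each arm (drug + selected dose); the
# valsartan arm shares the enalapril entry, and the polypill price follows
# the configured variant.
drug_selection <- function(pset) {
  st <- pset$settings
  sel <- list()
  for (d in c("atorvastatin", "hydrochlorothiazide", "aspirin", "enalapril")) {
    dose <- as.character(pset$doses[[d]])
    sp <- pset$drug_prices[[d]][[dose]]
    if (is.null(sp)) stop("no price entry for ", d, " dose ", dose)
    sel[[d]] <- sp
  }
  pp <- if (identical(st$polypill_variant, "E")) "polypill_e" else "polypill_v"
  sp <- pset$drug_prices[[pp]][["1"]]
  if (is.null(sp)) stop("no price entry for ", pp)
  sel[["polypill"]] <- sp
  sel
}

# Realize a concrete numeric parameter vector from the set: base-case means,
# a Monte-Carlo draw (draw = TRUE, uses the current RNG state), or means with
# named overrides (tornado). Returns the structured realized-value list the
# engine consumes, plus the flat vector under $values.
realize_parameters <- function(pset, draw = FALSE, overrides = NULL) {
  reg <- param_registry(pset)
  vals <- vapply(reg, function(e) e$spec$mean, numeric(1))
  if (draw)
    vals[] <- vapply(reg, function(e) sample_parameter(e$spec, 1), numeric(1))
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(vals))
    if (length(bad)) stop("unknown parameter id(s): ", paste(bad, collapse = ", "))
    vals[names(overrides)] <- unlist(overrides)
    # probabilities and utilities stay inside [0, 1] under perturbation
    is_prob <- vapply(reg, function(e) e$type == "prob", logical(1))
    vals[is_prob] <- pmin(pmax(vals[is_prob], 0), 1)
  }
  assemble_rv(pset, vals)
}

assemble_rv <- function(pset, vals) {
  v <- function(id) unname(vals[[id]])
  has <- function(id) id %in% names(vals)
  rng_or_scalar <- function(prefix) {
    if (has(paste0(prefix, ".low")))
      c(v(paste0(prefix, ".low")), v(paste0(prefix, ".high")))
    else rep(v(prefix), 2)
  }

  risk <- sapply(model_events(), function(e) rng_or_scalar(paste0("risk.", e)))
  rownames(risk) <- c("low", "high")

  states <- health_states()
  util <- stats::setNames(numeric(9), states)
  util["EventFree"] <- pset$utilities$event_free$mean
  util["Stroke"] <- v("utility.stroke"); util["HF"] <- v("utility.hf")
  util["AcuteMI"] <- v("utility.acute_mi"); util["PostMI"] <- v("utility.post_mi")
  util["AcuteAngina"] <- v("utility.acute_angina")
  util["PostAngina"] <- v("utility.post_angina")
  util["PVD"] <- v("utility.pvd"); util["Dead"] <- 0

  cost <- stats::setNames(numeric(9), states)
  cost["Stroke"] <- v("cost.stroke"); cost["HF"] <- v("cost.hf")
  cost["AcuteMI"] <- v("cost.acute_mi"); cost["AcuteAngina"] <- v("cost.acute_angina")
  cost["PVD"] <- v("cost.pvd")  # post-event MI/angina years carry no printed cost

  labs <- strategy_labels()
  eff <- matrix(1, nrow = length(labs), ncol = length(model_events()),
                dimnames = list(labs, model_events()))
  printed <- matrix(FALSE, nrow = length(labs), ncol = length(model_events()),
                    dimnames = list(labs, model_events()))
  for (s in names(pset$effects))
    for (e in model_events()) {
      id <- paste0("effect.", s, ".", e)
      if (has(id)) { eff[s, e] <- v(id); printed[s, e] <- TRUE }
    }
  eff["valsartan", ] <- eff["enalapril", ]          # no separate trial data
  printed["valsartan", ] <- printed["enalapril", ]

  composite <- vapply(labs, function(s) {
    p <- eff[s, printed[s, ]]
    if (!length(p)) 1 else exp(mean(log(p)))
  }, numeric(1))

  st <- pset$settings
  price <- vapply(names(drug_selection(pset)), function(d) v(paste0("price.", d)),
                  numeric(1))
  price["valsartan"] <- price[["enalapril"]]
  frac <- function(d) pset$dose_fraction[[d]] %||% 1
  drug_annual <- vapply(labs, function(s) {
    d <- if (s == "polypill") "polypill" else s
    annual_medication_cost(price[[d]], pack_size = 10, doses_per_day = 1,
                           cost_model = st$cost_model,
                           dose_fraction = frac(d),
                           factor = st$drug_cost_factor)
  }, numeric(1))

  list(
    risk = risk, util = util, state_cost = cost,
    eff = eff, printed = printed, composite = composite,
    fatal_stroke = v("fatal.stroke"), fatal_hf = v("fatal.hf"),
    fatal_mi = list(men = c(v("fatal.mi.men.low"), v("fatal.mi.men.high")),
                    women = c(v("fatal.mi.women.low"), v("fatal.mi.women.high"))),
    smr = vapply(model_events(), function(e) v(paste0("smr.", e)), numeric(1)),
    disease_death = v("disease_death"),
    drug_annual = drug_annual,
    values = vals)
}

# A drawn rv is invalid when a ranged pair came out inverted; the PSA
# resamples such iterations.
rv_is_valid <- function(rv) {
  all(rv$risk["low", ] <= rv$risk["high", ]) &&
    rv$fatal_mi$men[1] <= rv$fatal_mi$men[2] &&
    rv$fatal_mi$women[1] <= rv$fatal_mi$women[2] &&
    all(is.finite(rv$values))
}
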