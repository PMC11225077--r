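test_that("discounting, interpolation and effect application match closed forms", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.058, 1), 1 / 1.058, tolerance = 1e-12)
  expect_equal(discount_factor(0.03, 2), 1 / 1.0609, tolerance = 1e-12)
  expect_error(discount_factor(-0.01, 1))

  expect_equal(interpolate_risk(35, 0.011, 0.094, 35, 85), 0.011)
  expect_equal(interpolate_risk(60, 0.011, 0.094, 35, 85), 0.0525)
  expect_equal(interpolate_risk(85, 0.011, 0.094, 35, 85), 0.094)
  expect_equal(interpolate_risk(100, 0.011, 0.094, 35, 85), 0.094) # clamped
  expect_error(interpolate_risk(50, 0.5, 0.1, 35, 85))

  expect_equal(apply_relative_effect(0.005, 1), 0.005)
  expect_equal(apply_relative_effect(0.005, 0.43), 1 - 0.995^0.43,
               tolerance = 1e-12)
  expect_equal(apply_relative_effect(0.005, 0.43), 0.0021531, tolerance = 1e-4)
  expect_equal(apply_relative_effect(0, 0.43), 0)
  expect_error(apply_relative_effect(1, 0.43))
})

test_that("SMR mortality operates on the rate scale against the life table", {
  lt <- flat_life_table(0.01, years = 10)
  expect_equal(other_cause_mortality(lt, 36, 1), 0.01, tolerance = 1e-12)
  expect_equal(other_cause_mortality(lt, 36, 2.72), 1 - 0.99^2.72,
               tolerance = 1e-12)
  lt2 <- flat_life_table(0.6, years = 10)
  expect_equal(other_cause_mortality(lt2, 36, 2.72), 1 - 0.4^2.72,
               tolerance = 1e-12)
  expect_lt(other_cause_mortality(lt2, 36, 2.72), 1)
  expect_error(other_cause_mortality(lt, 200, 1), "outside")
})

test_that("case fatality is constant for stroke/HF and age-sex resolved for MI", {
  expect_equal(event_fatality("stroke", 47, params = PSET), 0.19)
  expect_equal(event_fatality("hf", 70, params = PSET), 0.17)
  expect_equal(event_fatality("mi", 35, sex = "male", params = PSET), 0.19)
  expect_equal(event_fatality("mi", 60, sex = "male", params = PSET), 0.275)
  expect_equal(event_fatality("mi", 85, sex = "female", params = PSET), 0.40)
  # blend is the configured mixture of the sexes
  expect_equal(event_fatality("mi", 60, params = PSET),
               0.5 * 0.275 + 0.5 * (0.23 + 0.40) / 2, tolerance = 1e-12)
  expect_error(event_fatality("pvd", 60, params = PSET))
})

test_that("transition matrices are row-stochastic with the model's topology", {
  S <- health_states()
  for (strat in c("polypill", "aspirin", "hydrochlorothiazide")) {
    for (age in c(35, 60, 85, 99, 100)) {
      P <- build_transition_matrix(age, strat, PSET)
      expect_equal(unname(rowSums(P)), rep(1, 9), tolerance = 1e-12)
      expect_true(all(P >= 0 & P <= 1))
      # tunnels: acute states feed only their post state or death
      expect_equal(sum(P["AcuteMI", c("PostMI", "Dead")]), 1, tolerance = 1e-12)
      expect_equal(sum(P["AcuteAngina", c("PostAngina", "Dead")]), 1,
                   tolerance = 1e-12)
      # chronic states only persist or die; no events between disease states
      for (s in c("Stroke", "HF", "PostMI", "PostAngina", "PVD"))
        expect_equal(sum(P[s, c(s, "Dead")]), 1, tolerance = 1e-12)
      expect_equal(P["Dead", "Dead"], 1)
    }
  }
})

test_that("event-free transitions compose baseline risk, effect and fatality", {
  P <- build_transition_matrix(35, "polypill", PSET)
  p_stroke <- apply_relative_effect(0.005, 0.43)
  expect_equal(P["EventFree", "Stroke"], p_stroke * (1 - 0.19),
               tolerance = 1e-12)
  p_mi <- apply_relative_effect(0.011, 0.66)
  f_mi <- event_fatality("mi", 35, params = PSET)
  expect_equal(P["EventFree", "AcuteMI"], p_mi * (1 - f_mi), tolerance = 1e-12)
  # angina and PVD carry no acute fatality
  expect_equal(P["EventFree", "AcuteAngina"],
               apply_relative_effect(0.015, 0.77), tolerance = 1e-12)
  expect_equal(P["EventFree", "PVD"], 0.007, tolerance = 1e-12)  # no effect
  # death collects background, disease-specific and fatal-event mass
  dd <- 1 - (1 - 0.015)^exp(mean(log(c(0.43, 0.83, 0.77, 0.66))))
  qx <- PSET$life_table$qx[PSET$life_table$age == 35]
  expect_equal(P["EventFree", "Dead"],
               qx + dd + p_stroke * 0.19 +
                 apply_relative_effect(0.004, 0.83) * 0.17 + p_mi * f_mi,
               tolerance = 1e-12)
})

test_that("a pure survival chain reproduces the discounted geometric series", {
  ps <- degenerate_pset(q = 0.1, years = 300)
  r <- run_cohort(ps, "polypill", half_cycle = FALSE)
  expect_equal(r$qalys, 1 / (1 - 0.9 / 1.03), tolerance = 1e-10)
  expect_equal(r$qalys, 7.9231, tolerance = 1e-4)
  expect_equal(r$cost, 0, tolerance = 1e-12)
  # ten guaranteed alive cycles at zero discount accrue ten QALYs
  ps2 <- degenerate_pset(q = 1e-12, years = 9)  # ages 35..44: ten cycles
  ps2$settings$discount_qaly <- 0
  r2 <- run_cohort(ps2, "polypill", half_cycle = FALSE)
  expect_equal(r2$qalys, sum((1 - 1e-12)^(0:9)) + 0, tolerance = 1e-9)
  expect_equal(r2$qalys, 10, tolerance = 1e-6)
})

test_that("the engine matches an independent scalar recursion on a 3-state chain", {
  p <- 0.05; f <- 0.2; smr <- 2; q <- 0.02; eff <- 0.5
  ps <- three_state_pset(p_stroke = p, fatal = f, smr = smr, q = q, eff = eff)
  for (hcc in c(TRUE, FALSE)) {
    r <- run_cohort(ps, "aspirin", half_cycle = hcc)
    # brute-force enumeration over cycles, written independently of the engine
    rv <- polypillcea:::realize_parameters(ps)
    u_stroke <- rv$util[["Stroke"]]
    c_stroke <- rv$state_cost[["Stroke"]]
    drug <- rv$drug_annual[["aspirin"]]
    T <- ps$settings$max_age - ps$settings$start_age + 1
    pe <- 1 - (1 - p)^eff
    d_stroke <- 1 - (1 - q)^smr
    ef <- 1; stk <- 0
    qaly <- cost <- 0
    for (t in 0:(T - 1)) {
      qt <- if (t == T - 1) 1 else q     # closure at the terminal age
      ef2 <- if (qt >= 1) 0 else ef * (1 - qt - pe)
      stk2 <- stk * (1 - (if (qt >= 1) 1 else d_stroke)) +
        (if (qt >= 1) 0 else ef * pe * (1 - f))
      w_ef <- if (hcc) (ef + ef2) / 2 else ef
      w_st <- if (hcc) (stk + stk2) / 2 else stk
      qaly <- qaly + (w_ef * 1 + w_st * u_stroke) * 1.03^(-t)
      cost <- cost + (w_ef * drug + w_st * (c_stroke + drug)) * 1.058^(-t)
      ef <- ef2; stk <- stk2
    }
    expect_equal(r$qalys, qaly, tolerance = 1e-10)
    expect_equal(r$cost, cost, tolerance = 1e-10)
  }
})

test_that("cohort mass is conserved and death is monotone in every arm", {
  for (s in strategy_labels()) {
    r <- run_cohort(PSET, s)
    occ <- as.matrix(r$trace[, health_states()])
    expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-12)
    expect_true(all(diff(r$trace$Dead) >= -1e-15))
    expect_true(r$cost >= 0 && r$qalys >= 0)
  }
})

test_that("uniform protective effects never reduce QALYs", {
  reg <- polypillcea:::param_registry(PSET)
  eff_ids <- grep("^effect\\.aspirin\\.", names(reg), value = TRUE)
  null_eff <- as.list(stats::setNames(rep(1, length(eff_ids)), eff_ids))
  prot_eff <- as.list(stats::setNames(rep(0.8, length(eff_ids)), eff_ids))
  r_null <- run_cohort(PSET, "aspirin",
                       rv = polypillcea:::realize_parameters(PSET, overrides = null_eff))
  r_prot <- run_cohort(PSET, "aspirin",
                       rv = polypillcea:::realize_parameters(PSET, overrides = prot_eff))
  expect_gte(r_prot$qalys, r_null$qalys)
})

test_that("totals fall as their own discount rate rises, and QALYs respect bounds", {
  base <- run_cohort(PSET, "polypill")
  ps_hi_q <- PSET; ps_hi_q$settings$discount_qaly <- 0.06
  ps_hi_c <- PSET; ps_hi_c$settings$discount_cost <- 0.10
  expect_lt(run_cohort(ps_hi_q, "polypill")$qalys, base$qalys)
  expect_lt(run_cohort(ps_hi_c, "polypill")$cost, base$cost)

  # discounted QALYs <= discounted life-years <= undiscounted life-years
  tr <- base$trace
  alive <- 1 - tr$Dead
  disc_ly <- sum(alive * discount_factor(0.03, tr$cycle))
  expect_lte(base$qalys, disc_ly + 1e-9)
  expect_lte(disc_ly, sum(alive) + 1e-9)
})
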