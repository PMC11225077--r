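test_that("tornado bars are sorted, and inert parameters have zero spread", {
  tb <- tornado(PSET, comparison = c("polypill", "atorvastatin"), delta = 0.2)
  expect_true(all(diff(abs(tb$spread)) <= 1e-9))
  # prices of drugs in neither compared arm cannot move the comparison
  for (p in c("price.aspirin", "price.enalapril", "price.hydrochlorothiazide"))
    expect_equal(tb$spread[tb$parameter == p], 0, tolerance = 1e-9)
  # prices of the compared arms do
  expect_gt(abs(tb$spread[tb$parameter == "price.polypill"]), 0)
  expect_equal(attr(tb, "comparison"), c("polypill", "atorvastatin"))
})

test_that("tornado with delta = 0 yields all-zero spreads", {
  tb <- tornado(PSET, comparison = c("polypill", "aspirin"), delta = 0)
  expect_true(all(abs(tb$spread) < 1e-9))
  expect_true(all(abs(tb$low - attr(tb, "base")) < 1e-9))
})

test_that("NMB responds linearly to a pure additive cost parameter", {
  t1 <- tornado(PSET, comparison = c("polypill", "aspirin"), delta = 0.2)
  t2 <- tornado(PSET, comparison = c("polypill", "aspirin"), delta = 0.1)
  for (p in c("cost.stroke", "cost.acute_mi", "price.polypill")) {
    s1 <- t1$spread[t1$parameter == p]
    s2 <- t2$spread[t2$parameter == p]
    expect_equal(s1, 2 * s2, tolerance = 1e-8)
  }
  # one-sided variant: low edge sits at the base outcome
  ti <- tornado(PSET, comparison = c("polypill", "aspirin"), delta = 0.2,
                sides = "increase")
  expect_true(all(ti$low == attr(ti, "base")))
})

test_that("identical arms make every tornado bar vanish", {
  tb <- tornado(PSET, comparison = c("enalapril", "valsartan"), delta = 0.2)
  expect_true(all(abs(tb$spread) < 1e-9))
})

test_that("the PSA is reproducible from its seed", {
  a <- run_psa(PSET, n = 3, seed = 11, strategies = c("polypill", "aspirin"))
  b <- run_psa(PSET, n = 3, seed = 11, strategies = c("polypill", "aspirin"))
  expect_identical(a$samples, b$samples)
  expect_identical(a$draws, b$draws)
  c <- run_psa(PSET, n = 3, seed = 12, strategies = c("polypill", "aspirin"))
  expect_false(identical(a$samples, c$samples))
})

test_that("PSA draws recover the post-capping input moments", {
  psa <- run_psa(PSET, n = 400, seed = 5, strategies = "polypill")
  checks <- list(
    utility.stroke = c(0.63, 0.95 * sqrt(0.63 * 0.37)),  # capped sd
    cost.stroke = c(1215.5, 1350),
    effect.polypill.stroke = c(0.43, 0.23),
    smr.mi = c(2.68, 1.54))
  for (id in names(checks)) {
    m <- checks[[id]][1]; s <- checks[[id]][2]
    expect_lt(abs(mean(psa$draws[, id]) - m), 4 * s / sqrt(400))
  }
  expect_true(all(psa$draws[, "utility.stroke"] >= 0 &
                  psa$draws[, "utility.stroke"] <= 1))
  expect_true(all(psa$samples$cost >= 0))
  expect_true(all(psa$samples$qalys >= 0))
})

test_that("PSA collapses to the deterministic base case when all sds vanish", {
  ps0 <- point_mass_pset()
  psa <- run_psa(ps0, n = 2, seed = 1, strategies = c("polypill", "aspirin"))
  det <- run_strategies(ps0, strategies = c("polypill", "aspirin"))
  for (s in c("polypill", "aspirin")) {
    expect_equal(unique(psa$cost[, s]), det$cost[det$strategy == s],
                 tolerance = 1e-12)
    expect_equal(unique(psa$qalys[, s]), det$qalys[det$strategy == s],
                 tolerance = 1e-12)
  }
})

test_that("CEAC probabilities are a proper partition at every threshold", {
  psa <- run_psa(PSET, n = 60, seed = 9)
  cc <- ceac(psa, wtp_grid = c(0, 10000, 21768, 50000))
  sums <- as.numeric(tapply(cc$probability, cc$wtp, sum))
  expect_equal(sums, rep(1, 4), tolerance = 1e-12)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # at wtp = 0 the NMB rule reduces to lowest cost
  at0 <- cc[cc$wtp == 0, ]
  cheapest_share <- sapply(psa$strategies, function(s) {
    wins <- psa$cost == apply(psa$cost, 1, min)
    mean(wins[, s] / rowSums(wins))
  })
  expect_equal(at0$probability, unname(cheapest_share[at0$strategy]),
               tolerance = 1e-12)
  # default grid includes the configured threshold
  cc_def <- ceac(psa)
  expect_true(21768 %in% cc_def$wtp)
})

test_that("degenerate CEAC geometries behave", {
  solo <- run_psa(PSET, n = 5, seed = 3, strategies = "polypill")
  cs <- ceac(solo, wtp_grid = c(0, 21768))
  expect_true(all(cs$probability == 1))
  # an arm with maximal NMB in every iteration has a flat curve at 1
  fake <- structure(list(
    strategies = c("a", "b"), n = 4, wtp = 21768,
    cost = cbind(a = rep(1, 4), b = rep(100, 4)),
    qalys = cbind(a = rep(2, 4), b = rep(1, 4))), class = "psa_result")
  cf <- ceac(fake, wtp_grid = c(0, 1000, 50000))
  expect_true(all(cf$probability[cf$strategy == "a"] == 1))
  expect_true(all(cf$probability[cf$strategy == "b"] == 0))
})

test_that("quadrant fractions partition the cost-effectiveness plane", {
  psa <- run_psa(PSET, n = 40, seed = 21)
  qs <- quadrant_summary(psa, reference = "polypill")
  expect_setequal(qs$comparator, setdiff(strategy_labels(), "polypill"))
  expect_equal(rowSums(qs[, c("ne", "se", "sw", "nw")]),
               rep(1, nrow(qs)), tolerance = 1e-12, ignore_attr = TRUE)
  # identical draws concentrate in a single quadrant
  fake <- structure(list(
    strategies = c("a", "b"), n = 3, wtp = 21768,
    cost = cbind(a = rep(5, 3), b = rep(9, 3)),
    qalys = cbind(a = rep(2, 3), b = rep(1, 3))), class = "psa_result")
  qf <- quadrant_summary(fake, reference = "a")
  expect_equal(qf$se, 1)  # more QALYs, lower cost
  expect_error(quadrant_summary(psa, reference = "nope"))
})
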