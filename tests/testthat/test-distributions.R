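test_that("beta method-of-moments recovers the printed fatal-stroke moments", {
  p <- beta_from_moments(0.19, 0.12)
  # frozen from nu = m(1-m)/sd^2 - 1
  expect_equal(p$alpha, 1.840625, tolerance = 1e-6)
  expect_equal(p$beta, 7.846875, tolerance = 1e-6)
  expect_false(attr(p, "capped"))
  # analytic moments round-trip
  expect_equal(p$alpha / (p$alpha + p$beta), 0.19, tolerance = 1e-9)
  v <- p$alpha * p$beta / ((p$alpha + p$beta)^2 * (p$alpha + p$beta + 1))
  expect_equal(sqrt(v), 0.12, tolerance = 1e-9)
})

test_that("uniform moments give the flat beta", {
  p <- beta_from_moments(0.5, sqrt(1 / 12))
  expect_equal(p$alpha, 1, tolerance = 1e-9)
  expect_equal(p$beta, 1, tolerance = 1e-9)
})

test_that("infeasible beta sd is capped, flagged, and capping is idempotent", {
  # stroke utility: sd^2 = 0.3136 > 0.63 * 0.37 = 0.2331
  expect_gt(0.56^2, 0.63 * 0.37)
  p <- beta_from_moments(0.63, 0.56)
  expect_true(attr(p, "capped"))
  sd_used <- attr(p, "sd_used")
  expect_equal(sd_used, 0.95 * sqrt(0.63 * 0.37), tolerance = 1e-12)
  # mean preserved; re-fitting with the capped sd changes nothing
  expect_equal(p$alpha / (p$alpha + p$beta), 0.63, tolerance = 1e-9)
  p2 <- beta_from_moments(0.63, sd_used)
  expect_false(attr(p2, "capped"))
  expect_equal(p2$alpha, p$alpha, tolerance = 1e-12)
  expect_equal(p2$beta, p$beta, tolerance = 1e-12)
})

test_that("beta fitting rejects out-of-domain means", {
  expect_error(beta_from_moments(1.2, 0.1))
  expect_error(beta_from_moments(0, 0.1))
  expect_error(beta_from_moments(0.5, 0))
})

test_that("gamma method-of-moments matches the printed cost rows", {
  p <- gamma_from_moments(136.7, 112)   # HF medication cost
  expect_equal(p$shape, 136.7^2 / 112^2, tolerance = 1e-12)
  expect_equal(p$scale, 112^2 / 136.7, tolerance = 1e-12)
  expect_equal(p$shape, 1.4897, tolerance = 1e-4)
  expect_equal(p$scale, 91.76, tolerance = 1e-3)

  p2 <- gamma_from_moments(1215.5, 1350)  # stroke annual cost
  expect_equal(p2$shape, 0.8106, tolerance = 1e-4)
  expect_equal(p2$scale, 1499.4, tolerance = 1e-4)

  # equal mean and sd is the exponential
  for (m in c(0.5, 42.85, 11461.6))
    expect_equal(gamma_from_moments(m, m)$shape, 1, tolerance = 1e-12)
  expect_error(gamma_from_moments(-1, 1))
})

test_that("lognormal fit treats the printed ratio as its arithmetic mean", {
  p <- lognormal_from_moments(0.43, 0.23)  # polypill stroke HR
  expect_equal(p$sigma, 0.5016, tolerance = 1e-4)
  expect_equal(p$mu, -0.9698, tolerance = 1e-4)
  # null effect with no spread is a point mass at 1
  p1 <- lognormal_from_moments(1.0, 0)
  expect_equal(p1$mu, 0)
  expect_equal(p1$sigma, 0)
  # statin stroke RR
  p2 <- lognormal_from_moments(0.80, 0.6)
  expect_equal(p2$sigma^2, log(1.5625), tolerance = 1e-9)
  expect_equal(p2$mu, log(0.8) - log(1.5625) / 2, tolerance = 1e-9)
  # median convention keeps mu = log(printed value)
  p3 <- lognormal_from_moments(0.80, 0.6, mean_is = "median")
  expect_equal(p3$mu, log(0.8), tolerance = 1e-12)
  expect_error(lognormal_from_moments(0, 0.1))
})

test_that("moment fits round-trip analytically for random feasible inputs", {
  set.seed(101)
  for (rep in 1:25) {
    m <- runif(1, 0.02, 0.98)
    sd <- runif(1, 0.01, 0.99) * sqrt(m * (1 - m))
    p <- beta_from_moments(m, sd)
    expect_equal(p$alpha / (p$alpha + p$beta), m, tolerance = 1e-9)
    v <- p$alpha * p$beta / ((p$alpha + p$beta)^2 * (p$alpha + p$beta + 1))
    expect_equal(sqrt(v), sd, tolerance = 1e-9)

    mg <- runif(1, 1, 5000); sg <- runif(1, 0.1, 2) * mg
    g <- gamma_from_moments(mg, sg)
    expect_equal(g$shape * g$scale, mg, tolerance = 1e-9)
    expect_equal(sqrt(g$shape) * g$scale, sg, tolerance = 1e-9)

    ml <- runif(1, 0.1, 2); sl <- runif(1, 0.05, 1.5) * ml
    l <- lognormal_from_moments(ml, sl)
    expect_equal(exp(l$mu + l$sigma^2 / 2), ml, tolerance = 1e-9)
    expect_equal(sqrt((exp(l$sigma^2) - 1) * exp(2 * l$mu + l$sigma^2)), sl,
                 tolerance = 1e-9)
  }
})

test_that("sampling recovers the target moments", {
  rng <- rng_stream(7, "moments")
  x <- sample_parameter(dist_spec("beta", 0.19, 0.12), n = 1e5, rng = rng)
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(mean(x), 0.19, tolerance = 0.002 / 0.19)
  # million-draw check, 4 standard errors
  y <- sample_parameter(dist_spec("gamma", 1215.5, 1350), n = 1e6,
                        rng = rng_stream(7, "gamma"))
  expect_true(all(y > 0))
  expect_lt(abs(mean(y) - 1215.5), 4 * 1350 / sqrt(1e6))
})

test_that("fixed specs and identical streams are deterministic", {
  expect_identical(sample_parameter(dist_spec("fixed", 871), n = 3),
                   rep(871, 3))
  a <- sample_parameter(dist_spec("lognormal", 0.66, 0.53), n = 10,
                        rng = rng_stream(3, "x"))
  b <- sample_parameter(dist_spec("lognormal", 0.66, 0.53), n = 10,
                        rng = rng_stream(3, "x"))
  c <- sample_parameter(dist_spec("lognormal", 0.66, 0.53), n = 10,
                        rng = rng_stream(3, "y"))
  expect_identical(a, b)
  expect_false(identical(a, c))
})
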