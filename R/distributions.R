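#' Distribution specification for an uncertain model input
#'
#' Every uncertain input is described by its distribution family together with
#' its mean and standard deviation on the natural scale (probability, utility,
#' USD, or ratio). Method-of-moments fitting converts the (mean, sd) pair into
#' the family's native parameters at sampling time.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param mean Mean on the natural scale. For `beta`, must lie in `[0, 1]`;
#'   for `gamma` and `lognormal`, must be positive.
#' @param sd Standard deviation on the same scale; `>= 0`. A zero sd (or the
#'   `fixed` family) makes the parameter deterministic.
#' @param mean_is For `lognormal` only: whether the printed mean is the
#'   `"arithmetic"` mean of the ratio (default) or its `"median"`.
#' @return An object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("beta", 0.19, 0.12)   # a case-fatality probability
#' dist_spec("gamma", 1215.5, 1350) # an annual cost in USD
dist_spec <- function(family = c("beta", "gamma", "lognormal", "fixed"),
                      mean, sd = 0, mean_is = c("arithmetic", "median")) {
  family <- match.arg(family)
  mean_is <- match.arg(mean_is)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd < 0) stop("sd must be non-negative")
  if (family == "beta" && (mean < 0 || mean > 1))
    stop("beta family requires mean in [0, 1], got ", mean)
  if (family %in% c("gamma", "lognormal") && mean <= 0)
    stop(family, " family requires mean > 0, got ", mean)
  structure(list(family = family, mean = mean, sd = sd, mean_is = mean_is),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(mean = %g, sd = %g)\n", x$family, x$mean, x$sd))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Fit a Beta distribution by the method of moments
#'
#' Solves for the shape parameters whose mean and sd match the inputs:
#' `nu = mean (1 - mean) / sd^2 - 1`, `alpha = mean nu`, `beta = (1 - mean) nu`.
#' The pair is feasible only when `sd^2 < mean (1 - mean)`; several published
#' utility inputs violate this bound, so an infeasible sd is capped at
#' `cap * sqrt(mean (1 - mean))` (default cap 0.95), the fit proceeds with the
#' capped sd, and the result is flagged via the `"capped"` attribute. Capping
#' is idempotent: re-fitting with the capped sd reproduces the same parameters.
#'
#' @param mean Mean probability, strictly inside (0, 1).
#' @param sd Standard deviation, `> 0`.
#' @param cap Fraction of the feasibility bound used when `sd` is infeasible.
#' @return A list with elements `alpha` and `beta` (class `beta_params`);
#'   attribute `capped` is `TRUE` when the sd had to be reduced, and attribute
#'   `sd_used` records the sd actually fitted.
#' @export
#' @examples
#' beta_from_moments(0.19, 0.12)   # fatal-stroke probability
#' beta_from_moments(0.5, sqrt(1 / 12)) # the uniform distribution
beta_from_moments <- function(mean, sd, cap = 0.95) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta_from_moments requires mean strictly inside (0, 1), got ", mean)
  if (!is.finite(sd) || sd <= 0)
    stop("beta_from_moments requires sd > 0, got ", sd)
  bound <- sqrt(mean * (1 - mean))
  capped <- FALSE
  if (sd >= bound) {
    sd <- cap * bound
    capped <- TRUE
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  structure(list(alpha = mean * nu, beta = (1 - mean) * nu),
            capped = capped, sd_used = sd, class = "beta_params")
}

#' Fit a Gamma distribution by the method of moments
#'
#' `shape = mean^2 / sd^2`, `scale = sd^2 / mean`. Used for all cost inputs.
#'
#' @param mean Mean (USD), `> 0`.
#' @param sd Standard deviation, `> 0`.
#' @return A list with elements `shape` and `scale` (class `gamma_params`).
#' @export
#' @examples
#' gamma_from_moments(136.7, 112) # annual HF medication cost
gamma_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0)
    stop("gamma_from_moments requires mean > 0, got ", mean)
  if (!is.finite(sd) || sd <= 0)
    stop("gamma_from_moments requires sd > 0, got ", sd)
  structure(list(shape = mean^2 / sd^2, scale = sd^2 / mean),
            class = "gamma_params")
}

#' Fit a log-normal distribution by the method of moments
#'
#' Used for relative-effect (RR/HR) inputs. By default the printed value is
#' read as the arithmetic mean of the ratio:
#' `sigma^2 = log(1 + sd^2 / mean^2)`, `mu = log(mean) - sigma^2 / 2`.
#' With `mean_is = "median"` the printed value is taken as the median, so
#' `mu = log(mean)` with the same `sigma`.
#'
#' @param mean Printed ratio, `> 0`.
#' @param sd Standard deviation on the ratio scale, `>= 0`.
#' @param mean_is `"arithmetic"` (default) or `"median"`.
#' @return A list with elements `mu` and `sigma` (class `lognormal_params`).
#' @export
#' @examples
#' lognormal_from_moments(0.43, 0.23) # polypill hazard ratio for stroke
lognormal_from_moments <- function(mean, sd, mean_is = c("arithmetic", "median")) {
  mean_is <- match.arg(mean_is)
  if (!is.finite(mean) || mean <= 0)
    stop("lognormal_from_moments requires mean > 0, got ", mean)
  if (!is.finite(sd) || sd < 0)
    stop("lognormal_from_moments requires sd >= 0, got ", sd)
  sigma2 <- log(1 + sd^2 / mean^2)
  mu <- if (mean_is == "arithmetic") log(mean) - sigma2 / 2 else log(mean)
  structure(list(mu = mu, sigma = sqrt(sigma2)), class = "lognormal_params")
}

#' Was a Beta fit's standard deviation capped?
#'
#' @param spec A `dist_spec`.
#' @param cap Cap fraction passed through to [beta_from_moments()].
#' @return `TRUE` if the spec is a Beta whose printed sd exceeds the
#'   feasibility bound `sqrt(mean (1 - mean))`.
#' @export
spec_is_capped <- function(spec, cap = 0.95) {
  stopifnot(is_dist_spec(spec))
  if (spec$family != "beta" || spec$sd == 0) return(FALSE)
  if (spec$mean <= 0 || spec$mean >= 1) return(FALSE)
  isTRUE(attr(beta_from_moments(spec$mean, spec$sd, cap = cap), "capped"))
}

#' Draw from a fitted distribution
#'
#' Fits the spec's family by the method of moments and returns `n` random
#' draws. A `fixed` family, a zero sd, or a degenerate Beta mean of exactly
#' 0 or 1 returns the mean itself (a point mass). Draws respect the family's
#' support: beta in `[0, 1]`, gamma and lognormal positive.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param rng Optional [rng_stream()]; when supplied, draws come from a
#'   reproducible stream keyed by the stream's seed and label, and the global
#'   RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' sample_parameter(dist_spec("fixed", 871), n = 3)
#' sample_parameter(dist_spec("beta", 0.19, 0.12), n = 5,
#'                  rng = rng_stream(1, "demo"))
sample_parameter <- function(spec, n = 1, rng = NULL) {
  stopifnot(is_dist_spec(spec))
  draw <- function() {
    if (spec$family == "fixed" || spec$sd == 0) return(rep(spec$mean, n))
    switch(spec$family,
      beta = {
        if (spec$mean <= 0 || spec$mean >= 1) return(rep(spec$mean, n))
        p <- beta_from_moments(spec$mean, spec$sd)
        stats::rbeta(n, p$alpha, p$beta)
      },
      gamma = {
        p <- gamma_from_moments(spec$mean, spec$sd)
        stats::rgamma(n, shape = p$shape, scale = p$scale)
      },
      lognormal = {
        p <- lognormal_from_moments(spec$mean, spec$sd, spec$mean_is)
        stats::rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
      })
  }
  if (is.null(rng)) draw() else with_rng_stream(rng, draw())
}

#' Reproducible random-number stream
#'
#' A labelled stream derived from a base seed: the same `(seed, label)` pair
#' always yields the same draw sequence, and distinct labels give effectively
#' independent streams.
#'
#' @param seed Integer base seed.
#' @param label Short text naming the stream.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed, label = "default") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(seed = as.integer(seed), label = as.character(label)),
            class = "rng_stream")
}

# deterministic 31-bit sub-seed from (seed, label)
stream_seed <- function(stream) {
  h <- sum(utf8ToInt(stream$label) * seq_along(utf8ToInt(stream$label)))
  as.integer((abs(stream$seed) * 48271 + h * 16807) %% (.Machine$integer.max - 1L)) + 1L
}

# evaluate expr under the stream's seed, restoring the caller's RNG state
with_rng_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(stream_seed(stream))
  expr
}
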