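#' Gompertz specification for a synthetic life table
#'
#' The national life table used by the analysis is not publicly reprinted, so
#' the package generates a deterministic stand-in with Gompertz mortality:
#' the all-cause hazard at age `x` is `h(x) = h35 * 2^((x - 35) / doubling)`,
#' giving the log-linear hazard increase typical of adult mortality. The
#' baseline hazard is either given directly (`h35`) or calibrated so that
#' further life expectancy at age 35 hits a target (`le35`, default 42
#' additional years, plausible for the Iranian population around 2020). The
#' table is a documented synthetic stand-in, not a national statistic.
#'
#' @param h35 Annual mortality hazard at age 35. Ignored when `le35` is given.
#' @param le35 Target further life expectancy at age 35, in years.
#' @param doubling_years Hazard doubling time in years of age; must be finite
#'   and positive (the hazard must increase with age).
#' @param terminal_age Last age of the table; its death probability is forced
#'   to 1 so the table closes.
#' @return An object of class `gompertz_spec`.
#' @export
#' @examples
#' gompertz_spec(le35 = 42)
#' gompertz_spec(h35 = 0.001)
gompertz_spec <- function(h35 = NULL, le35 = NULL, doubling_years = 8,
                          terminal_age = 100) {
  if (!is.finite(doubling_years) || doubling_years <= 0)
    stop("doubling_years must be positive: the hazard must increase with age")
  if (is.null(h35) && is.null(le35))
    stop("give either h35 or a target le35")
  slope <- log(2) / doubling_years
  if (!is.null(le35)) {
    stopifnot(le35 > 0, le35 < terminal_age - 35)
    f <- function(h) {
      lt <- life_table_from_hazard(h, slope, terminal_age)
      life_expectancy(lt, 35) - le35
    }
    h35 <- stats::uniroot(f, c(1e-6, 0.2), tol = 1e-12)$root
  }
  if (h35 <= 0) stop("baseline hazard must be positive")
  structure(list(h35 = h35, log_slope = slope, terminal_age = terminal_age),
            class = "gompertz_spec")
}

life_table_from_hazard <- function(h35, slope, terminal_age) {
  age <- 35:terminal_age
  h <- h35 * exp(slope * (age - 35))
  qx <- 1 - exp(-h)
  qx[length(qx)] <- 1
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Generate the synthetic life table
#'
#' Deterministic: annual death probabilities `qx = 1 - exp(-h(age))` with a
#' Gompertz hazard, ages 35 to the terminal age, and `qx = 1` at the terminal
#' age. `qx` is non-decreasing by construction.
#'
#' @param spec A [gompertz_spec()].
#' @return A `life_table`: data.frame with columns `age` and `qx`.
#' @export
#' @examples
#' lt <- generate_life_table(gompertz_spec(h35 = 0.001))
#' lt$qx[1]  # 1 - exp(-0.001)
generate_life_table <- function(spec = gompertz_spec(le35 = 42)) {
  stopifnot(inherits(spec, "gompertz_spec"))
  life_table_from_hazard(spec$h35, spec$log_slope, spec$terminal_age)
}

validate_life_table <- function(lt) {
  lt <- as.data.frame(lt)
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table needs columns age and qx")
  lt <- lt[order(lt$age), c("age", "qx")]
  if (any(diff(lt$age) != 1)) stop("life-table ages must be contiguous 1-year steps")
  if (any(lt$qx <= 0 | lt$qx > 1)) stop("life-table qx must lie in (0, 1]")
  if (lt$qx[nrow(lt)] != 1) stop("life-table qx at the terminal age must be 1")
  structure(lt, class = c("life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expected columns: `age` (1-year steps) and `qx` (annual death probability,
#' in (0, 1], equal to 1 at the terminal age). An optional `sex` column with
#' values `m`/`f` selects rows when `sex` is given.
#'
#' @param path CSV file path.
#' @param sex Optional, `"m"` or `"f"`, used when the file carries both.
#' @return A `life_table` data.frame.
#' @export
read_life_table <- function(path, sex = NULL) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(sex) && "sex" %in% names(lt)) lt <- lt[lt$sex == sex, ]
  validate_life_table(lt)
}

#' Write a life table to CSV
#' @param lt A `life_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

#' Life expectancy implied by a life table
#'
#' Further life expectancy at `age`, computed from the survival curve by the
#' trapezoid rule (half-year credit in the year of death).
#'
#' @param lt A `life_table`.
#' @param age Age at which to evaluate; defaults to the table's first age.
#' @return Expected further years of life.
#' @export
life_expectancy <- function(lt, age = min(lt$age)) {
  if (age < min(lt$age) || age > max(lt$age)) stop("age outside the life table")
  qx <- lt$qx[lt$age >= age]
  surv <- cumprod(1 - qx)
  sum(surv) + 0.5
}

#' Age-resolved baseline event-risk profiles
#'
#' Expands the baseline annual first-event risks into a per-age table:
#' stroke and heart failure are constant, while MI, angina and PVD are
#' interpolated linearly between their printed range endpoints over the
#' configured age span (default 35-85), clamped outside it.
#'
#' @param pset A [load_parameters()] result.
#' @return Data.frame with columns `age`, `stroke`, `hf`, `mi`, `angina`, `pvd`.
#' @export
#' @examples
#' rp <- generate_risk_profiles(load_parameters())
#' rp[rp$age == 35, ]  # range left endpoints
generate_risk_profiles <- function(pset) {
  stopifnot(inherits(pset, "parameter_set"))
  st <- pset$settings
  ages <- st$start_age:st$max_age
  rv <- realize_parameters(pset)
  out <- data.frame(age = ages)
  for (e in model_events())
    out[[e]] <- interpolate_risk(ages, rv$risk["low", e], rv$risk["high", e],
                                 st$risk_age_span[1], st$risk_age_span[2])
  out
}

#' Write a complete, loadable fixture config
#'
#' Copies the packaged base-case config (and materialises its synthetic life
#' table as CSV next to it), optionally jittering the means of all uncertain
#' inputs by a relative amount for stress-test fixtures. With `jitter = 0`
#' the output is byte-identical across seeds.
#'
#' @param path Output path for the YAML config.
#' @param seed Integer seed controlling the optional jitter only.
#' @param jitter Relative half-width of the uniform jitter on means
#'   (e.g. `0.1` for +/-10 percent); 0 disables it.
#' @param template Config to start from; defaults to the packaged base case.
#' @return `path`, invisibly.
#' @export
make_fixture_config <- function(path, seed = 1L, jitter = 0,
                                template = default_config_path()) {
  raw <- yaml::read_yaml(template)
  if (jitter > 0) {
    rng <- rng_stream(seed, "fixture-jitter")
    jit <- function(node) {
      if (is.list(node)) {
        if (!is.null(node$mean) && !is.null(node$dist) &&
            node$dist %in% c("beta", "gamma", "lognormal")) {
          f <- 1 + stats::runif(1, -jitter, jitter)
          m <- node$mean * f
          if (node$dist == "beta") m <- min(max(m, 1e-6), 1 - 1e-6)
          node$mean <- m
        } else {
          node[] <- lapply(node, jit)
        }
      }
      node
    }
    raw <- with_rng_stream(rng, jit(raw))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(raw, path)
  # materialise the life table the config implies, for tools that want the CSV
  g <- raw$life_table$gompertz
  if (is.null(raw$life_table$file) && !is.null(g)) {
    lt <- generate_life_table(gompertz_spec(le35 = g$le35 %||% 42,
                                            doubling_years = g$doubling_years %||% 8,
                                            terminal_age = g$terminal_age %||% 100))
    write_life_table(lt, file.path(dirname(path), "life_table_synthetic.csv"))
  }
  invisible(path)
}
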