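# Output assembly for the three analysis commands: each writes plain CSVs,
# a validation report, and a run manifest into its output directory.

write_manifest <- function(pset, output_dir, seed = NA, extra = list()) {
  man <- c(list(
    config = pset$source,
    config_md5 = unname(tools::md5sum(pset$source)),
    seed = seed,
    package_version = as.character(utils::packageVersion("polypillcea")),
    capped_or_defaulted = as.list(attr(pset, "notices")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  yaml::write_yaml(man, file.path(output_dir, "manifest.yaml"))
  invisible(man)
}

prepare_output <- function(output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  output_dir
}

#' Base-case run: incremental analysis and cohort traces
#'
#' Loads the config, runs every requested arm deterministically at the
#' base-case means, and writes `results.csv` (the incremental analysis),
#' one `trace_<arm>.csv` per arm, `validation.txt` and `manifest.yaml`.
#'
#' @param config Path to the model config; defaults to the packaged base case.
#' @param strategies Optional subset of arm labels.
#' @param output_dir Output directory (created if needed).
#' @return The incremental-analysis data.frame, invisibly; also attached are
#'   the raw per-arm results (attribute `"results"`).
#' @export
cmd_run <- function(config = default_config_path(), strategies = NULL,
                    output_dir = "polypill_run") {
  pset <- load_parameters(config)
  res <- run_strategies(pset, strategies = strategies)
  inc <- incremental_analysis(res)
  prepare_output(output_dir)
  utils::write.csv(inc, file.path(output_dir, "results.csv"), row.names = FALSE)
  for (r in attr(res, "results"))
    utils::write.csv(r$trace, file.path(output_dir,
                                        paste0("trace_", r$strategy, ".csv")),
                     row.names = FALSE)
  validation_report(pset, file.path(output_dir, "validation.txt"))
  write_manifest(pset, output_dir, extra = list(command = "run"))
  attr(inc, "results") <- attr(res, "results")
  invisible(inc)
}

#' Tornado run: one-way sensitivity outputs
#'
#' @param config Path to the model config.
#' @param delta Relative variation (default 0.2).
#' @param outcome `"nmb"` or `"icer"`.
#' @param comparison Two strategy labels; see [tornado()].
#' @param sides `"both"` or `"increase"`.
#' @param output_dir Output directory.
#' @return The tornado data.frame, invisibly.
#' @export
cmd_tornado <- function(config = default_config_path(), delta = 0.2,
                        outcome = "nmb", comparison = NULL, sides = "both",
                        output_dir = "polypill_tornado") {
  pset <- load_parameters(config)
  bars <- tornado(pset, comparison = comparison, delta = delta,
                  outcome = outcome, sides = sides)
  prepare_output(output_dir)
  utils::write.csv(bars, file.path(output_dir, "tornado.csv"), row.names = FALSE)
  ggplot2::ggsave(file.path(output_dir, "tornado.pdf"), plot_tornado(bars),
                  width = 7, height = 5)
  validation_report(pset, file.path(output_dir, "validation.txt"))
  write_manifest(pset, output_dir, extra = list(
    command = "tornado", delta = delta, outcome = outcome,
    comparison = as.list(attr(bars, "comparison")),
    top_parameters = as.list(utils::head(bars$parameter, 2))))
  message("largest bars: ", paste(utils::head(bars$parameter, 2), collapse = ", "))
  invisible(bars)
}

#' PSA run: Monte-Carlo samples, CEAC and plane outputs
#'
#' @param config Path to the model config.
#' @param n Number of PSA iterations.
#' @param seed Integer seed (required; the run is reproducible from it).
#' @param wtp_grid Thresholds for the acceptability curve; the default grid
#'   includes the configured threshold.
#' @param strategies Optional subset of arm labels.
#' @param output_dir Output directory.
#' @return The `psa_result`, invisibly.
#' @export
cmd_psa <- function(config = default_config_path(), n = 5000, seed,
                    wtp_grid = NULL, strategies = NULL,
                    output_dir = "polypill_psa") {
  if (missing(seed)) stop("seed is required for a PSA run")
  pset <- load_parameters(config)
  psa <- run_psa(pset, n = n, seed = seed, strategies = strategies)
  curves <- ceac(psa, wtp_grid)
  quads <- quadrant_summary(psa, reference = psa$strategies[1])
  prepare_output(output_dir)
  utils::write.csv(psa$samples, file.path(output_dir, "psa.csv"), row.names = FALSE)
  utils::write.csv(curves, file.path(output_dir, "ceac.csv"), row.names = FALSE)
  utils::write.csv(quads, file.path(output_dir, "quadrants.csv"), row.names = FALSE)
  ggplot2::ggsave(file.path(output_dir, "ce_plane.pdf"),
                  plot_ce_plane(psa, reference = psa$strategies[1]),
                  width = 8, height = 6)
  ggplot2::ggsave(file.path(output_dir, "ceac.pdf"),
                  plot_ceac(curves, wtp = pset$settings$wtp),
                  width = 7, height = 5)
  validation_report(pset, file.path(output_dir, "validation.txt"))
  write_manifest(pset, output_dir, seed = seed, extra = list(
    command = "psa", n = n, resampled = psa$resampled))
  invisible(psa)
}

#' Fixture generation command
#'
#' Writes a complete, loadable config (optionally jittered) plus its
#' synthetic life table; see [make_fixture_config()].
#'
#' @param output_dir Output directory.
#' @param seed Seed controlling the optional jitter.
#' @param jitter Relative jitter half-width on means; 0 for an exact copy.
#' @return Path of the written config, invisibly.
#' @export
cmd_fixtures <- function(output_dir = "polypill_fixtures", seed = 1L,
                         jitter = 0) {
  prepare_output(output_dir)
  invisible(make_fixture_config(file.path(output_dir, "config.yaml"),
                                seed = seed, jitter = jitter))
}
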