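#' Run the full analysis pipeline
#'
#' Executes the requested analyses in order -- base case, deterministic
#' sensitivity, probabilistic sensitivity, scenario -- and writes CSV
#' and JSON tables, figures and a run log to the output directory.
#' Every output table carries its units (GBP, QALYs, months) in the
#' header row; the run log records the package version, seed, input
#' hash and every placeholder-valued parameter used.
#'
#' @param inputs A [cua_inputs()] bundle, or the path of a YAML/JSON
#'   input document (loaded through [read_inputs()]).
#' @param output_dir Output directory, created if absent.
#' @param analyses Subset of `c("base", "dsa", "psa", "scenario")`.
#' @param psa_iterations Monte-Carlo iterations for the PSA.
#' @param seed Integer seed; required when the PSA is requested.
#' @param scenario Named override list for the scenario analysis;
#'   defaults to [scenario_procedure_times()].
#' @param plots Write figure files (PNG) alongside the tables.
#' @return Invisibly, a list with the computed objects (`outcomes`,
#'   `increment`, `tornado`, `psa`, `ceac`, `scenario`) and the paths
#'   written.
#' @export
run_pipeline <- function(inputs, output_dir,
                         analyses = c("base", "dsa", "psa", "scenario"),
                         psa_iterations = 1000, seed = NULL,
                         scenario = scenario_procedure_times(),
                         plots = TRUE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if ("psa" %in% analyses && is.null(seed)) {
    stop("`seed` is required when the PSA is requested", call. = FALSE)
  }
  input_path <- NULL
  if (is.character(inputs)) {
    input_path <- inputs
    inputs <- read_inputs(inputs)
  }
  validate_inputs(inputs)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  results <- list()
  log_lines <- c(
    sprintf("stentcua %s", as.character(utils::packageVersion("stentcua"))),
    sprintf("run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", if (is.null(seed)) "none" else seed),
    if (!is.null(input_path)) sprintf(
      "input: %s (md5 %s)", input_path, unname(tools::md5sum(input_path))))

  placeholders <- names(Filter(
    function(pv) pv$provenance %in% c("placeholder", "synthetic"),
    flatten_params(inputs)))
  if (length(placeholders)) {
    msg <- paste("placeholder-valued parameters in use:",
                 paste(placeholders, collapse = ", "))
    warning("cost outputs rest on placeholder values: ",
            paste(placeholders, collapse = ", "), call. = FALSE)
    log_lines <- c(log_lines, msg)
  }

  emit_csv <- function(df, name, units) {
    p <- file.path(output_dir, paste0(name, ".csv"))
    con <- file(p, "w")
    writeLines(paste0("# units: ", units), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    paths <<- c(paths, p)
  }
  emit_plot <- function(gg, name) {
    if (!plots) return(invisible())
    p <- file.path(output_dir, paste0(name, ".png"))
    ggplot2::ggsave(p, gg, width = 7, height = 5, dpi = 150)
    paths <<- c(paths, p)
  }

  if ("base" %in% analyses) {
    outcomes <- compare_strategies(inputs)
    results$outcomes <- outcomes
    emit_csv(as.data.frame(outcomes), "outcomes",
             "horizon: months; cost/nmb: GBP; qalys: QALYs; lys: years; stents: count")
    jsonlite::write_json(
      as.list(as.data.frame(outcomes)),
      file.path(output_dir, "outcomes.json"), auto_unbox = FALSE, digits = NA)
    paths <- c(paths, file.path(output_dir, "outcomes.json"))
    inc <- increment_over_time(inputs)
    results$increment <- inc
    emit_csv(inc, "increment_over_time",
             "month: months; delta_cost: GBP (discounted, cumulative)")
    emit_plot(plot_increment_over_time(inc), "increment_over_time")
    # per-strategy cohort traces with discount factors
    for (nm in names(inputs$strategies)) {
      tr <- run_cohort(inputs, nm)
      tr$discount_factor <- discount_factor(
        tr$cycle, inputs$settings$discount_rate_annual)
      emit_csv(tr, paste0("trace_", nm),
               "cycle: months; occupancies: proportions; events: expected counts")
    }
  }
  if ("dsa" %in% analyses) {
    tornado <- dsa_univariate(inputs)
    results$tornado <- tornado
    emit_csv(as.data.frame(tornado), "tornado",
             "delta_cost/nmb: GBP at the largest reporting horizon")
    emit_plot(plot_tornado(tornado, "delta_cost"), "tornado_cost")
    emit_plot(plot_tornado(tornado, "nmb"), "tornado_nmb")
  }
  if ("psa" %in% analyses) {
    psa <- psa_run(inputs, n = psa_iterations, seed = seed)
    results$psa <- psa
    emit_csv(psa$samples, "psa_samples",
             "probabilities: per month; utilities: per year; costs/delta_cost/nmb: GBP; delta_qalys: QALYs")
    cc <- ceac(psa)
    results$ceac <- cc
    emit_csv(cc, "ceac", "wtp: GBP/QALY; p_cost_effective: proportion")
    emit_plot(plot_ce_plane(psa), "ce_plane")
    emit_plot(plot_ceac(cc), "ceac")
    log_lines <- c(log_lines,
                   sprintf("psa: %d iterations, %d invalid draw(s) redrawn",
                           psa_iterations, psa$rejections))
  }
  if ("scenario" %in% analyses) {
    sc <- scenario_apply(inputs, scenario)
    results$scenario <- sc
    emit_csv(as.data.frame(sc), "scenario_outcomes",
             "horizon: months; cost/nmb: GBP; qalys: QALYs; lys: years; stents: count")
    log_lines <- c(log_lines, paste(
      "scenario overrides:",
      paste(names(scenario), unlist(scenario), sep = "=", collapse = "; ")))
  }

  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  results$paths <- c(paths, log_path)
  invisible(results)
}
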