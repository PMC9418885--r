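#' Configure an end-to-end simulation/analysis run
#'
#' @param scenarios character vector of force-spectroscopy preset names
#'   (see [list_force_presets()]).
#' @param n_curves curves per scenario batch (400 per
#'   sample is the customary batch size).
#' @param seed master seed; every stage derives its sub-seeds from it.
#' @param min_force,min_thickness rupture detection gates (nN, nm).
#' @param force_tolerance relative tolerance on the recovered mean final
#'   rupture force used for the per-batch pass flag.
#' @param step_tolerance absolute tolerance on the mean step count.
#' @param out_dir optional output directory for CSV/JSON/text reports.
#' @return a list of class `run_config`.
#' @export
run_config <- function(scenarios = list_force_presets(), n_curves = 400,
                       seed = 1, min_force = 0.1, min_thickness = 0.1,
                       force_tolerance = 0.05, step_tolerance = 0.1,
                       out_dir = NULL) {
  if (n_curves < 1) abort("n_curves must be >= 1")
  known <- list_force_presets()
  bad <- setdiff(scenarios, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown scenario(s): %s", paste(bad, collapse = ", ")))
  }
  structure(list(scenarios = scenarios, n_curves = n_curves, seed = seed,
                 min_force = min_force, min_thickness = min_thickness,
                 force_tolerance = force_tolerance,
                 step_tolerance = step_tolerance, out_dir = out_dir),
            class = "run_config")
}

# load a run configuration from a YAML file; flags in `override` win
#' @rdname run_config
#' @param path YAML file with `run_config` fields.
#' @param override named list of fields overriding the file.
#' @export
read_run_config <- function(path, override = list()) {
  cfg <- yaml::read_yaml(path)
  cfg <- modifyList(cfg, override)
  do.call(run_config, cfg)
}

#' Run the full simulate-analyse-summarise pipeline
#'
#' For every configured scenario: generate a batch of synthetic approach
#' curves with known truth, run detection/classification, summarise, and
#' compare the recovered statistics (mean final rupture force, mean step
#' count) to the generator truth. Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @param verbose log one structured line per stage?
#' @return an object of class `run_report`: list with `batches` (one row
#'   per scenario: recovered vs truth, deltas, pass flags), `summaries`,
#'   `events` (all classified events with scenario), `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$scenarios) == 0) {
    warn("no scenarios configured: empty report")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  batches <- list()
  events <- list()
  summaries <- list()
  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[i]
    seed_i <- sub_seed(config$seed, 1000L + i)
    preset <- force_preset(sc)
    say("[simulate] scenario=%s n=%d seed=%d", sc, config$n_curves, seed_i)
    gen <- gen_curve_batch(preset, config$n_curves, seed_i)
    say("[analyze-fs] scenario=%s min_force=%g min_thickness=%g",
        sc, config$min_force, config$min_thickness)
    batch <- analyze_curves(gen$curves, min_force = config$min_force,
                            min_thickness = config$min_thickness,
                            setpoint_warn = FALSE)
    smry <- summarize_curves(batch)
    truth_events <- map(gen$truth, "events")
    truth_final <- map_dbl(truth_events, function(e) {
      if (nrow(e) == 0) NA_real_ else e$rupture_force_nN[nrow(e)]
    })
    truth_steps <- map_int(truth_events, nrow)
    d_force <- smry$mean_final_rupture_force_nN - mean(truth_final, na.rm = TRUE)
    d_steps <- smry$mean_step_count - mean(truth_steps)
    batches[[i]] <- tibble(
      scenario = sc, n_curves = config$n_curves, seed = seed_i,
      mean_final_force_nN = smry$mean_final_rupture_force_nN,
      truth_mean_final_force_nN = mean(truth_final, na.rm = TRUE),
      delta_force_nN = d_force,
      mean_step_count = smry$mean_step_count,
      truth_mean_step_count = mean(truth_steps),
      delta_step_count = d_steps,
      force_ok = abs(d_force) <=
        config$force_tolerance * mean(truth_final, na.rm = TRUE),
      steps_ok = abs(d_steps) <= config$step_tolerance)
    summaries[[i]] <- mutate(smry, scenario = sc, .before = 1)
    if (nrow(batch$events) > 0) {
      events[[i]] <- mutate(batch$events, scenario = sc, .before = 1)
    }
    say("[summarize] scenario=%s events=%d mean_force=%.3f", sc,
        smry$n_events, smry$mean_final_rupture_force_nN)
  }
  report <- structure(
    list(batches = bind_rows(batches), summaries = bind_rows(summaries),
         events = bind_rows(events), config = config,
         config_hash = config_hash(config)),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  # small rolling hash; provenance marker, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Persist a run report as CSV + JSON + readable text
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$batches, file.path(dir, "batches.csv"))
  readr::write_csv(report$summaries, file.path(dir, "summaries.csv"))
  if (nrow(report$events) > 0) {
    readr::write_csv(
      select(report$events, "scenario", "curve_id",
             force_nN = "rupture_force_nN", thickness_nm = "thickness_nm",
             dplyr::any_of("label")),
      file.path(dir, "force_thickness_map.csv"))
  }
  jsonlite::write_json(
    list(config = unclass(report$config), config_hash = report$config_hash,
         batches = report$batches),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d scenario batch(es), config %s\n",
              nrow(x$batches), x$config_hash))
  if (nrow(x$batches) > 0) {
    print(select(x$batches, "scenario", "mean_final_force_nN",
                 "truth_mean_final_force_nN", "mean_step_count",
                 "truth_mean_step_count", "force_ok", "steps_ok"))
  }
  invisible(x)
}
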