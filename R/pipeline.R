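#' Reproducible pipeline runner
#'
#' Executes one named pipeline command from a configuration (an R list, or
#' a path to a JSON or YAML file), writes its output tables to the output
#' directory, and records a provenance manifest (`manifest.json`) holding
#' the full configuration, the run seed, the package version, and MD5
#' checksums of every input and output file. Two runs with the same
#' configuration and seed produce bit-identical outputs.
#'
#' Commands and their parameter blocks:
#' \describe{
#'   \item{make-synthetic}{generates `tuning_curves.csv`,
#'     `conductances.csv`, `rates.csv`, and `eye_trace.csv` from the
#'     synthetic-data module; block `synthetic` passes arguments through to
#'     [make_population()], [make_conductance_set()],
#'     [make_grating_rates()], and [make_eye_trace()].}
#'   \item{make-mosaic}{writes `positions.csv`; block `mosaic` passes
#'     through to [generate_mosaics()].}
#'   \item{drp}{reads `positions.csv` (config `input`), writes `drp.csv`;
#'     block `drp` passes through to [density_recovery_profile()].}
#'   \item{predict-okr}{reads `tuning_curves.csv` (config `input`), writes
#'     `predictions.csv`; block `predict` passes through to
#'     [predict_bar_conditions()].}
#'   \item{analyze-eye}{reads `eye_trace.csv` (config `input`), detects and
#'     removes saccades, writes `okr_summary.csv`; block `eye` passes
#'     thresholds to [detect_saccades()] and a `stimulus` sub-block to
#'     [make_stimulus()].}
#' }
#'
#' @param config list or path to a JSON/YAML config file. Required fields:
#'   `command`, `seed`, `out_dir`; plus the command's parameter block.
#' @return list with `outputs` (paths) and `manifest` (the manifest list),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  for (field in c("command", "seed", "out_dir")) {
    if (is.null(config[[field]])) {
      stop("configuration is missing required field '", field, "'")
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  inputs <- character(0)
  outputs <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  switch(config$command,
    "make-synthetic" = {
      blk <- config$synthetic %||% list()
      pop <- do.call(make_population,
                     c(pick(blk, names(formals(make_population))),
                       list(seed = seed)))
      write_table(population_to_table(pop), out("tuning_curves.csv"),
                  "tuning_curves")
      set <- do.call(make_conductance_set,
                     c(pick(blk, names(formals(make_conductance_set))),
                       list(seed = seed)))
      write_table(conductance_set_to_table(set), out("conductances.csv"),
                  "conductances")
      stim <- make_stimulus("oscillating")
      rates <- do.call(make_grating_rates,
                       c(list(stim = stim),
                         pick(blk, names(formals(make_grating_rates))),
                         list(seed = seed)))
      write_table(rates_to_table(rates), out("rates.csv"), "rates")
      tr <- do.call(make_eye_trace,
                    c(list(stim = stim),
                      pick(blk, names(formals(make_eye_trace))),
                      list(seed = seed)))
      write_table(eye_trace_to_table(tr), out("eye_trace.csv"), "eye_trace")
      outputs <- c(out("tuning_curves.csv"), out("conductances.csv"),
                   out("rates.csv"), out("eye_trace.csv"))
    },
    "make-mosaic" = {
      blk <- config$mosaic %||% list()
      field <- do.call(generate_mosaics,
                       c(pick(blk, names(formals(generate_mosaics))),
                         list(seed = seed)))
      write_table(field$positions, out("positions.csv"), "positions")
      outputs <- out("positions.csv")
    },
    "drp" = {
      if (is.null(config$input)) stop("'drp' requires config field 'input'")
      inputs <- config$input
      df <- read_table(config$input, "positions")
      blk <- config$drp %||% list()
      prof <- do.call(density_recovery_profile,
                      c(list(field = as.matrix(df[c("x_um", "y_um")])),
                        pick(blk, c("bin_um", "max_um", "edge_correction",
                                    "retina_radius_um"))))
      utils::write.csv(prof$profile, out("drp.csv"), row.names = FALSE)
      outputs <- out("drp.csv")
    },
    "predict-okr" = {
      if (is.null(config$input)) stop("'predict-okr' requires config field 'input'")
      inputs <- config$input
      pop <- table_to_population(read_table(config$input, "tuning_curves"))
      blk <- config$predict %||% list()
      dists <- response_distributions(pop, mode = blk$mode %||% "cell")
      pred <- predict_bar_conditions(dists,
                                     n_boot = blk$n_boot %||% 10000,
                                     seed = seed)
      df <- pred$conditions
      df$ordering <- NA
      df$ordering[seq_along(pred$orderings)] <- unname(pred$orderings)
      utils::write.csv(df, out("predictions.csv"), row.names = FALSE)
      outputs <- out("predictions.csv")
    },
    "analyze-eye" = {
      if (is.null(config$input)) stop("'analyze-eye' requires config field 'input'")
      inputs <- config$input
      df <- read_table(config$input, "eye_trace")
      trace <- eye_trace(df$time_s, df$theta_deg)
      blk <- config$eye %||% list()
      stim <- do.call(make_stimulus, blk$stimulus %||% list(kind = "oscillating"))
      iv <- detect_saccades(trace,
                            vel_thresh = blk$vel_thresh %||% 50,
                            acc_thresh = blk$acc_thresh %||% 2000)
      des <- remove_saccades(trace, iv)
      gn <- slow_phase_gain(des, stim)
      st <- nystagmus_stats(trace, stim, intervals = iv,
                            subtract_drift = isTRUE(blk$subtract_drift))
      summ <- data.frame(
        stage = c("superior", "inferior"),
        gain = c(gn$median_gain[["superior"]], gn$median_gain[["inferior"]]),
        fast_rate_hz = c(st$fast_rate_hz[["superior"]],
                         st$fast_rate_hz[["inferior"]]),
        slow_distance_deg = st$slow_distance_deg,
        drift_deg_s = st$drift_deg_s)
      utils::write.csv(summ, out("okr_summary.csv"), row.names = FALSE)
      outputs <- out("okr_summary.csv")
    },
    stop("unknown command: ", config$command)
  )

  manifest <- list(
    command = config$command, seed = seed, config = config,
    package_version = as.character(utils::packageVersion("retinokr")),
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(outputs = outputs, manifest = manifest))
}

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# keep only list entries whose names match `allowed` (drops seed: supplied
# explicitly by the runner)
pick <- function(blk, allowed) {
  blk[intersect(setdiff(names(blk), "seed"), allowed)]
}
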