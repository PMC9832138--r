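#' Read a circuit configuration file
#'
#' Builds a [circuit_params()] (or [fourvar_params()] when the file sets
#' `model: fourvar`) from a YAML or JSON configuration whose keys mirror the
#' parameter field names (`tau_NMDA`, `g_E_rec_NMDA`, `gamma_EE`, `nu0_I`,
#' ...). An optional `schedule` block (`t_pre`, `t_stim`, `t_post`) is
#' returned as attribute `schedule`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `circuit_params` or `fourvar_params` object.
#' @export
read_circuit_config <- function(path) {
  abort_if(!file.exists(path), paste0("config file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  schedule <- NULL
  if (!is.null(cfg$schedule)) {
    schedule <- do.call(trial_schedule, cfg$schedule)
    cfg$schedule <- NULL
  }
  model <- cfg$model %||% "twovar"
  cfg$model <- NULL
  params <- if (identical(model, "fourvar")) {
    do.call(fourvar_params, cfg)
  } else {
    do.call(circuit_params, cfg)
  }
  attr(params, "schedule") <- schedule
  params
}

#' Write a circuit configuration file
#'
#' @param params A `circuit_params` or `fourvar_params` object.
#' @param path Output path (`.yaml` or `.json` by extension).
#' @param schedule Optional [trial_schedule()] stored as a `schedule` block.
#' @return `path`, invisibly.
#' @export
write_circuit_config <- function(params, path, schedule = NULL) {
  cfg <- unclass(params)
  cfg$gain_E <- unname(cfg$gain_E)
  if (!is.null(cfg$gain_I)) cfg$gain_I <- unname(cfg$gain_I)
  cfg$model <- if (inherits(params, "fourvar_params")) "fourvar" else "twovar"
  if (!is.null(schedule)) {
    cfg$schedule <- schedule[c("t_pre", "t_stim", "t_post")]
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

#' Write a trajectory to CSV with a JSON manifest
#'
#' The trajectory table goes to `<stem>.csv` (header
#' `time,S1,S2,rE1,rE2,rI1,rI2,Ieta1,Ieta2`) and the trial metadata (seed,
#' stimulus, schedule, parameter hash) to `<stem>.json`.
#'
#' @param traj An `mf_trajectory`.
#' @param stem Output path without extension.
#' @return The CSV path, invisibly.
#' @export
write_trajectory <- function(traj, stem) {
  stopifnot(inherits(traj, "mf_trajectory"))
  csv <- paste0(stem, ".csv")
  utils::write.csv(as.data.frame(traj), csv, row.names = FALSE)
  stim <- attr(traj, "stim")
  sched <- attr(traj, "schedule")
  manifest <- list(
    seed = attr(traj, "seed"),
    params_hash = attr(traj, "params_hash"),
    stimulus = stim[c("coherence", "mu", "t_on", "t_off")],
    schedule = sched[c("t_pre", "t_stim", "t_post")],
    n_rows = nrow(traj)
  )
  jsonlite::write_json(manifest, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csv)
}
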