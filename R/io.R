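# Trial-table dialect: comma-separated, header row, UTF-8, '.' decimal.
.trial_columns <- c("observer_id", "experiment", "session", "block",
                    "trial", "head_posture", "head_roll_deg",
                    "distractor_orientation_deg", "fixation_shift",
                    "ring_eccentricity_deg", "target_location",
                    "target_tilt_direction", "contrast", "correct",
                    "gaze_dev_deg")

#' Write a trial table to CSV
#'
#' @param trials trial table (one row per trial).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  stopifnot(is.data.frame(trials))
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads a comma-separated trial table and validates the columns the
#' pipeline needs.  `correct` is coerced to logical.
#'
#' @param path CSV file path.
#' @param required columns that must be present (defaults to the full
#'   trial-record layout).
#' @return data.frame of trials.
#' @export
read_trial_table <- function(path, required = .trial_columns) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tr))
  if (length(miss)) {
    stop("trial table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  }
  tr$correct <- as.logical(tr$correct)
  tr
}

#' Read a flat key-value configuration file
#'
#' Configurations are flat YAML mappings whose keys mirror
#' [default_config()] (observer parameters, seeds, resampling settings).
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a flat key-value mapping")
  cfg
}

#' Write a configuration to a flat YAML file
#'
#' @param config named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Observer parameters from a flat configuration
#'
#' Round-trips [observer_params()] through the flat config namespace: any
#' of the keys `chance`, `lapse`, `hva`, `vma`, `e2`, `alpha0`, `beta`,
#' `oblique_drop`, `frame`, `seed` present in `config` override the
#' defaults.
#'
#' @param config named list (e.g. from [read_config()]).
#' @return An [observer_params()].
#' @export
as_observer_params <- function(config) {
  keys <- c("chance", "lapse", "hva", "vma", "e2", "alpha0", "beta",
            "oblique_drop", "frame", "seed")
  do.call(observer_params, config[intersect(names(config), keys)])
}

#' Flat configuration from observer parameters
#'
#' @param params an [observer_params()].
#' @return Named list suitable for [write_config()].
#' @export
as_config <- function(params) {
  stopifnot(inherits(params, "observer_params"))
  unclass(params)
}

# MD5 of the canonical JSON serialization of a config.
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Machine-readable run manifest
#'
#' Records everything needed to reproduce a pipeline run: the resolved
#' configuration and its hash, the master seed, package and R versions,
#' and a timestamp (the only non-deterministic field).
#'
#' @param config resolved configuration list.
#' @return Named list.
#' @export
run_manifest <- function(config) {
  list(
    package = "vpfields",
    package_version = as.character(utils::packageVersion("vpfields")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config_hash = .config_hash(config),
    config = config
  )
}

#' Write a structured report as JSON text
#'
#' @param x report object (lists/data.frames of plain values).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}

# Flatten a contrast_result for JSON reports.
.contrast_as_list <- function(cr) {
  list(statistic = cr$statistic, df = cr$df, sem = cr$sem, p = cr$p,
       mean_diff = cr$mean_diff, axis = cr$axis,
       frame_roll_deg = cr$frame_roll_deg,
       set_a = cr$set_a, set_b = cr$set_b)
}

.write_exp1_outputs <- function(report, trials, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(trials, file.path(out_dir, "exp1_trials.csv"))
  utils::write.csv(report$cells, file.path(out_dir, "exp1_cells.csv"),
                   row.names = FALSE)
  write_report(
    list(anova = as.data.frame(report$anova),
         anova_degenerate = attr(report$anova, "degenerate"),
         sphericity_correction = attr(report$anova,
                                      "sphericity_correction"),
         contrasts = lapply(report$contrasts, .contrast_as_list),
         thresholds = report$thresholds,
         exclusions = report$exclusions),
    file.path(out_dir, "exp1_report.json"))
  write_report(report$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

.write_exp2_outputs <- function(report, trials, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(trials, file.path(out_dir, "exp2_trials.csv"))
  utils::write.csv(report$comparison$points,
                   file.path(out_dir, "exp2_observed_vs_predicted.csv"),
                   row.names = FALSE)
  cmp <- report$comparison
  write_report(
    list(
      winner = cmp$winner,
      winner_nonsig = cmp$winner_nonsig,
      models = lapply(cmp$models, function(z) {
        list(paired = .contrast_as_list(z$paired),
             regression = z$regression)
      }),
      maps = list(retinotopic = report$maps$retinotopic,
                  head_centric = report$maps$head_centric,
                  snap_rule = report$maps$snap_rule),
      observed_summary = report$observed$summary,
      baseline_summary = report$baseline$summary,
      thresholds = report$thresholds,
      exclusions = report$exclusions
    ),
    file.path(out_dir, "exp2_report.json"))
  write_report(report$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
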