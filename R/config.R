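#' Assemble a full run configuration
#'
#' One nested configuration drives the whole chain (simulate, preprocess,
#' train, baseline, evaluate), so every fixed constant of the protocol — 7-s
#' segments, 128 Hz, STFT window 50, the 3.5-s excision window, the
#' 22:00-07:00 night window, 5 folds, 1000 bootstrap replicates — lives in
#' one auditable place, and every random process has an explicit seed.
#'
#' @param sim Named list overriding [sim_config()] defaults.
#' @param preprocess Named list: `setting` (1 or 2), `stft_window`,
#'   `stft_hop`, `gate` (logical).
#' @param encoder Named list overriding [encoder_config()] defaults.
#' @param patient Named list overriding [gbm_config()] defaults, plus
#'   `n_bins`.
#' @param eval Named list: `k`, `n_boot`, `t_list`, `period`,
#'   `train_segments_per_patient`.
#' @param seed Master seed, used wherever a section does not set its own.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = list(), preprocess = list(), encoder = list(),
                       patient = list(), eval = list(), seed = 1L) {
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0L) {
      abort(sprintf(
        "unknown key(s) in %s config: %s", section, paste(bad, collapse = ", ")
      ))
    }
  }
  seed <- as.integer(seed)
  sim$seed <- sim$seed %||% seed
  check_keys(sim, names(formals(sim_config)), "sim")
  sim_cfg <- do.call(sim_config, sim)

  pp_defaults <- list(setting = 1, stft_window = 50, stft_hop = 25, gate = TRUE)
  check_keys(preprocess, names(pp_defaults), "preprocess")
  pp_cfg <- modifyList(pp_defaults, preprocess)

  encoder$seed <- encoder$seed %||% seed
  check_keys(encoder, names(formals(encoder_config)), "encoder")
  if (!is.null(encoder$channels)) encoder$channels <- unlist(encoder$channels)
  enc_cfg <- do.call(encoder_config, encoder)

  n_bins <- patient$n_bins %||% 24
  patient$n_bins <- NULL
  patient$seed <- patient$seed %||% seed
  check_keys(patient, names(formals(gbm_config)), "patient")
  gbm_cfg <- do.call(gbm_config, patient)

  ev_defaults <- list(
    k = 5, n_boot = 1000, t_list = c(3, 6, 12, 36), period = "ALL",
    train_segments_per_patient = Inf
  )
  check_keys(eval, names(ev_defaults), "eval")
  ev_cfg <- modifyList(ev_defaults, eval)
  ev_cfg$t_list <- unlist(ev_cfg$t_list)

  structure(
    list(
      sim = sim_cfg, preprocess = pp_cfg, encoder = enc_cfg,
      patient = gbm_cfg, n_bins = as.integer(n_bins), eval = ev_cfg,
      seed = seed
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any of the sections `sim`, `preprocess`,
#'   `encoder`, `patient`, `eval` and a top-level `seed`. Unknown keys are
#'   an error.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("sim", "preprocess", "encoder", "patient", "eval", "seed")
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0L) {
    abort(paste0("unknown top-level config key(s): ", paste(bad, collapse = ", ")))
  }
  run_config(
    sim = raw$sim %||% list(),
    preprocess = raw$preprocess %||% list(),
    encoder = raw$encoder %||% list(),
    patient = raw$patient %||% list(),
    eval = raw$eval %||% list(),
    seed = raw$seed %||% 1L
  )
}

#' Write the resolved configuration next to run artifacts
#' @param config A `run_config`.
#' @param dir Output directory.
#' @keywords internal
snapshot_config <- function(config, dir) {
  snap <- rapply(unclass(config), function(x) {
    if (inherits(x, "Date") || inherits(x, "POSIXct")) format(x) else x
  }, how = "replace")
  snap$package_version <- as.character(utils::packageVersion("holterpaf"))
  yaml::write_yaml(snap, file.path(dir, "config_snapshot.yaml"))
}

#' Execute a full configured run
#'
#' Simulates the cohort (unless `manifest_path` points at an existing one),
#' runs the two-stage experiment plus baseline for the configured setting and
#' period, and writes `metrics_<tag>.json`, `roc_<tag>.csv`,
#' `predictions_<tag>.csv`, `elapsed_<tag>.csv` and a config snapshot under
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param manifest_path Optional existing manifest CSV (skips simulation).
#' @return The `paf_experiment`, invisibly.
#' @export
run_all <- function(config, out_dir, manifest_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- if (is.null(manifest_path)) {
    generate_cohort(config$sim, file.path(out_dir, "cohort"))
  } else {
    read_cohort_manifest(manifest_path)
  }
  exp <- run_experiment(
    manifest,
    setting = config$preprocess$setting,
    encoder = config$encoder,
    gbm = config$patient,
    k = config$eval$k,
    n_bins = config$n_bins,
    stft_window = config$preprocess$stft_window,
    stft_hop = config$preprocess$stft_hop,
    period = config$eval$period,
    train_segments_per_patient = config$eval$train_segments_per_patient,
    n_boot = config$eval$n_boot,
    seed = config$seed
  )
  tag <- sprintf("setting%d_%s", config$preprocess$setting,
    tolower(config$eval$period))
  write.csv(exp$predictions, file.path(out_dir, paste0("predictions_", tag, ".csv")),
    row.names = FALSE)
  write.csv(exp$roc, file.path(out_dir, paste0("roc_", tag, ".csv")),
    row.names = FALSE)
  write.csv(exp$elapsed, file.path(out_dir, paste0("elapsed_", tag, ".csv")),
    row.names = FALSE)
  metrics <- list(
    report = exp$report,
    segment_auroc = exp$segment_auroc,
    cutoff = exp$cutoff
  )
  jsonlite::write_json(metrics, file.path(out_dir, paste0("metrics_", tag, ".json")),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  snapshot_config(config, out_dir)
  invisible(exp)
}
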