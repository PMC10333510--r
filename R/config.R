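#' Default run configuration
#'
#' The full pipeline configuration with every stage's defaults: cohort
#' simulation, preprocessing, training regime, leave-one-out evaluation and
#' interpretation. Values mirror the package defaults (the study-scale
#' cohort and the canonical training regime); config files override any
#' subset of keys.
#'
#' @return Nested named list (the `RunConfig` template).
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "mcrnn_out",
    log_level = "info",
    simulate = list(
      n_per_class = list(BP = 72L, MDD = 138L, SZ = 70L, NC = 47L),
      duration = 300, fs = 1000,
      background_rms = 10, white_rms = 1, noise_exponent = 1,
      artifact_rate = 0, artifact_kind = "amplitude_burst",
      sz_amp = 12, mdd_amp = 16, bp_amp = 13
    ),
    preprocess = list(
      target_fs = 250, band_lo = 0.5, band_hi = 70,
      epoch_s = 1, reject_uv = 100, normalize = "per_channel_z"
    ),
    train = list(
      batch_size = 512L, lr0 = 0.001, decay = 0.01,
      decay_mode = "inverse_time", max_epochs = 1000L, patience = 50L,
      val_fraction = 0.2, val_split_level = "epoch", class_weights = "none"
    ),
    evaluate = list(
      loocv = TRUE, subjects_per_class = NA, figures = FALSE
    ),
    interpret = list(mode = "zeros"),
    embed = list(method = "umap", n_neighbors = 15L, min_dist = 0.1)
  )
}

# merge user values over the template, rejecting unknown keys
#' @keywords internal
merge_config <- function(template, user, path = "") {
  if (is.null(user)) return(template)
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(template))
      stop("unknown config key: ", key, call. = FALSE)
    if (is.list(template[[nm]]) && nm != "n_per_class") {
      template[[nm]] <- merge_config(template[[nm]], user[[nm]], key)
    } else {
      template[[nm]] <- user[[nm]]
    }
  }
  template
}

#' Read and validate a run configuration
#'
#' Loads a YAML config file, rejects unknown keys (reporting the offending
#' key path) and fills unset keys from [default_run_config()]. The result
#' round-trips losslessly through [write_run_config()].
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user)
}

#' Write a run configuration to YAML
#' @param config config list.
#' @param path destination.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# provenance record written into every output directory
#' @keywords internal
write_provenance <- function(out_dir, config, seed) {
  cfg_file <- file.path(out_dir, "config_used.yaml")
  write_run_config(config, cfg_file)
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(cfg_file)),
         seed = seed,
         package = "mcrnn",
         version = as.character(utils::packageVersion("mcrnn"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
}
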