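# Configuration, result writing and reproducibility glue.

config_sections <- c("device", "triplet", "bcm", "crossbar", "rearing")

#' Default configuration
#'
#' The full set of model constants as a nested list (sections `device`,
#' `triplet`, `bcm`, `crossbar`, `rearing`), suitable for writing to YAML and
#' editing.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  dev <- unclass(device_params())
  tri <- unclass(triplet_params())
  list(
    device = dev,
    triplet = tri,
    bcm = list(rho0 = 15, tau_avg = 1e4),
    crossbar = list(w0 = 0.5, g = 50, window = 200, epochs = 2000, seed = 1,
                    learn_scale = 0.024, init_frac = 0.1, rho_norm = 30,
                    record_every = 10, high_rate = 30, low_rate = 14),
    rearing = list(condition = "normal", size = 9, epochs = 18000,
                   epoch_duration = 200, seed = 1, deprived_eye = "right",
                   noise_mode = "redraw", G_ref = 4500, learn_scale = 1e-5,
                   init_frac = 0.1, record_every = 25, high_rate = 30,
                   low_rate = 14, noise_lo = 4, noise_hi = 6)
  )
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, fills missing values from [default_config()]
#' and validates every section by constructing the corresponding parameter
#' objects (invalid values are rejected with field-level messages).  An empty
#' or absent-section file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return The validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  for (sec in names(user)) {
    if (!sec %in% config_sections) {
      abort(sprintf("Unknown config section `%s` (known: %s).", sec,
                    paste(config_sections, collapse = ", ")))
    }
    unknown <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(unknown)) {
      abort(sprintf("Unknown field(s) in section `%s`: %s.", sec,
                    paste(unknown, collapse = ", ")))
    }
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  # constructors carry the invariants; they abort with the offending field
  do.call(device_params, cfg$device)
  do.call(triplet_params, cfg$triplet)
  with(cfg$bcm, {
    check_number(rho0, "bcm.rho0", lower = 0, strict_lower = TRUE)
    check_number(tau_avg, "bcm.tau_avg", lower = 0, strict_lower = TRUE)
  })
  do.call(crossbar_config, config_crossbar_args(cfg))
  do.call(rearing_protocol, config_rearing_args(cfg))
  invisible(cfg)
}

config_crossbar_args <- function(cfg) {
  cb <- cfg$crossbar
  list(pattern = make_cross_pattern(cb$high_rate, cb$low_rate),
       w0 = cb$w0, g = cb$g, window = cb$window, epochs = cb$epochs,
       seed = cb$seed, device = do.call(device_params, cfg$device),
       rho0 = cfg$bcm$rho0, tau_avg = cfg$bcm$tau_avg,
       learn_scale = cb$learn_scale, init_frac = cb$init_frac,
       rho_norm = cb$rho_norm, record_every = cb$record_every)
}

config_rearing_args <- function(cfg) {
  re <- cfg$rearing
  list(condition = re$condition, size = re$size, high_rate = re$high_rate,
       low_rate = re$low_rate, noise_range = c(re$noise_lo, re$noise_hi),
       epochs = re$epochs, epoch_duration = re$epoch_duration, seed = re$seed,
       deprived_eye = re$deprived_eye, noise_mode = re$noise_mode,
       G_ref = re$G_ref, device = do.call(device_params, cfg$device),
       rho0 = cfg$bcm$rho0, tau_avg = cfg$bcm$tau_avg,
       learn_scale = re$learn_scale, init_frac = re$init_frac,
       record_every = re$record_every)
}

#' Save a configuration to YAML
#'
#' @param cfg A configuration list (validated on the way out).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

write_csv_checked <- function(df, path) {
  tryCatch(utils::write.csv(df, path, row.names = FALSE),
           error = function(e) {
             abort(sprintf("Failed to write %s: %s", path, conditionMessage(e)))
           })
  path
}

#' Write experiment results to a directory
#'
#' Writes deterministic CSV traces plus a JSON run manifest sufficient to
#' re-run the experiment (see [run_from_manifest()]).  A `tuning_result`
#' produces `weights_left.csv`, `weights_right.csv`, `rates.csv`,
#' `theta.csv`, `manifest.json`; a `crossbar_fit` produces `final.csv`,
#' `weights.csv`, `rates.csv`, `manifest.json`.
#'
#' @param result A `tuning_result` or `crossbar_fit`.
#' @param out_dir Output directory (created if missing).
#' @return Tibble inventory of the written files (`file`, `md5`), invisibly.
#' @export
write_results <- function(result, out_dir) {
  UseMethod("write_results")
}

finish_inventory <- function(files, out_dir, manifest_extra) {
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- c(manifest_extra, list(
    package = "memcortex",
    version = as.character(utils::packageVersion("memcortex")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  ))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(tibble::tibble(
    file = c(vapply(files, basename, character(1)), "manifest.json"),
    path = c(files, manifest_path)
  ))
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory: %s", out_dir))
  }
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 warning = function(w) FALSE, error = function(e) FALSE)
  if (!isTRUE(ok)) abort(sprintf("Output directory is not writable: %s", out_dir))
  unlink(probe)
  invisible(out_dir)
}

#' @export
write_results.tuning_result <- function(result, out_dir) {
  ensure_dir(out_dir)
  wm <- result$weight_maps
  size <- result$protocol$size
  eye_grid <- function(eye) {
    m <- matrix(wm$weight[wm$eye == eye], size, size, byrow = TRUE)
    as.data.frame(m)
  }
  files <- c(
    write_csv_checked(eye_grid("left"), file.path(out_dir, "weights_left.csv")),
    write_csv_checked(eye_grid("right"), file.path(out_dir, "weights_right.csv")),
    write_csv_checked(result$rate_trace[c("epoch", "orientation", "rho_y")],
                      file.path(out_dir, "rates.csv")),
    write_csv_checked(result$rate_trace[c("epoch", "theta")],
                      file.path(out_dir, "theta.csv"))
  )
  pr <- result$protocol
  finish_inventory(files, out_dir, list(
    kind = "rearing",
    protocol = list(condition = pr$condition, size = pr$size,
                    orientations = pr$orientations,
                    high_rate = pr$high_rate, low_rate = pr$low_rate,
                    noise_lo = pr$noise_range[1], noise_hi = pr$noise_range[2],
                    epochs = pr$epochs, epoch_duration = pr$epoch_duration,
                    seed = pr$seed, deprived_eye = pr$deprived_eye,
                    noise_mode = pr$noise_mode, G_ref = pr$G_ref,
                    rho0 = pr$bcm$rho0, tau_avg = pr$bcm$tau_avg,
                    learn_scale = pr$learn_scale,
                    G_min = pr$bcm$w_min * pr$G_ref,
                    G_max = pr$bcm$w_max * pr$G_ref,
                    init_frac = pr$init_frac,
                    record_every = pr$record_every)
  ))
}

#' @export
write_results.crossbar_fit <- function(result, out_dir) {
  ensure_dir(out_dir)
  cfg <- result$config
  files <- c(
    write_csv_checked(result$final, file.path(out_dir, "final.csv")),
    write_csv_checked(result$weight_trace, file.path(out_dir, "weights.csv")),
    write_csv_checked(result$rate_trace, file.path(out_dir, "rates.csv"))
  )
  finish_inventory(files, out_dir, list(
    kind = "crossbar",
    config = list(high_rate = max(cfg$pattern$rate),
                  low_rate = min(cfg$pattern$rate), w0 = cfg$w0, g = cfg$g,
                  window = cfg$window, epochs = cfg$epochs, seed = cfg$seed,
                  rho0 = cfg$bcm$rho0, tau_avg = cfg$bcm$tau_avg,
                  learn_scale = cfg$learn_scale,
                  G_min = cfg$device$G_min, G_max = cfg$device$G_max,
                  init_frac = cfg$init_frac, rho_norm = cfg$rho_norm,
                  record_every = cfg$record_every)
  ))
}

#' Re-run an experiment from its manifest
#'
#' Reconstructs the protocol or config recorded in a `manifest.json` and
#' re-runs the experiment; with the same package version the outputs are
#' bit-identical to the originals.
#'
#' @param manifest_path Path to a manifest written by [write_results()].
#' @return The re-computed `tuning_result` or `crossbar_fit`.
#' @export
run_from_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("Manifest not found: %s", manifest_path))
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (identical(m$kind, "rearing")) {
    pr <- m$protocol
    proto <- rearing_protocol(
      condition = pr$condition, size = pr$size,
      orientations = as.numeric(pr$orientations),
      high_rate = pr$high_rate, low_rate = pr$low_rate,
      noise_range = c(pr$noise_lo, pr$noise_hi), epochs = pr$epochs,
      epoch_duration = pr$epoch_duration, seed = pr$seed,
      deprived_eye = pr$deprived_eye, noise_mode = pr$noise_mode,
      G_ref = pr$G_ref, device = device_params(G_min = pr$G_min,
                                               G_max = pr$G_max),
      rho0 = pr$rho0, tau_avg = pr$tau_avg, learn_scale = pr$learn_scale,
      init_frac = pr$init_frac, record_every = pr$record_every
    )
    run_rearing(proto)
  } else if (identical(m$kind, "crossbar")) {
    cb <- m$config
    cfg <- crossbar_config(
      pattern = make_cross_pattern(cb$high_rate, cb$low_rate), w0 = cb$w0,
      g = cb$g, window = cb$window, epochs = cb$epochs, seed = cb$seed,
      device = device_params(G_min = cb$G_min, G_max = cb$G_max),
      rho0 = cb$rho0, tau_avg = cb$tau_avg, learn_scale = cb$learn_scale,
      init_frac = cb$init_frac, rho_norm = cb$rho_norm,
      record_every = cb$record_every
    )
    run_crossbar_learning(cfg)
  } else {
    abort(sprintf("Unknown manifest kind: %s", m$kind))
  }
}
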