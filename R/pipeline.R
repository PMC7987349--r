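# End-to-end pipelines: schedule -> simulate -> beamform -> reconstruct ->
# metrics, plus the stage commands backing the command-line interface.
# Stage outputs persist in standard formats (CSV, JSON, NIfTI, TIFF) with RDS
# for channel-data intermediates; every output records the configuration
# fingerprint, seed and package version so stages refuse mismatched inputs.

provenance <- function(cfg) {
  list(
    config_fingerprint = config_fingerprint(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("planesweep"))
  )
}

check_provenance <- function(meta, cfg, stage) {
  fp <- config_fingerprint(cfg)
  if (!identical(meta$config_fingerprint, fp)) {
    stop(sprintf(
      "%s: input was produced under a different configuration (fingerprint %s, expected %s)",
      stage, meta$config_fingerprint, fp
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate and beamform one sweep of imaging planes
#'
#' For each row of a (partitioned) schedule, simulates the plane-wave
#' transmission at that scan angle and beamforms it onto a fixed pixel grid.
#'
#' @param phantom A `us_phantom`.
#' @param tx A [transducer_model()].
#' @param acq An [acquisition_config()].
#' @param schedule_rows Data frame with at least `scan_deg` (one row per
#'   plane), e.g. one volume of a partitioned schedule.
#' @param grid Pixel grid for [das_beamform()].
#' @param steer_deg In-plane steering angle for all transmissions.
#' @param snr_db Per-channel SNR (dB).
#' @param seed Optional base seed; plane `i` uses `seed + i`.
#' @return List of `bmode_frame`s (with `scan_alpha_deg` set per plane).
#' @export
image_sweep <- function(phantom, tx, acq, schedule_rows, grid = NULL,
                        steer_deg = 0, snr_db = Inf, seed = NULL) {
  n <- nrow(schedule_rows)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    rf <- simulate_rf(
      phantom, tx, acq,
      scan_alpha_deg = schedule_rows$scan_deg[i], steer_deg = steer_deg,
      snr_db = snr_db, seed = if (is.null(seed)) NULL else seed + i
    )
    frames[[i]] <- das_beamform(rf, tx, acq, grid = grid)
  }
  frames
}

#' Stage commands
#'
#' Deterministic pipeline stages, each re-runnable from persisted
#' intermediates. `cmd_schedule()` writes the transmit schedule CSV and a
#' JSON rate report and prints the volume rate, planes per volume and
#' regime. `cmd_simulate()` writes RF frames for one complete volume,
#' `cmd_beamform()` beamforms them, `cmd_reconstruct()` writes the Cartesian
#' volume (NIfTI + TIFF + sidecars), `cmd_calibrate()` runs the synthetic
#' sweep calibration loop, `cmd_metrics()` writes wire-centroid metrics, and
#' `cmd_demo()` chains all stages.
#'
#' @param cfg A `run_config` (see [read_run_config()]).
#' @param output_dir Output directory; defaults to `cfg$output_dir`.
#' @return `cmd_schedule()`: list with `schedule` and `rate`, invisibly;
#'   the other stages return their main output path or object invisibly.
#' @export
cmd_schedule <- function(cfg, output_dir = cfg$output_dir) {
  cfg <- validate_run_config(cfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  acq <- config_acquisition(cfg)
  kin <- config_kinematics(cfg)
  rate <- volume_rate(effective_prf(acq$prf_hz, acq$n_compound_angles), kin)
  sch <- partition_into_volumes(build_schedule(acq, kin), rate)
  write_schedule_csv(sch, file.path(output_dir, "schedule.csv"))
  jsonlite::write_json(
    c(unclass(rate)[c(
      "volume_rate_hz", "regime", "multiplier_m", "planes_np",
      "peak_sampled", "effective_prf_hz", "period_samples"
    )], provenance(cfg)),
    file.path(output_dir, "rate.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_resolved_config(cfg, output_dir)
  cat(sprintf(
    "volume rate %.6g Hz, %d planes per volume, %s\n",
    rate$volume_rate_hz, rate$planes_np, rate$regime
  ))
  invisible(list(schedule = sch, rate = rate))
}

#' @rdname cmd_schedule
#' @export
cmd_simulate <- function(cfg, output_dir = cfg$output_dir) {
  cfg <- validate_run_config(cfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  acq <- config_acquisition(cfg)
  kin <- config_kinematics(cfg)
  tx <- config_transducer(cfg)
  phantom <- config_phantom(cfg)
  rate <- volume_rate(effective_prf(acq$prf_hz, acq$n_compound_angles), kin)
  sch <- partition_into_volumes(build_schedule(acq, kin), rate)
  vid <- complete_volume_ids(sch)
  if (!length(vid)) stop("schedule contains no complete volume", call. = FALSE)
  rows <- sch[sch$volume_id == vid[1], , drop = FALSE]
  frames <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    frames[[i]] <- simulate_rf(
      phantom, tx, acq,
      scan_alpha_deg = rows$scan_deg[i],
      snr_db = cfg$acquisition$snr_db %||% Inf,
      seed = cfg$seed + i
    )
    frames[[i]]$plane_index <- rows$index[i]
  }
  path <- file.path(output_dir, "rf-frames.rds")
  saveRDS(
    list(frames = frames, rows = rows, meta = provenance(cfg)),
    path
  )
  write_phantom_csv(phantom, file.path(output_dir, "phantom.csv"))
  write_resolved_config(cfg, output_dir)
  invisible(path)
}

#' @rdname cmd_schedule
#' @param frames_path Path to the `rf-frames.rds` written by
#'   `cmd_simulate()`.
#' @export
cmd_beamform <- function(cfg, frames_path, output_dir = cfg$output_dir) {
  cfg <- validate_run_config(cfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- readRDS(frames_path)
  check_provenance(stage$meta, cfg, "beamform")
  acq <- config_acquisition(cfg)
  tx <- config_transducer(cfg)
  bframes <- lapply(stage$frames, das_beamform, tx = tx, acq = acq)
  path <- file.path(output_dir, "bmode-frames.rds")
  saveRDS(list(frames = bframes, rows = stage$rows, meta = provenance(cfg)), path)
  invisible(path)
}

#' @rdname cmd_schedule
#' @param bmode_path Path to the `bmode-frames.rds` written by
#'   `cmd_beamform()`.
#' @export
cmd_reconstruct <- function(cfg, bmode_path, output_dir = cfg$output_dir) {
  cfg <- validate_run_config(cfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- readRDS(bmode_path)
  check_provenance(stage$meta, cfg, "reconstruct")
  vol <- reconstruct_volume(
    stage$frames,
    grid_spec = list(voxel_mm = cfg$reconstruction$voxel_mm)
  )
  path <- file.path(output_dir, "volume.nii.gz")
  write_volume_nifti(vol, path)
  write_volume_tiff(vol, file.path(output_dir, "volume.tif"))
  saveRDS(list(volume = vol, meta = provenance(cfg)),
    file.path(output_dir, "volume.rds")
  )
  invisible(path)
}

#' @rdname cmd_schedule
#' @export
cmd_calibrate <- function(cfg, output_dir = cfg$output_dir) {
  cfg <- validate_run_config(cfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  kin <- config_kinematics(cfg)
  cal <- cfg$calibration %||% list()
  sweep <- simulate_sweep_map(
    kin,
    duration_s = cal$duration_s %||% (10 / kin$tilt_freq_hz),
    sample_rate_hz = cal$sample_rate_hz %||% 10000,
    range_z_mm = cal$range_z_mm %||% 16.9,
    angle_noise_sd_deg = cal$angle_noise_sd_deg %||% 0.2,
    seed = cfg$seed
  )
  meas <- track_beam_angle(sweep$map, sweep$y_mm, sweep$range_z_mm, sweep$times_s)
  fit <- fit_sinusoid(meas)
  path <- file.path(output_dir, "calibration.json")
  write_calibration_json(fit, path, extra = provenance(cfg))
  invisible(path)
}

#' @rdname cmd_schedule
#' @param volume_path Path to the `volume.rds` written by
#'   `cmd_reconstruct()`.
#' @export
cmd_metrics <- function(cfg, volume_path, output_dir = cfg$output_dir) {
  cfg <- validate_run_config(cfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- readRDS(volume_path)
  check_provenance(stage$meta, cfg, "metrics")
  phantom <- config_phantom(cfg)
  path <- file.path(output_dir, "metrics.csv")
  if (!is.null(phantom$wire_y_mm)) {
    cent <- wire_centroids(stage$volume, phantom$wire_y_mm, phantom$wire_z_mm)
    df <- data.frame(
      wire = seq_along(phantom$wire_y_mm),
      true_y_mm = phantom$wire_y_mm, true_z_mm = phantom$wire_z_mm,
      est_y_mm = cent$y_mm, est_z_mm = cent$z_mm,
      err_mm = sqrt((cent$y_mm - phantom$wire_y_mm)^2 +
        (cent$z_mm - phantom$wire_z_mm)^2),
      seed = cfg$seed
    )
  } else {
    df <- data.frame(note = "no wire targets in phantom", seed = cfg$seed)
  }
  write_metrics_csv(df, path)
  invisible(path)
}

#' @rdname cmd_schedule
#' @export
cmd_demo <- function(cfg = default_run_config(), output_dir = cfg$output_dir) {
  cfg <- validate_run_config(cfg)
  cmd_schedule(cfg, output_dir)
  rf <- cmd_simulate(cfg, output_dir)
  bm <- cmd_beamform(cfg, rf, output_dir)
  vol <- cmd_reconstruct(cfg, bm, output_dir)
  cmd_metrics(cfg, file.path(output_dir, "volume.rds"), output_dir)
  cmd_calibrate(cfg, output_dir)
  invisible(output_dir)
}
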