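# Run configuration: YAML schema, packaged default profile, provenance.

required_config_keys <- list(
  acquisition = c(
    "sound_speed_m_s", "imaging_depth_mm", "prf_hz", "n_compound_angles",
    "n_scan_lines", "mirror_offset_mm", "duration_s"
  ),
  mirror = c("half_range_deg", "tilt_freq_hz", "phase_rad", "offset_deg"),
  transducer = c(
    "n_elements", "pitch_mm", "center_freq_mhz", "sampling_freq_mhz",
    "pulse_cycles", "elevational_focus_mm", "elevational_fwhm_mm"
  ),
  phantom = "type",
  reconstruction = c("voxel_mm", "dynamic_range_db")
)

#' Read and validate a run configuration
#'
#' Configurations are YAML with `acquisition`, `mirror`, `transducer`,
#' `phantom` and `reconstruction` sections plus top-level `seed` and
#' `output_dir`. Every required key must be present; validation happens
#' before any run.
#'
#' @param path Path to a YAML configuration.
#' @return A validated `run_config` list.
#' @seealso [default_run_config()] for the packaged default profile.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list to validate.
#' @export
validate_run_config <- function(cfg) {
  missing <- character(0)
  for (section in names(required_config_keys)) {
    if (is.null(cfg[[section]])) {
      missing <- c(missing, section)
      next
    }
    need <- required_config_keys[[section]]
    absent <- need[!need %in% names(cfg[[section]])]
    if (length(absent)) {
      missing <- c(missing, paste(section, absent, sep = "."))
    }
  }
  for (key in c("seed", "output_dir")) {
    if (is.null(cfg[[key]])) missing <- c(missing, key)
  }
  if (length(missing)) {
    stop("configuration schema error; missing key(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Packaged default acquisition profile
#'
#' The default configuration shipped with the package: 128-element
#' 15.625-MHz linear array, 20-kHz PRF, 250-Hz mirror tilting frequency,
#' 11.95 degrees half-side tilt range — the operating point at which the
#' volume rate is 500 Hz with 41 planes per volume.
#'
#' @return A validated `run_config`.
#' @export
default_run_config <- function() {
  read_run_config(
    system.file("extdata", "default-profile.yaml", package = "planesweep")
  )
}

#' Configuration accessors
#'
#' Build the typed objects used by the simulation and reconstruction
#' functions from a `run_config`.
#'
#' @param cfg A `run_config`.
#' @return The corresponding [acquisition_config()], [mirror_kinematics()],
#'   [transducer_model()] or `us_phantom`.
#' @export
config_acquisition <- function(cfg) {
  a <- cfg$acquisition
  acquisition_config(
    sound_speed_m_s = a$sound_speed_m_s, imaging_depth_mm = a$imaging_depth_mm,
    prf_hz = a$prf_hz, n_compound_angles = a$n_compound_angles,
    n_scan_lines = a$n_scan_lines, mirror_offset_mm = a$mirror_offset_mm,
    duration_s = a$duration_s
  )
}

#' @rdname config_acquisition
#' @export
config_kinematics <- function(cfg) {
  m <- cfg$mirror
  mirror_kinematics(m$half_range_deg, m$tilt_freq_hz, m$phase_rad, m$offset_deg)
}

#' @rdname config_acquisition
#' @export
config_transducer <- function(cfg) {
  t <- cfg$transducer
  transducer_model(
    n_elements = t$n_elements, pitch_mm = t$pitch_mm,
    center_freq_mhz = t$center_freq_mhz, sampling_freq_mhz = t$sampling_freq_mhz,
    pulse_cycles = t$pulse_cycles, elevational_focus_mm = t$elevational_focus_mm,
    elevational_fwhm_mm = t$elevational_fwhm_mm
  )
}

#' @rdname config_acquisition
#' @export
config_phantom <- function(cfg) {
  p <- cfg$phantom
  if (identical(p$type, "wires")) {
    make_wire_phantom(
      n_wires = p$n_wires %||% 4L, spacing_mm = p$spacing_mm %||% 3,
      depth_mm = p$depth_mm %||% 15, wire_length_mm = p$wire_length_mm %||% 10,
      depth_jitter_mm = p$depth_jitter_mm %||% 0, seed = cfg$seed
    )
  } else if (identical(p$type, "cysts")) {
    make_cyst_phantom(
      x_range_mm = unlist(p$x_range_mm %||% c(-4, 4)),
      y_range_mm = unlist(p$y_range_mm %||% c(-3, 3)),
      z_range_mm = unlist(p$z_range_mm %||% c(14, 26)),
      cavity_centers_mm = p$cavity_centers_mm %||% list(c(0, 0, 17), c(0, 0, 23)),
      cavity_radius_mm = p$cavity_radius_mm %||% 1.5,
      density_per_mm3 = p$density_per_mm3 %||% 200,
      seed = cfg$seed
    )
  } else {
    stop("unknown phantom type: ", p$type, call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash of a configuration, for stage-input provenance
# checks (kept below 2^53 so double arithmetic stays exact).
config_fingerprint <- function(cfg) {
  bytes <- as.integer(serialize(lapply(unclass(cfg), unclass), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483629
  sprintf("%08x", h)
}

#' Write the resolved configuration next to run outputs
#'
#' @param cfg A `run_config`.
#' @param output_dir Directory (created if needed).
#' @return Path of the written YAML, invisibly.
#' @export
write_resolved_config <- function(cfg, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(output_dir, "resolved-config.yaml")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
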