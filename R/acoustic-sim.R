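# Pulse-echo RF simulation for one plane-wave transmission. The mirror fold
# is modelled as a rigid rotation of the scene about the mirror hinge axis
# (the beam-reflection validation showed an ideal reflector is faithful), with
# the transducer-to-mirror path added to every delay.

#' Linear-array transducer model
#'
#' @param n_elements Number of elements.
#' @param pitch_mm Element pitch (mm).
#' @param center_freq_mhz Transmit centre frequency (MHz).
#' @param sampling_freq_mhz Channel sampling frequency (MHz); must be at
#'   least four times the centre frequency.
#' @param pulse_cycles Number of cycles in the Gaussian-enveloped tone burst.
#' @param elevational_focus_mm Depth of the elevational lens focus (mm).
#' @param elevational_fwhm_mm Elevational beamwidth (FWHM) at the focus (mm).
#' @return An object of class `transducer_model`.
#' @examples
#' tx <- transducer_model()
#' @export
transducer_model <- function(n_elements = 128L, pitch_mm = 0.1,
                             center_freq_mhz = 15.625,
                             sampling_freq_mhz = 62.5, pulse_cycles = 3,
                             elevational_focus_mm = 6,
                             elevational_fwhm_mm = 0.5) {
  if (n_elements < 1) stop("`n_elements` must be >= 1", call. = FALSE)
  if (sampling_freq_mhz < 4 * center_freq_mhz) {
    stop("sampling frequency must be >= 4x the centre frequency (aliasing)",
      call. = FALSE
    )
  }
  structure(
    list(
      n_elements = as.integer(n_elements),
      pitch_mm = pitch_mm,
      center_freq_mhz = center_freq_mhz,
      sampling_freq_mhz = sampling_freq_mhz,
      pulse_cycles = pulse_cycles,
      elevational_focus_mm = elevational_focus_mm,
      elevational_fwhm_mm = elevational_fwhm_mm
    ),
    class = "transducer_model"
  )
}

#' Element lateral positions
#'
#' @param tx A [transducer_model()].
#' @return Element centre positions along `x` (mm), centred on 0.
#' @export
element_positions <- function(tx) {
  (seq_len(tx$n_elements) - (tx$n_elements + 1) / 2) * tx$pitch_mm
}

#' Express a scene in the rotated imaging-plane frame
#'
#' The tilting mirror steers the imaging plane by the scan angle `alpha`
#' about the hinge axis (`x`). Equivalently the scene is rotated into the
#' plane's frame: a scatterer lying on the plane at angle `alpha` maps to
#' elevational offset `y' = 0` with its range from the mirror centre
#' preserved.
#'
#' @param phantom A `us_phantom`.
#' @param scan_alpha_deg Scan angle in degrees.
#' @return A `us_phantom` with rotated positions (`y` is now the offset from
#'   the imaging plane, `z` the in-plane depth).
#' @export
rotate_scene <- function(phantom, scan_alpha_deg) {
  stopifnot(inherits(phantom, "us_phantom"))
  a <- deg2rad(scan_alpha_deg)
  y <- phantom$positions[, "y"]
  z <- phantom$positions[, "z"]
  out <- phantom
  out$positions[, "y"] <- y * cos(a) - z * sin(a)
  out$positions[, "z"] <- y * sin(a) + z * cos(a)
  out
}

#' Elevational beam weight
#'
#' Gaussian amplitude weight `exp(-offset^2 / (2 sigma(z)^2))` for a
#' scatterer at elevational offset `offset` and depth `range`. The beamwidth
#' follows a Gaussian-beam model
#' `FWHM(z) = w0 sqrt(1 + ((z - zf)/zR)^2)` with waist FWHM `w0` at the
#' elevational focus `zf` and Rayleigh range `zR = pi a0^2 / lambda`
#' (`a0` the 1/e amplitude radius at the waist).
#'
#' @param offset_mm Elevational offset(s) from the imaging plane (mm).
#' @param range_mm Depth(s) of the scatterer (mm, > 0).
#' @param tx A [transducer_model()].
#' @param sound_speed_m_s Speed of sound used for the wavelength (m/s).
#' @return Weight(s) in `[0, 1]`.
#' @export
elevational_weight <- function(offset_mm, range_mm, tx,
                               sound_speed_m_s = 1480) {
  if (any(range_mm <= 0)) stop("`range_mm` must be positive", call. = FALSE)
  fw <- elevational_fwhm_at(range_mm, tx, sound_speed_m_s)
  sigma <- fw / (2 * sqrt(2 * log(2)))
  exp(-offset_mm^2 / (2 * sigma^2))
}

#' @rdname elevational_weight
#' @export
elevational_fwhm_at <- function(range_mm, tx, sound_speed_m_s = 1480) {
  lambda_mm <- sound_speed_m_s / (tx$center_freq_mhz * 1e6) * 1e3
  w0 <- tx$elevational_fwhm_mm
  a0 <- w0 / (2 * sqrt(log(2))) # 1/e amplitude radius at the waist
  zr <- pi * a0^2 / lambda_mm
  w0 * sqrt(1 + ((range_mm - tx$elevational_focus_mm) / zr)^2)
}

#' Simulate pulse-echo RF channel data for one plane-wave transmission
#'
#' Single-scattering point-target model: each scatterer within three
#' standard deviations of the elevational beam contributes a Gaussian-
#' enveloped tone burst at the centre frequency, delayed by the steered
#' plane-wave transmit arrival plus the per-element Euclidean return path
#' (both including the transducer-to-mirror distance), and weighted by the
#' elevational beam profile. Optional additive white Gaussian noise at a
#' configurable per-channel SNR.
#'
#' @param phantom A `us_phantom` (may be empty: yields a silent frame).
#' @param tx A [transducer_model()].
#' @param acq An [acquisition_config()].
#' @param scan_alpha_deg Mirror scan angle of this transmission (degrees).
#' @param steer_deg In-plane plane-wave steering angle (degrees).
#' @param snr_db Per-channel SNR in dB (`Inf` = noiseless).
#' @param seed Optional seed for the noise (recorded in the frame).
#' @return An `rf_frame`: `channel_data` (time samples x elements),
#'   `fs_hz`, `t0_s`, `scan_alpha_deg`, `steer_deg`, `seed`.
#' @export
simulate_rf <- function(phantom, tx, acq, scan_alpha_deg = 0, steer_deg = 0,
                        snr_db = Inf, seed = NULL) {
  stopifnot(
    inherits(phantom, "us_phantom"), inherits(tx, "transducer_model"),
    inherits(acq, "acquisition_config")
  )
  c_m_s <- acq$sound_speed_m_s
  fs <- tx$sampling_freq_mhz * 1e6
  f0 <- tx$center_freq_mhz * 1e6
  nt <- as.integer(ceiling(
    2 * (acq$imaging_depth_mm + acq$mirror_offset_mm) * 1e-3 / c_m_s * fs
  ))
  rot <- rotate_scene(phantom, scan_alpha_deg)
  pos <- rot$positions
  amp <- rot$amplitude
  if (nrow(pos)) {
    inplane <- pos[, "z"] > 0
    pos <- pos[inplane, , drop = FALSE]
    amp <- amp[inplane]
  }
  if (nrow(pos)) {
    w <- elevational_weight(pos[, "y"], pos[, "z"], tx, c_m_s)
    keep <- w > exp(-9 / 2) # 3 sigma
    pos <- pos[keep, , drop = FALSE]
    amp <- amp[keep] * w[keep]
  }
  if (nrow(pos)) {
    sigma_t <- tx$pulse_cycles / f0 / (2 * sqrt(2 * log(2)))
    data <- rf_sim_core(
      pos[, "x"] * 1e-3, pos[, "y"] * 1e-3, pos[, "z"] * 1e-3, amp,
      element_positions(tx) * 1e-3, c_m_s, fs, nt, f0, sigma_t,
      deg2rad(steer_deg), acq$mirror_offset_mm * 1e-3
    )
  } else {
    data <- matrix(0, nrow = nt, ncol = tx$n_elements)
  }
  if (is.finite(snr_db)) {
    if (!is.null(seed)) set.seed(seed)
    sig_rms <- sqrt(mean(data^2))
    if (sig_rms > 0) {
      noise_sd <- sig_rms / 10^(snr_db / 20)
      data <- data + matrix(rnorm(length(data), 0, noise_sd), nrow = nt)
    }
  }
  structure(
    list(
      channel_data = data, fs_hz = fs, t0_s = 0,
      scan_alpha_deg = scan_alpha_deg, steer_deg = steer_deg,
      plane_index = NA_integer_, seed = seed
    ),
    class = "rf_frame"
  )
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf(
    "RF frame: %d samples x %d elements, alpha = %.2f deg, steer = %.2f deg\n",
    nrow(x$channel_data), ncol(x$channel_data), x$scan_alpha_deg, x$steer_deg
  ))
  invisible(x)
}
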