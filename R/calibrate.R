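# Recovery of mirror kinematics from calibration sweeps: acoustic beam-peak
# tracking, sinusoid fitting, voltage-angle linearity, resonance peak.

#' Map asymmetric measured tilt ranges to sinusoid parameters
#'
#' A measured tilt range of `+upper / -lower` degrees is represented by the
#' symmetric sinusoid with amplitude `A = (upper + lower) / 2` and offset
#' `gamma = (upper - lower) / 2`.
#'
#' @param upper_deg,lower_deg Magnitudes of the upward and downward tilt
#'   extremes (degrees, >= 0).
#' @param tilt_freq_hz Mirror tilting frequency (Hz).
#' @param phase_rad Initial phase (radians).
#' @return A [mirror_kinematics()] object.
#' @examples
#' range_to_kinematics(12.6, 11.3, 250) # A = 11.95, gamma = 0.65
#' @export
range_to_kinematics <- function(upper_deg, lower_deg, tilt_freq_hz,
                                phase_rad = 0) {
  mirror_kinematics(
    half_range_deg = (upper_deg + lower_deg) / 2,
    tilt_freq_hz = tilt_freq_hz,
    phase_rad = phase_rad,
    offset_deg = (upper_deg - lower_deg) / 2
  )
}

#' Simulate an acoustic calibration sweep map
#'
#' Forward model of the acoustic calibration measurement: a receive aperture
#' at fixed depth records the elevational beam intensity over time while the
#' mirror sweeps. Each time column is a Gaussian beam profile centred at the
#' elevational position corresponding to the instantaneous scan angle;
#' optional angular noise jitters the beam centre, and dropout columns are
#' zeroed to emulate lost acquisitions.
#'
#' @param kin True [mirror_kinematics()].
#' @param duration_s Sweep duration (s).
#' @param sample_rate_hz Temporal sampling rate of the map (Hz).
#' @param y_mm Elevational receiver positions (rows of the map, mm).
#' @param range_z_mm Depth of the receiver line (mm, > 0).
#' @param beam_fwhm_mm Elevational beam FWHM at that depth (mm).
#' @param angle_noise_sd_deg Standard deviation of tilt-angle noise (deg).
#' @param dropout_cols Indices of time columns to zero out.
#' @param seed Optional seed for the noise.
#' @return List with `map` (y by time intensity), `times_s`, `y_mm`,
#'   `range_z_mm` and the generating `kin`.
#' @export
simulate_sweep_map <- function(kin, duration_s = 0.04, sample_rate_hz = 10000,
                               y_mm = seq(-8, 8, by = 0.1), range_z_mm = 16.9,
                               beam_fwhm_mm = 1, angle_noise_sd_deg = 0,
                               dropout_cols = integer(0), seed = NULL) {
  stopifnot(inherits(kin, "mirror_kinematics"))
  stop_if_not_scalar_pos(range_z_mm, "range_z_mm")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(1 / sample_rate_hz, duration_s, by = 1 / sample_rate_hz)
  tilt <- tilt_angle_at(kin, times)
  if (angle_noise_sd_deg > 0) {
    tilt <- tilt + rnorm(length(tilt), 0, angle_noise_sd_deg)
  }
  yc <- range_z_mm * tan(deg2rad(2 * tilt))
  sigma <- beam_fwhm_mm / (2 * sqrt(2 * log(2)))
  map <- exp(-outer(y_mm, yc, `-`)^2 / (2 * sigma^2))
  if (length(dropout_cols)) map[, dropout_cols] <- 0
  list(map = map, times_s = times, y_mm = y_mm, range_z_mm = range_z_mm,
       kin = kin)
}

#' Track the beam angle across a sweep map
#'
#' Per time column, the peak elevational position is located with parabolic
#' sub-sample refinement, converted to a scan angle via `atan2` against the
#' receiver depth, and halved to a tilt angle. Flat (dropout) columns are
#' flagged as missing, not interpolated.
#'
#' @param map Intensity map (rows elevational positions, columns time).
#' @param y_mm Elevational positions of the rows (mm).
#' @param range_z_mm Depth of the receiver line (mm).
#' @param times_s Times of the columns (s).
#' @return A `sweep_measurement`: `times_s`, `tilt_deg` (NA where missing),
#'   `missing` logical vector.
#' @export
track_beam_angle <- function(map, y_mm, range_z_mm, times_s) {
  map <- as.matrix(map)
  if (ncol(map) < 1L) stop("map must have at least one time column", call. = FALSE)
  stopifnot(nrow(map) == length(y_mm), ncol(map) == length(times_s))
  dy <- if (length(y_mm) > 1) y_mm[2] - y_mm[1] else 1
  tilt <- rep(NA_real_, ncol(map))
  missing <- rep(FALSE, ncol(map))
  for (j in seq_len(ncol(map))) {
    col <- map[, j]
    if (max(col) - min(col) <= 1e-12) {
      missing[j] <- TRUE
      next
    }
    i <- which.max(col)
    yp <- y_mm[i]
    if (i > 1 && i < length(col)) {
      denom <- col[i - 1] - 2 * col[i] + col[i + 1]
      if (denom < 0) yp <- yp + 0.5 * dy * (col[i - 1] - col[i + 1]) / denom
    }
    tilt[j] <- rad2deg(atan2(yp, range_z_mm)) / 2
  }
  structure(
    list(times_s = times_s, tilt_deg = tilt, missing = missing),
    class = "sweep_measurement"
  )
}

#' Fit a sinusoid to tracked tilt angles
#'
#' Least-squares fit of `theta(t) = A sin(2 pi F t + phi) + gamma`. With the
#' frequency known the model is linear in the `sin`/`cos`/constant basis;
#' with the frequency unknown, a coarse 1-Hz grid over `freq_band_hz` is
#' scanned and the best frequency refined with [stats::optimize()]
#' (golden-section/parabolic search). The amplitude is reported non-negative
#' with the phase adjusted accordingly, normalised to `[0, 2 pi)`.
#'
#' @param meas A `sweep_measurement` (missing samples are dropped).
#' @param freq_known_hz Mirror frequency if known (Hz), else `NULL`.
#' @param freq_band_hz Search band when the frequency is unknown (Hz).
#' @return A `calibration_fit`: `A_hat_deg`, `phi_hat_rad`, `gamma_hat_deg`,
#'   `Fm_hat_hz`, `rms_residual_deg`, `n_used`.
#' @export
fit_sinusoid <- function(meas, freq_known_hz = NULL,
                         freq_band_hz = c(100, 350)) {
  stopifnot(inherits(meas, "sweep_measurement"))
  ok <- !meas$missing & is.finite(meas$tilt_deg)
  t <- meas$times_s[ok]
  th <- meas$tilt_deg[ok]
  if (length(t) < 4L) stop("under-determined: need at least 4 samples", call. = FALSE)

  fit_at <- function(f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
    fit <- .lm.fit(X, th)
    list(coef = fit$coefficients, rss = sum(fit$residuals^2))
  }

  if (is.null(freq_known_hz)) {
    span <- diff(range(t))
    if (span * freq_band_hz[1] < 2) {
      stop("under-determined: need at least 2 mirror periods of data", call. = FALSE)
    }
    grid <- seq(freq_band_hz[1], freq_band_hz[2], by = 1)
    rss <- vapply(grid, function(f) fit_at(f)$rss, numeric(1))
    f0 <- grid[which.min(rss)]
    lo <- max(freq_band_hz[1], f0 - 1)
    hi <- min(freq_band_hz[2], f0 + 1)
    fm <- optimize(function(f) fit_at(f)$rss, c(lo, hi), tol = 1e-7)$minimum
  } else {
    if (diff(range(t)) * freq_known_hz < 2) {
      stop("under-determined: need at least 2 mirror periods of data", call. = FALSE)
    }
    fm <- freq_known_hz
  }
  best <- fit_at(fm)
  a <- best$coef[1]
  b <- best$coef[2]
  amp <- sqrt(a^2 + b^2)
  phi <- if (amp > 0) atan2(b, a) else 0
  structure(
    list(
      A_hat_deg = amp,
      phi_hat_rad = phi %% (2 * pi),
      gamma_hat_deg = best$coef[3],
      Fm_hat_hz = fm,
      rms_residual_deg = sqrt(best$rss / length(t)),
      n_used = length(t)
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Sinusoid fit: A = %.4f deg, phi = %.4f rad, gamma = %.4f deg, Fm = %.3f Hz (rms %.4g deg, n = %d)\n",
    x$A_hat_deg, x$phi_hat_rad, x$gamma_hat_deg, x$Fm_hat_hz,
    x$rms_residual_deg, x$n_used
  ))
  invisible(x)
}

#' Voltage-to-tilt-range linearity
#'
#' Ordinary least-squares line through (driving voltage, total tilt range)
#' calibration points.
#'
#' @param voltages_vpp Driving voltages (Vpp).
#' @param total_ranges_deg Total tilt ranges (degrees).
#' @return List with `slope_deg_per_vpp`, `intercept_deg`, `r_squared`.
#' @export
fit_voltage_angle <- function(voltages_vpp, total_ranges_deg) {
  if (length(voltages_vpp) < 2L || length(total_ranges_deg) < 2L) {
    stop("need at least 2 calibration points", call. = FALSE)
  }
  if (length(unique(voltages_vpp)) < 2L) {
    stop("degenerate calibration: all driving voltages identical", call. = FALSE)
  }
  fit <- lm(total_ranges_deg ~ voltages_vpp)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((total_ranges_deg - mean(total_ranges_deg))^2)
  list(
    slope_deg_per_vpp = unname(coef(fit)[2]),
    intercept_deg = unname(coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  )
}

#' Resonance peak of a frequency response
#'
#' Argmax of the tilt-amplitude response with three-point parabolic
#' refinement. If the response is monotone (peak at a boundary of the tested
#' band), the boundary frequency is returned with a warning.
#'
#' @param freqs_hz Tested driving frequencies (Hz), sorted ascending.
#' @param amplitudes_deg Measured tilt amplitudes (degrees).
#' @return Resonant frequency estimate (Hz).
#' @export
resonance_peak <- function(freqs_hz, amplitudes_deg) {
  if (length(freqs_hz) < 3L) stop("need at least 3 points", call. = FALSE)
  stopifnot(length(freqs_hz) == length(amplitudes_deg))
  i <- which.max(amplitudes_deg)
  if (i == 1L || i == length(freqs_hz)) {
    warning("response is monotone over the tested band; returning the boundary frequency",
      call. = FALSE
    )
    return(freqs_hz[i])
  }
  # exact parabola through the three bracketing points (allows uneven spacing)
  x <- freqs_hz[(i - 1):(i + 1)]
  y <- amplitudes_deg[(i - 1):(i + 1)]
  cf <- unname(solve(cbind(1, x, x^2), y))
  if (cf[3] >= 0) {
    return(freqs_hz[i])
  }
  unname(-cf[2] / (2 * cf[3]))
}

#' Write a calibration report as JSON
#'
#' @param fit A `calibration_fit`.
#' @param path Output path.
#' @param extra Optional named list merged into the report (seeds, notes).
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(fit, path, extra = list()) {
  stopifnot(inherits(fit, "calibration_fit"))
  jsonlite::write_json(c(unclass(fit), extra), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
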