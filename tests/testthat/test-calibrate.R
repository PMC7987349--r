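# Calibration: beam tracking, sinusoid fitting, voltage linearity, resonance.

test_that("sinusoid fitting is exact on noiseless model data", {
  kin <- mirror_kinematics(12, 250, phase_rad = 0.3, offset_deg = 0.6)
  t <- seq(1e-4, 0.04, by = 1e-4)
  meas <- structure(
    list(times_s = t, tilt_deg = tilt_angle_at(kin, t),
         missing = rep(FALSE, length(t))),
    class = "sweep_measurement"
  )
  fit <- fit_sinusoid(meas, freq_known_hz = 250)
  expect_equal(fit$A_hat_deg, 12, tolerance = 1e-9)
  expect_equal(fit$phi_hat_rad, 0.3, tolerance = 1e-9)
  expect_equal(fit$gamma_hat_deg, 0.6, tolerance = 1e-9)
  expect_lt(fit$rms_residual_deg, 1e-9)

  # frequency-unknown path recovers the same parameters
  fit2 <- fit_sinusoid(meas)
  expect_equal(fit2$Fm_hat_hz, 250, tolerance = 1e-3)
  expect_equal(fit2$A_hat_deg, 12, tolerance = 1e-5)

  # offset-only data (A = 0) degenerates gracefully
  meas0 <- structure(
    list(times_s = t, tilt_deg = rep(0.6, length(t)),
         missing = rep(FALSE, length(t))),
    class = "sweep_measurement"
  )
  fit0 <- fit_sinusoid(meas0, freq_known_hz = 250)
  expect_lt(fit0$A_hat_deg, 1e-9)
  expect_equal(fit0$gamma_hat_deg, 0.6, tolerance = 1e-9)

  # under-determined input is refused
  short <- structure(
    list(times_s = t[1:3], tilt_deg = tilt_angle_at(kin, t[1:3]),
         missing = rep(FALSE, 3)),
    class = "sweep_measurement"
  )
  expect_error(fit_sinusoid(short, freq_known_hz = 250), "under-determined")
  expect_error(
    fit_sinusoid(structure(
      list(times_s = t[1:50], tilt_deg = tilt_angle_at(kin, t[1:50]),
           missing = rep(FALSE, 50)),
      class = "sweep_measurement"
    ), freq_known_hz = 250),
    "2 mirror periods"
  )
})

test_that("the reported amplitude is non-negative with the phase absorbed", {
  # theta = -A sin(w t) is A sin(w t + pi)
  t <- seq(1e-4, 0.04, by = 1e-4)
  meas <- structure(
    list(times_s = t, tilt_deg = -8 * sin(2 * pi * 250 * t),
         missing = rep(FALSE, length(t))),
    class = "sweep_measurement"
  )
  fit <- fit_sinusoid(meas, freq_known_hz = 250)
  expect_equal(fit$A_hat_deg, 8, tolerance = 1e-9)
  expect_equal(fit$phi_hat_rad, pi, tolerance = 1e-9)
})

test_that("beam tracking recovers angles and flags dropouts", {
  kin <- mirror_kinematics(11, 250, phase_rad = 0.2)
  sweep <- simulate_sweep_map(kin, duration_s = 0.02, dropout_cols = 17L)
  meas <- track_beam_angle(sweep$map, sweep$y_mm, sweep$range_z_mm, sweep$times_s)
  expect_true(meas$missing[17])
  expect_true(is.na(meas$tilt_deg[17]))
  ok <- !meas$missing
  truth <- tilt_angle_at(kin, sweep$times_s)
  expect_lt(max(abs(meas$tilt_deg[ok] - truth[ok])), 0.05)

  # a static beam tracks to a constant angle
  flatkin <- mirror_kinematics(0, 250, offset_deg = 1.5)
  sweep2 <- simulate_sweep_map(flatkin, duration_s = 0.005)
  meas2 <- track_beam_angle(sweep2$map, sweep2$y_mm, sweep2$range_z_mm,
                            sweep2$times_s)
  expect_lt(diff(range(meas2$tilt_deg)), 1e-6)
  expect_equal(mean(meas2$tilt_deg), 1.5, tolerance = 0.02)
})

test_that("the full calibration loop closes on the generating kinematics", {
  kin <- mirror_kinematics(11.95, 250, phase_rad = 0.4, offset_deg = 0.65)
  sweep <- simulate_sweep_map(kin,
    duration_s = 0.04, angle_noise_sd_deg = 0.2,
    seed = 77
  )
  meas <- track_beam_angle(sweep$map, sweep$y_mm, sweep$range_z_mm, sweep$times_s)
  fit <- fit_sinusoid(meas)
  expect_lt(abs(fit$A_hat_deg - 11.95), 0.1)
  expect_lt(abs(fit$Fm_hat_hz - 250), 0.5)
  expect_lt(abs(fit$gamma_hat_deg - 0.65), 0.1)
})

test_that("asymmetric measured ranges map to amplitude plus offset", {
  kin <- range_to_kinematics(12.6, 11.3, 250)
  expect_equal(kin$half_range_deg, 11.95)
  expect_equal(kin$offset_deg, 0.65)
  # the represented extremes reproduce the measurement
  t <- seq(0, 4e-3, by = 1e-5)
  th <- tilt_angle_at(kin, t)
  expect_equal(max(th), 12.6, tolerance = 1e-3)
  expect_equal(min(th), -11.3, tolerance = 1e-3)
})

test_that("voltage-angle calibration is an ordinary least-squares line", {
  # two-point line through the measured 5 and 10 Vpp total ranges
  fit <- fit_voltage_angle(c(5, 10), c(14.4, 23.9))
  expect_equal(fit$slope_deg_per_vpp, 1.9)
  expect_equal(fit$intercept_deg, 4.9)

  prop <- fit_voltage_angle(c(1, 2, 4), c(2, 4, 8))
  expect_equal(prop$intercept_deg, 0, tolerance = 1e-12)
  expect_equal(prop$r_squared, 1)

  # duplicated voltages with differing readings: the line passes through
  # their best-fit mean and cannot explain all variance
  dup <- fit_voltage_angle(c(5, 5, 10), c(10, 12, 20))
  expect_equal(dup$intercept_deg + 5 * dup$slope_deg_per_vpp, 11)
  expect_lt(dup$r_squared, 1)

  expect_error(fit_voltage_angle(5, 10), "at least 2")
  expect_error(fit_voltage_angle(c(5, 5), c(10, 12)), "degenerate")
})

test_that("resonance peaks are located with parabolic refinement", {
  f <- seq(100, 350, by = 10)
  lorentz <- 1 / (1 + ((f - 240) / 30)^2)
  expect_lt(abs(resonance_peak(f, lorentz) - 240), 2)
  # an off-grid peak is still refined to within a fraction of the step
  lorentz2 <- 1 / (1 + ((f - 243) / 30)^2)
  expect_lt(abs(resonance_peak(f, lorentz2) - 243), 2)
  # symmetric triangle: exact
  tri <- pmax(0, 1 - abs(f - 240) / 50)
  expect_equal(resonance_peak(f, tri), 240)
  # monotone response: boundary value plus a warning
  expect_warning(top <- resonance_peak(f, f / 350), "monotone")
  expect_equal(top, 350)
  expect_error(resonance_peak(c(100, 200), c(1, 2)), "at least 3")
})
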