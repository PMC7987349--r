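# Scheduler: PRF closed forms, tilt/scan trajectory, volume-rate regimes,
# schedule construction, volume partitioning and multiplexed variants.

test_that("PRF follows the round-trip closed form and rejects bad input", {
  expect_equal(prf_from_depth(1500, 30), 25000)
  expect_equal(prf_from_depth(1500, 15), 50000)
  expect_equal(prf_from_depth(1540, 77), 10000)
  expect_error(prf_from_depth(-1500, 30), "positive")
  expect_error(prf_from_depth(1500, 0), "positive")
})

test_that("effective PRF divides by the number of compounding angles", {
  expect_equal(effective_prf(25000, 1), 25000)
  expect_equal(effective_prf(13500, 3), 4500)
  expect_equal(effective_prf(20000, 4), 5000)
  expect_error(effective_prf(20000, 0), ">= 1")
})

test_that("tilt trajectory evaluates the sinusoid and scan angle doubles it", {
  kin <- mirror_kinematics(12, 250)
  expect_equal(tilt_angle_at(kin, 0), 0)
  expect_equal(tilt_angle_at(kin, 1e-3), 12)
  kin2 <- mirror_kinematics(10, 100, phase_rad = pi, offset_deg = 2)
  expect_equal(tilt_angle_at(kin2, 0), 2)
  # alpha = 2 theta exactly, everywhere
  kin3 <- mirror_kinematics(11.3, 250, phase_rad = 0.7, offset_deg = -0.4)
  t <- seq(0, 0.02, by = 1e-5)
  expect_identical(scan_angle_at(kin3, t), 2 * tilt_angle_at(kin3, t))
  kin45 <- mirror_kinematics(45, 250, phase_rad = pi / 2)
  expect_equal(scan_angle_at(kin45, 0), 90)
})

test_that("volume rate reproduces the documented operating points", {
  kin <- mirror_kinematics(11.95, 250)
  r1 <- volume_rate(20000, kin)
  expect_equal(r1$volume_rate_hz, 500)
  expect_equal(r1$regime, "condition1")
  expect_true(r1$peak_sampled)
  expect_equal(planes_per_volume(20000, r1), 41L)

  r2 <- volume_rate(1000, kin)
  expect_equal(r2$volume_rate_hz, 500)
  expect_equal(r2$regime, "condition1")
  expect_equal(planes_per_volume(1000, r2), 3L)

  r3 <- volume_rate(1125, kin)
  expect_equal(r3$volume_rate_hz, 125)
  expect_equal(r3$regime, "condition2")
  expect_equal(r3$multiplier_m, 2L)
  expect_equal(planes_per_volume(1125, r3), 9L)

  r4 <- volume_rate(1062.5, kin)
  expect_equal(r4$volume_rate_hz, 62.5)
  expect_equal(r4$multiplier_m, 4L)
  expect_equal(planes_per_volume(1062.5, r4), 17L)

  # even ratio with a phase that dodges the sweep extrema: no +1 plane
  kin_shift <- mirror_kinematics(11.95, 250, phase_rad = pi / 100)
  r5 <- suppressWarnings(volume_rate(25000, kin_shift))
  expect_equal(r5$volume_rate_hz, 500)
  expect_false(r5$peak_sampled)
  expect_equal(planes_per_volume(25000, r5), 50L)
})

test_that("irrational-like ratios are rejected as non-repeating", {
  kin <- mirror_kinematics(10, 250)
  expect_error(volume_rate(250 * sqrt(2), kin), "non-repeating")
  # and the search cap is honoured
  expect_error(volume_rate(250 * (1 + 1 / 101), kin, m_max = 64L), "non-repeating")
  expect_equal(volume_rate(250 * (1 + 1 / 101), kin, m_max = 128L)$multiplier_m, 101L)
})

test_that("condition-1 at nonzero phase is flagged, not silently classified", {
  kin <- mirror_kinematics(10, 250, phase_rad = pi / 4)
  expect_warning(r <- volume_rate(2000, kin), "phase") # r = 8, (r/pi)phi = 2
  expect_equal(r$regime, "condition1")
})

test_that("schedules sample t_n = n/PRFe and repeat with the oracle period", {
  kin <- mirror_kinematics(12, 250)
  acq <- test_acq(prf_hz = 1000, duration_s = 0.004)
  sch <- build_schedule(acq, kin)
  expect_equal(sch$time_s, (1:4) / 1000)
  expect_equal(sch$tilt_deg, c(12, 0, -12, 0), tolerance = 1e-12)
  expect_equal(sch$scan_deg, 2 * sch$tilt_deg)

  # r = 1125/250 = 4.5: sampled tilt sequence repeats every 9 samples
  acq2 <- test_acq(prf_hz = 1125, duration_s = 0.032)
  sch2 <- build_schedule(acq2, kin)
  expect_equal(sch2$tilt_deg[1:9], sch2$tilt_deg[10:18], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sch2$tilt_deg[1:8], sch2$tilt_deg[2:9])))

  # degenerate duration: empty schedule
  acq3 <- test_acq(prf_hz = 1000, duration_s = 1e-6)
  expect_equal(nrow(build_schedule(acq3, kin)), 0L)
})

test_that("volume partitioning matches the half-sweep / period semantics", {
  kin <- mirror_kinematics(12, 250)
  # r = 4: half-sweep volumes of 3 samples covering {-A, 0, +A}
  acq <- test_acq(prf_hz = 1000, duration_s = 0.02)
  rate <- volume_rate(1000, kin)
  sch <- partition_into_volumes(build_schedule(acq, kin), rate)
  ids <- complete_volume_ids(sch)
  expect_gt(length(ids), 3)
  for (vid in ids[1:3]) {
    v <- sch[sch$volume_id == vid, ]
    expect_equal(nrow(v), 3L)
    expect_setequal(round(v$tilt_deg, 9), c(-12, 0, 12))
    expect_true(all(v$sweep_dir %in% c("up", "down")))
    expect_equal(length(unique(v$sweep_dir)), 1L)
  }
  # shared extremal samples appear in two adjacent volumes
  peaks <- sch[abs(abs(sch$tilt_deg) - 12) < 1e-9, ]
  expect_true(all(table(peaks$index) == 2))

  # r = 80: 41 samples per volume
  acq80 <- test_acq(prf_hz = 20000, duration_s = 0.008)
  rate80 <- volume_rate(20000, kin)
  sch80 <- partition_into_volumes(build_schedule(acq80, kin), rate80)
  sizes <- table(sch80$volume_id)
  expect_true(all(sizes[complete_volume_ids(sch80)] == 41))

  # r = 4.25: full-period volumes of 17 samples, 17 distinct angles
  acq17 <- test_acq(prf_hz = 1062.5, duration_s = 0.033)
  rate17 <- volume_rate(1062.5, kin)
  sch17 <- partition_into_volumes(build_schedule(acq17, kin), rate17)
  v1 <- sch17[sch17$volume_id == 1, ]
  expect_equal(nrow(v1), 17L)
  expect_equal(length(unique(round(v1$tilt_deg, 9))), 17L)

  # too-short schedule
  acq_short <- test_acq(prf_hz = 1062.5, duration_s = 0.01)
  expect_error(
    partition_into_volumes(build_schedule(acq_short, kin), rate17),
    "shorter than one volume"
  )
})

test_that("condition-1 double coverage: non-extremal angles sampled twice per cycle", {
  kin <- mirror_kinematics(10, 250)
  acq <- test_acq(prf_hz = 3000, duration_s = 0.012) # r = 12
  sch <- build_schedule(acq, kin)
  cycle <- sch$tilt_deg[sch$time_s > 0.004 & sch$time_s <= 0.008]
  counts <- table(round(cycle, 9))
  extremal <- abs(abs(as.numeric(names(counts))) - 10) < 1e-9
  expect_true(all(counts[!extremal] == 2))
  expect_true(all(counts[extremal] == 1))
})

test_that("raising the tilt frequency trades planes for volume rate", {
  fms <- c(100, 125, 200, 250, 500, 625)
  res <- lapply(fms, function(fm) {
    volume_rate(20000, mirror_kinematics(10, fm))
  })
  fv <- vapply(res, `[[`, numeric(1), "volume_rate_hz")
  np <- vapply(res, `[[`, integer(1), "planes_np")
  expect_true(all(diff(fv) > 0))
  expect_true(all(diff(np) < 0))
})

test_that("multiplexed scheduling obeys the compounding / line-by-line tradeoffs", {
  kin <- mirror_kinematics(11.95, 250)
  # line-by-line: Fv / nl, positions unchanged
  acq_l <- test_acq(prf_hz = 20000, duration_s = 0.008, n_scan_lines = 3L)
  ml <- multiplex_schedule(acq_l, kin, "line_by_line")
  expect_equal(ml$result$volume_rate_hz, 500 / 3)
  expect_equal(ml$result$sampled_positions, 41L)
  # the sampled elevational angle set is untouched
  plain <- build_schedule(test_acq(prf_hz = 20000, duration_s = 0.008), kin)
  expect_setequal(
    round(unique(ml$schedule$tilt_deg), 9),
    round(unique(plain$tilt_deg), 9)
  )
  expect_equal(sort(unique(ml$schedule$beam_index)), 1:3)

  # compounding at 13.5 kHz PRF with 3 angles: rate kept, positions / 3
  acq_c <- test_acq(prf_hz = 13500, duration_s = 0.008, n_compound_angles = 3L)
  mc <- multiplex_schedule(acq_c, kin, "compound")
  expect_equal(mc$result$volume_rate_hz, 500)
  expect_equal(mc$result$sampled_positions, 9L)
  expect_equal(unique(mc$schedule$steer_index[1:6]), c(1L, 2L, 3L))

  # na = 1 compounding is plane-wave imaging
  acq_p <- test_acq(prf_hz = 20000, duration_s = 0.008)
  mp <- multiplex_schedule(acq_p, kin, "compound")
  rate_p <- volume_rate(20000, kin)
  expect_equal(mp$result$volume_rate_hz, rate_p$volume_rate_hz)
  expect_equal(mp$result$sampled_positions, rate_p$planes_np)
})

test_that("volume rate and planes agree with brute-force enumeration", {
  # reduced version of the acceptance sweep, for fast module-level feedback
  ratios <- random_ratios(40, seed = 101)
  phis <- c(0, pi / 7, pi / 4)
  for (rr in ratios) {
    r <- rr[["num"]] / rr[["den"]]
    for (phi in phis) {
      kin <- mirror_kinematics(10, 250, phase_rad = phi)
      rate <- suppressWarnings(volume_rate(r * 250, kin, m_max = 128L))
      orc <- oracle_rate(r, phi)
      expect_equal(rate$volume_rate_hz, orc$fv,
        info = sprintf("r = %s, phi = %.4f", format(r), phi)
      )
      expect_equal(planes_per_volume(r * 250, rate), orc$np,
        info = sprintf("r = %s, phi = %.4f", format(r), phi)
      )
    }
  }
})
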