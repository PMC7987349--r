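# Shared fixtures. Imaging tests use a reduced aperture (fewer elements than
# the 128-element default) so each frame simulates and beamforms quickly; the
# physics is unchanged.
test_transducer <- function(n_elements = 64L) {
  transducer_model(n_elements = n_elements)
}

test_acq <- function(imaging_depth_mm = 20, duration_s = 0.012,
                     prf_hz = 20000, ...) {
  acquisition_config(
    imaging_depth_mm = imaging_depth_mm, duration_s = duration_s,
    prf_hz = prf_hz, ...
  )
}

point_phantom <- function(x, y, z, amplitude = 1) {
  structure(
    list(
      positions = cbind(x = x, y = y, z = z),
      amplitude = rep(amplitude, length.out = length(x)),
      label = "points"
    ),
    class = "us_phantom"
  )
}

# One complete volume of a partitioned schedule.
first_complete_volume <- function(acq, kin) {
  rate <- volume_rate(effective_prf(acq$prf_hz, acq$n_compound_angles), kin)
  sch <- partition_into_volumes(build_schedule(acq, kin), rate)
  vid <- complete_volume_ids(sch)[1]
  sch[sch$volume_id == vid, , drop = FALSE]
}

# Synthetic constant-intensity B-mode frame at a given scan angle.
constant_frame <- function(value, alpha_deg, x_mm = seq(-2, 2, by = 0.2),
                           d_mm = seq(10, 20, by = 0.1)) {
  env <- matrix(value, length(d_mm), length(x_mm))
  structure(
    list(
      envelope = env, iq = env + 0i, x_mm = x_mm, d_mm = d_mm,
      scan_alpha_deg = alpha_deg, steer_deg = 0
    ),
    class = "bmode_frame"
  )
}
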