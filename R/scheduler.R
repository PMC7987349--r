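# Timing/kinematics core: PRF bounds, sinusoidal tilt trajectory, volume-rate
# regimes, schedule construction, volume partitioning and multiplexed variants.

#' Mirror kinematics of the tilting reflector
#'
#' Parameters of the sinusoidal tilt trajectory
#' `theta(t) = A sin(2 pi Fm t + phi) + gamma`, where `A` is the half-side
#' tilt range, `Fm` the tilting frequency, `phi` the initial phase and `gamma`
#' a constant tilt offset. The reflected scan angle is always twice the tilt
#' angle (law of reflection).
#'
#' @param half_range_deg Half-side tilt amplitude `A` in degrees (>= 0).
#' @param tilt_freq_hz Mirror tilting frequency `Fm` in Hz (> 0).
#' @param phase_rad Initial phase `phi` in radians; normalised to `[0, 2 pi)`.
#' @param offset_deg Tilt offset `gamma` in degrees.
#' @return An object of class `mirror_kinematics`.
#' @examples
#' kin <- mirror_kinematics(11.95, 250)
#' tilt_angle_at(kin, 1e-3)
#' @export
mirror_kinematics <- function(half_range_deg, tilt_freq_hz, phase_rad = 0,
                              offset_deg = 0) {
  if (!is.numeric(half_range_deg) || length(half_range_deg) != 1L ||
      !is.finite(half_range_deg) || half_range_deg < 0) {
    stop("`half_range_deg` must be a single non-negative number", call. = FALSE)
  }
  stop_if_not_scalar_pos(tilt_freq_hz, "tilt_freq_hz")
  structure(
    list(
      half_range_deg = as.numeric(half_range_deg),
      tilt_freq_hz = as.numeric(tilt_freq_hz),
      phase_rad = as.numeric(phase_rad) %% (2 * pi),
      offset_deg = as.numeric(offset_deg)
    ),
    class = "mirror_kinematics"
  )
}

#' @export
print.mirror_kinematics <- function(x, ...) {
  cat(sprintf(
    "Mirror kinematics: A = %.3f deg, Fm = %.6g Hz, phi = %.6g rad, gamma = %.3f deg\n",
    x$half_range_deg, x$tilt_freq_hz, x$phase_rad, x$offset_deg
  ))
  invisible(x)
}

#' Acquisition configuration
#'
#' Pulse-echo acquisition parameters. The pulse repetition frequency must
#' respect the round-trip travel time over the full path (imaging depth plus
#' the transducer-to-mirror distance).
#'
#' @param sound_speed_m_s Speed of sound in the medium (m/s).
#' @param imaging_depth_mm Imaging depth measured from the mirror plate
#'   centre (mm).
#' @param prf_hz Pulse repetition frequency (Hz).
#' @param n_compound_angles Number of compounding transmit angles (>= 1).
#' @param n_scan_lines Number of focused scan lines for line-by-line mode
#'   (>= 1).
#' @param mirror_offset_mm Transducer-to-mirror distance (mm).
#' @param duration_s Acquisition duration (s).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sound_speed_m_s = 1480,
                               imaging_depth_mm = 28.6,
                               prf_hz = 20000,
                               n_compound_angles = 1L,
                               n_scan_lines = 1L,
                               mirror_offset_mm = 2.1,
                               duration_s = 0.012) {
  stop_if_not_scalar_pos(sound_speed_m_s, "sound_speed_m_s")
  stop_if_not_scalar_pos(imaging_depth_mm, "imaging_depth_mm")
  stop_if_not_scalar_pos(prf_hz, "prf_hz")
  if (n_compound_angles < 1) stop("`n_compound_angles` must be >= 1", call. = FALSE)
  if (n_scan_lines < 1) stop("`n_scan_lines` must be >= 1", call. = FALSE)
  prf_max <- sound_speed_m_s / (2 * (imaging_depth_mm + mirror_offset_mm) * 1e-3)
  if (prf_hz > prf_max * (1 + 1e-9)) {
    stop(sprintf(
      "prf_hz = %g exceeds the round-trip limit c/(2 d_total) = %.1f Hz",
      prf_hz, prf_max
    ), call. = FALSE)
  }
  structure(
    list(
      sound_speed_m_s = sound_speed_m_s,
      imaging_depth_mm = imaging_depth_mm,
      prf_hz = prf_hz,
      n_compound_angles = as.integer(n_compound_angles),
      n_scan_lines = as.integer(n_scan_lines),
      mirror_offset_mm = mirror_offset_mm,
      duration_s = duration_s
    ),
    class = "acquisition_config"
  )
}

#' Maximum pulse repetition frequency at a given depth
#'
#' `PRF = c / (2 d)`: one transmit per round-trip travel time.
#'
#' @param sound_speed_m_s Speed of sound (m/s), positive.
#' @param imaging_depth_mm Imaging depth (mm), positive.
#' @return PRF in Hz.
#' @examples
#' prf_from_depth(1500, 30) # 25000 Hz
#' @export
prf_from_depth <- function(sound_speed_m_s, imaging_depth_mm) {
  stop_if_not_scalar_pos(sound_speed_m_s, "sound_speed_m_s")
  stop_if_not_scalar_pos(imaging_depth_mm, "imaging_depth_mm")
  sound_speed_m_s / (2 * imaging_depth_mm * 1e-3)
}

#' Effective PRF under angular compounding
#'
#' Compounding over `na` steering angles divides the per-frame rate:
#' `PRFe = PRF / na`.
#'
#' @param prf_hz Pulse repetition frequency (Hz).
#' @param n_compound_angles Number of compounding angles (>= 1).
#' @return Effective PRF in Hz.
#' @export
effective_prf <- function(prf_hz, n_compound_angles) {
  stop_if_not_scalar_pos(prf_hz, "prf_hz")
  if (!is.numeric(n_compound_angles) || length(n_compound_angles) != 1L ||
      n_compound_angles < 1) {
    stop("`n_compound_angles` must be >= 1", call. = FALSE)
  }
  prf_hz / n_compound_angles
}

#' Tilt angle of the mirror at a given time
#'
#' Evaluates `theta(t) = A sin(2 pi Fm t + phi) + gamma` in degrees.
#'
#' @param kin A [mirror_kinematics()] object.
#' @param time_s Time(s) in seconds (vectorised).
#' @return Tilt angle(s) in degrees.
#' @export
tilt_angle_at <- function(kin, time_s) {
  stopifnot(inherits(kin, "mirror_kinematics"))
  kin$half_range_deg * sin(2 * pi * kin$tilt_freq_hz * time_s + kin$phase_rad) +
    kin$offset_deg
}

#' Scan angle of the reflected beam at a given time
#'
#' The reflected beam turns by exactly twice the mechanical tilt:
#' `alpha = 2 theta`.
#'
#' @inheritParams tilt_angle_at
#' @return Scan angle(s) in degrees.
#' @export
scan_angle_at <- function(kin, time_s) {
  2 * tilt_angle_at(kin, time_s)
}

#' Volume rate and sampling regime
#'
#' Classifies the ratio `r = PRFe / Fm` of effective pulse rate to mirror
#' tilting frequency. Under condition 1 (`r` an even integer and
#' `(r / pi) phi` an integer) every elevational location is imaged twice per
#' tilting cycle and the volume rate is `2 Fm`. Otherwise (condition 2) the
#' sampled-angle sequence repeats every `m` mirror cycles, where `m` is the
#' smallest positive integer with `m r` integer, and the volume rate is
#' `Fm / m`.
#'
#' @param effective_prf_hz Effective PRF in Hz (> 0).
#' @param kin A [mirror_kinematics()] object.
#' @param tol Relative tolerance for the integer/evenness tests.
#' @param m_max Largest repetition multiplier searched; ratios needing more
#'   are rejected as non-repeating.
#' @return An object of class `rate_result` with fields `volume_rate_hz`,
#'   `regime` (`"condition1"` or `"condition2"`), `multiplier_m`, `planes_np`,
#'   `peak_sampled` (whether any transmit lands on a sweep extremum),
#'   `period_samples` and the inputs.
#' @examples
#' kin <- mirror_kinematics(11.95, 250)
#' volume_rate(20000, kin) # condition 1, 500 Hz
#' volume_rate(1062.5, kin) # condition 2, m = 4, 62.5 Hz
#' @export
volume_rate <- function(effective_prf_hz, kin, tol = 1e-9, m_max = 64L) {
  stop_if_not_scalar_pos(effective_prf_hz, "effective_prf_hz")
  stopifnot(inherits(kin, "mirror_kinematics"))
  fm <- kin$tilt_freq_hz
  phi <- kin$phase_rad
  r <- effective_prf_hz / fm

  cond1 <- near_int(r, tol) && (round(r) %% 2 == 0) && near_int(r * phi / pi, tol)
  if (cond1 && phi != 0) {
    warning(
      "condition-1 classification at nonzero initial phase (phi = ",
      format(phi), "); the even-ratio regime is phase-sensitive",
      call. = FALSE
    )
  }
  if (cond1) {
    m <- NA_integer_
    fv <- 2 * fm
    period <- as.integer(round(r))
  } else {
    m <- NA_integer_
    for (k in seq_len(m_max)) {
      if (near_int(k * r, tol)) {
        m <- as.integer(k)
        break
      }
    }
    if (is.na(m)) {
      stop(sprintf(
        "non-repeating schedule: no multiplier m <= %d makes m * (PRFe/Fm) an integer",
        m_max
      ), call. = FALSE)
    }
    fv <- fm / m
    period <- as.integer(round(m * r))
  }

  u <- (2 * pi * seq_len(period) / r + phi - pi / 2) / pi
  peak <- any(abs(u - round(u)) < 1e-9)
  np <- as.integer(round(effective_prf_hz / fv)) + as.integer(cond1 && peak)

  structure(
    list(
      volume_rate_hz = fv,
      regime = if (cond1) "condition1" else "condition2",
      multiplier_m = m,
      planes_np = np,
      peak_sampled = peak,
      effective_prf_hz = effective_prf_hz,
      tilt_freq_hz = fm,
      phase_rad = phi,
      period_samples = period
    ),
    class = "rate_result"
  )
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "Volume rate %.6g Hz (%s%s), %d planes per volume, peak %ssampled\n",
    x$volume_rate_hz, x$regime,
    if (!is.na(x$multiplier_m)) sprintf(", m = %d", x$multiplier_m) else "",
    x$planes_np, if (x$peak_sampled) "" else "not "
  ))
  invisible(x)
}

#' Number of imaging planes sampled in one volume
#'
#' `Np = PRFe / Fv`, plus one extra plane under condition 1 when the sweep
#' extrema are themselves sampled (the extremal plane is then shared by the
#' two adjacent half-sweep volumes).
#'
#' @param effective_prf_hz Effective PRF in Hz.
#' @param rate A `rate_result` from [volume_rate()].
#' @return Integer count of planes per volume.
#' @export
planes_per_volume <- function(effective_prf_hz, rate) {
  stopifnot(inherits(rate, "rate_result"))
  q <- effective_prf_hz / rate$volume_rate_hz
  if (!near_int(q)) {
    stop("internal inconsistency: PRFe / Fv is not an integer", call. = FALSE)
  }
  as.integer(round(q)) +
    as.integer(rate$regime == "condition1" && rate$peak_sampled)
}

#' Build the transmit schedule against the tilting mirror
#'
#' Samples the tilt trajectory at `t_n = n / PRFe`, `n = 1, 2, ...` over the
#' configured duration. Scan angles are exactly twice the tilt angles.
#'
#' @param acq An [acquisition_config()] object.
#' @param kin A [mirror_kinematics()] object.
#' @return A `plane_schedule` data frame with columns `index`, `time_s`,
#'   `tilt_deg`, `scan_deg`, `volume_id` (NA until
#'   [partition_into_volumes()]), `sweep_dir`.
#' @export
build_schedule <- function(acq, kin) {
  stopifnot(inherits(acq, "acquisition_config"), inherits(kin, "mirror_kinematics"))
  prfe <- effective_prf(acq$prf_hz, acq$n_compound_angles)
  n_max <- floor(acq$duration_s * prfe + 1e-9)
  n <- if (n_max >= 1) seq_len(n_max) else integer(0)
  time_s <- n / prfe
  tilt <- tilt_angle_at(kin, time_s)
  sch <- data.frame(
    index = as.integer(n),
    time_s = time_s,
    tilt_deg = tilt,
    scan_deg = 2 * tilt,
    volume_id = rep(NA_integer_, length(n)),
    sweep_dir = rep(NA_character_, length(n)),
    stringsAsFactors = FALSE
  )
  attr(sch, "effective_prf_hz") <- prfe
  attr(sch, "kinematics") <- kin
  class(sch) <- c("plane_schedule", "data.frame")
  sch
}

#' Assign transmit samples to imaging volumes
#'
#' Under condition 1 a volume is one monotonic half-sweep of the tilt
#' trajectory between consecutive extrema; samples landing exactly on an
#' extremum are shared by (duplicated into) both adjacent volumes. Under
#' condition 2 a volume is one full repetition period of the sampled-angle
#' sequence (`m` mirror cycles).
#'
#' @param schedule A `plane_schedule` from [build_schedule()].
#' @param rate A `rate_result` from [volume_rate()] for the same
#'   configuration.
#' @return The schedule with `volume_id` and `sweep_dir` filled (rows at
#'   shared extrema appear once per adjacent volume), ordered by time then
#'   volume. Volume ids start at 1; leading/trailing volumes may be
#'   incomplete (fewer than `planes_np` rows).
#' @export
partition_into_volumes <- function(schedule, rate) {
  stopifnot(inherits(schedule, "plane_schedule"), inherits(rate, "rate_result"))
  if (nrow(schedule) < rate$planes_np) {
    stop("schedule shorter than one volume", call. = FALSE)
  }
  kin <- attr(schedule, "kinematics")
  out <- schedule
  if (rate$regime == "condition1") {
    psi <- 2 * pi * rate$tilt_freq_hz * schedule$time_s + kin$phase_rad
    u <- (psi - pi / 2) / pi
    at_peak <- abs(u - round(u)) < 1e-9
    base <- ifelse(at_peak, round(u), floor(u))
    out$volume_id <- as.integer(base)
    extra <- schedule[at_peak, , drop = FALSE]
    extra$volume_id <- as.integer(base[at_peak] - 1)
    out <- rbind(as.data.frame(out), as.data.frame(extra))
    out$sweep_dir <- ifelse(out$volume_id %% 2 == 0, "down", "up")
    out$volume_id <- out$volume_id - min(out$volume_id) + 1L
    out <- out[order(out$time_s, out$volume_id), , drop = FALSE]
  } else {
    out$volume_id <- (out$index - 1L) %/% rate$period_samples + 1L
    out$sweep_dir <- "period"
    out <- as.data.frame(out)
  }
  rownames(out) <- NULL
  attr(out, "effective_prf_hz") <- attr(schedule, "effective_prf_hz")
  attr(out, "kinematics") <- kin
  attr(out, "rate") <- rate
  class(out) <- c("plane_schedule", "data.frame")
  out
}

#' Ids of complete volumes in a partitioned schedule
#'
#' @param schedule A partitioned `plane_schedule`.
#' @return Integer vector of `volume_id`s whose sample count equals the
#'   planes-per-volume of the schedule's rate.
#' @export
complete_volume_ids <- function(schedule) {
  rate <- attr(schedule, "rate")
  if (is.null(rate)) stop("schedule has not been partitioned", call. = FALSE)
  sizes <- table(schedule$volume_id)
  as.integer(names(sizes)[sizes == rate$planes_np])
}

#' Multiplexed scheduling: compounding and line-by-line variants
#'
#' In `compound` mode consecutive transmissions cycle through the steering
#' angles at the full PRF; the volume rate is unchanged relative to the
#' compounded effective PRF but the number of distinct elevational positions
#' per volume drops by the number of angles. In `line_by_line` mode each
#' focused beam occupies a full sweep, so the volume rate divides by the
#' number of lines while the sampled elevational positions are unchanged.
#'
#' @param acq An [acquisition_config()] object (`n_compound_angles` /
#'   `n_scan_lines` select the multiplex factor).
#' @param kin A [mirror_kinematics()] object.
#' @param mode `"compound"` or `"line_by_line"`.
#' @return A list with `result` (class `multiplex_result`: `mode`,
#'   `volume_rate_hz`, `sampled_positions`, underlying `rate`) and
#'   `schedule` (annotated with `steer_index`/`frame_index` or
#'   `beam_index`).
#' @export
multiplex_schedule <- function(acq, kin, mode = c("compound", "line_by_line")) {
  stopifnot(inherits(acq, "acquisition_config"), inherits(kin, "mirror_kinematics"))
  mode <- match.arg(mode)
  if (mode == "compound") {
    na <- acq$n_compound_angles
    prfe <- acq$prf_hz / na
    rate <- volume_rate(prfe, kin)
    n_max <- floor(acq$duration_s * acq$prf_hz + 1e-9)
    n <- if (n_max >= 1) seq_len(n_max) else integer(0)
    time_s <- n / acq$prf_hz
    tilt <- tilt_angle_at(kin, time_s)
    sch <- data.frame(
      index = as.integer(n),
      time_s = time_s,
      tilt_deg = tilt,
      scan_deg = 2 * tilt,
      steer_index = as.integer((n - 1L) %% na + 1L),
      frame_index = as.integer((n - 1L) %/% na + 1L),
      stringsAsFactors = FALSE
    )
    result <- structure(
      list(
        mode = mode,
        volume_rate_hz = rate$volume_rate_hz,
        sampled_positions = rate$planes_np,
        rate = rate
      ),
      class = "multiplex_result"
    )
    list(result = result, schedule = sch)
  } else {
    nl <- acq$n_scan_lines
    acq1 <- acq
    acq1$n_compound_angles <- 1L
    rate <- volume_rate(acq$prf_hz, kin)
    sch <- build_schedule(acq1, kin)
    sch <- partition_into_volumes(sch, rate)
    sch$beam_index <- as.integer((sch$volume_id - 1L) %% nl + 1L)
    result <- structure(
      list(
        mode = mode,
        volume_rate_hz = rate$volume_rate_hz / nl,
        sampled_positions = rate$planes_np,
        rate = rate
      ),
      class = "multiplex_result"
    )
    list(result = result, schedule = sch)
  }
}

#' @export
print.multiplex_result <- function(x, ...) {
  cat(sprintf(
    "%s mode: volume rate %.6g Hz, %d sampled elevational positions per volume\n",
    x$mode, x$volume_rate_hz, x$sampled_positions
  ))
  invisible(x)
}

#' Write a transmit schedule to CSV
#'
#' @param schedule A `plane_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  cols <- intersect(
    c("index", "time_s", "tilt_deg", "scan_deg", "volume_id", "sweep_dir",
      "steer_index", "frame_index", "beam_index"),
    names(schedule)
  )
  write.csv(as.data.frame(schedule)[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
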