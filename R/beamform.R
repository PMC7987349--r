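# Delay-and-sum beamforming of plane-wave RF frames into B-mode images,
# coherent compounding, and the mechanical-translation comparison mode.

# Analytic signal (FFT Hilbert transform) of each column of a real matrix.
# Columns are zero-padded to an FFT-friendly length; echoes decay before the
# record end, so the periodic-extension edge effect is negligible.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n0 <- nrow(x)
  n <- stats::nextn(n0)
  if (n > n0) x <- rbind(x, matrix(0, n - n0, ncol(x)))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  out <- mvfft(mvfft(x) * h, inverse = TRUE) / n
  out[seq_len(n0), , drop = FALSE]
}

#' Delay-and-sum beamforming of one plane-wave RF frame
#'
#' Per pixel, channel samples are summed at the two-way delay (steered
#' plane-wave transmit arrival plus per-element return path, both including
#' the transducer-to-mirror distance) with linear interpolation in time.
#' Beamforming operates on the analytic signal so that the envelope is the
#' magnitude of the complex sum; all elements receive (no f-number aperture
#' growth) with rectangular apodization by default.
#'
#' @param frame An `rf_frame` from [simulate_rf()].
#' @param tx The [transducer_model()] used for the frame.
#' @param acq The [acquisition_config()] used for the frame.
#' @param grid List with `x_mm` (lateral pixel positions) and `d_mm` (depth
#'   pixel positions, from the mirror centre). Defaults to the full aperture
#'   at half-wavelength axial and one-pitch lateral spacing.
#' @param apodization `"rect"` or `"hann"` receive apodization.
#' @return A `bmode_frame`: `envelope` (depth x lateral, linear), `iq`
#'   (complex pre-envelope data for compounding), `x_mm`, `d_mm`,
#'   `scan_alpha_deg`, `steer_deg`.
#' @export
das_beamform <- function(frame, tx, acq, grid = NULL,
                         apodization = c("rect", "hann")) {
  stopifnot(inherits(frame, "rf_frame"), inherits(tx, "transducer_model"))
  apodization <- match.arg(apodization)
  ex <- element_positions(tx)
  if (is.null(grid)) {
    lambda_mm <- acq$sound_speed_m_s / (tx$center_freq_mhz * 1e6) * 1e3
    grid <- list(
      x_mm = ex,
      d_mm = seq(acq$mirror_offset_mm + 1, acq$imaging_depth_mm,
        by = lambda_mm / 2
      )
    )
  }
  nt <- nrow(frame$channel_data)
  max_tau <- 2 * (max(grid$d_mm) + acq$mirror_offset_mm) * 1e-3 /
    acq$sound_speed_m_s
  if (max_tau > frame$t0_s + nt / frame$fs_hz) {
    stop("grid outside recorded time window", call. = FALSE)
  }
  apod <- if (apodization == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(tx$n_elements) - 1) / (tx$n_elements - 1))
  } else {
    rep(1, tx$n_elements)
  }
  iq <- analytic_signal(frame$channel_data)
  nd <- length(grid$d_mm)
  nx <- length(grid$x_mm)
  px <- rep(grid$x_mm, each = nd) * 1e-3
  pd <- rep(grid$d_mm, times = nx) * 1e-3
  res <- das_core(
    Re(iq), Im(iq), ex * 1e-3, apod, acq$sound_speed_m_s, frame$fs_hz,
    frame$t0_s, deg2rad(frame$steer_deg), acq$mirror_offset_mm * 1e-3, px, pd
  )
  z <- matrix(complex(real = res$re, imaginary = res$im), nrow = nd, ncol = nx)
  structure(
    list(
      envelope = Mod(z), iq = z, x_mm = grid$x_mm, d_mm = grid$d_mm,
      scan_alpha_deg = frame$scan_alpha_deg, steer_deg = frame$steer_deg
    ),
    class = "bmode_frame"
  )
}

#' @export
print.bmode_frame <- function(x, ...) {
  cat(sprintf(
    "B-mode frame: %d depth x %d lateral pixels, alpha = %.2f deg\n",
    length(x$d_mm), length(x$x_mm), x$scan_alpha_deg
  ))
  invisible(x)
}

#' Log compression of a linear envelope
#'
#' `20 log10(envelope / max)`, clipped at the stated dynamic range.
#'
#' @param envelope Non-negative linear envelope (matrix or array).
#' @param dynamic_range_db Display dynamic range in dB (positive).
#' @return dB image in `[-dynamic_range_db, 0]`.
#' @export
log_compress <- function(envelope, dynamic_range_db = 40) {
  m <- max(envelope)
  if (m == 0) {
    return(array(-dynamic_range_db, dim = dim(envelope)))
  }
  pmax(20 * log10(pmax(envelope, .Machine$double.xmin) / m), -dynamic_range_db)
}

#' Coherent compounding of beamformed frames
#'
#' Sums the pre-envelope (complex) beamformed data of steered transmissions
#' sharing a pixel grid, then takes the envelope.
#'
#' @param frames List of `bmode_frame`s on identical grids.
#' @return A `bmode_frame` with the compounded data.
#' @export
compound <- function(frames) {
  if (!length(frames)) stop("no frames to compound", call. = FALSE)
  ref <- frames[[1]]
  for (f in frames[-1]) {
    if (!isTRUE(all.equal(f$x_mm, ref$x_mm)) ||
        !isTRUE(all.equal(f$d_mm, ref$d_mm))) {
      stop("mismatched grids: frames must share the pixel grid", call. = FALSE)
    }
  }
  iq <- Reduce(`+`, lapply(frames, `[[`, "iq"))
  out <- ref
  out$iq <- iq
  out$envelope <- Mod(iq)
  out$steer_deg <- vapply(frames, `[[`, numeric(1), "steer_deg")
  out
}

#' Mechanical-translation scanning (benchmark mode)
#'
#' Simulates the conventional 3-D benchmark in which the transducer is
#' translated elevationally in fixed steps with the mirror static at zero
#' scan angle: each frame images the scene shifted by the step offset.
#'
#' @param phantom A `us_phantom`.
#' @param tx A [transducer_model()].
#' @param acq An [acquisition_config()].
#' @param step_mm Translation step (mm, > 0).
#' @param n_steps Number of positions.
#' @param y_start_mm Elevational position of the first frame (mm).
#' @param grid Pixel grid passed to [das_beamform()].
#' @param snr_db Per-channel SNR (dB).
#' @param seed Optional base seed; position `k` uses `seed + k`.
#' @return A `translation_sweep`: list with `frames` (B-mode frames) and
#'   `y_mm` (elevational positions).
#' @export
translate_scan <- function(phantom, tx, acq, step_mm = 0.5, n_steps = 41L,
                           y_start_mm = 0, grid = NULL, snr_db = Inf,
                           seed = NULL) {
  if (step_mm <= 0) stop("`step_mm` must be positive", call. = FALSE)
  ys <- y_start_mm + (seq_len(n_steps) - 1) * step_mm
  frames <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    ph <- phantom
    ph$positions[, "y"] <- ph$positions[, "y"] - ys[k]
    rf <- simulate_rf(ph, tx, acq,
      scan_alpha_deg = 0, steer_deg = 0, snr_db = snr_db,
      seed = if (is.null(seed)) NULL else seed + k
    )
    frames[[k]] <- das_beamform(rf, tx, acq, grid = grid)
  }
  structure(list(frames = frames, y_mm = ys), class = "translation_sweep")
}

#' Export a B-mode frame
#'
#' `write_bmode_tiff()` stores the linear envelope as 32-bit float TIFF
#' (scaled to `[0, 1]`, scale recorded in a JSON sidecar);
#' `write_bmode_png()` stores the log-compressed image as 8-bit PNG with the
#' dynamic range in the sidecar.
#'
#' @param frame A `bmode_frame`.
#' @param path Output path.
#' @param dynamic_range_db Dynamic range for log compression (PNG only).
#' @return `path`, invisibly.
#' @export
write_bmode_tiff <- function(frame, path) {
  m <- max(frame$envelope)
  img <- if (m > 0) frame$envelope / m else frame$envelope
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = m, x_mm = frame$x_mm, d_mm = frame$d_mm,
         scan_alpha_deg = frame$scan_alpha_deg, units = "linear envelope / scale"),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_bmode_tiff
#' @export
write_bmode_png <- function(frame, path, dynamic_range_db = 40) {
  db <- log_compress(frame$envelope, dynamic_range_db)
  png::writePNG((db + dynamic_range_db) / dynamic_range_db, path)
  jsonlite::write_json(
    list(dynamic_range_db = dynamic_range_db, x_mm = frame$x_mm,
         d_mm = frame$d_mm, scan_alpha_deg = frame$scan_alpha_deg),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
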