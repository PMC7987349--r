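# Image-quality metrics: contrast-to-noise ratio, FWHM resolution, rms
# intensity. All statistics are computed on linear (pre-log-compression)
# envelope intensities: the CNR variance semantics do not survive dB data.

#' Rectangular region of interest
#'
#' @param center_mm Length-3 centre `(x, y, z)` in mm.
#' @param half_extents_mm Length-3 half-extents in mm.
#' @return An object of class `roi`.
#' @export
roi <- function(center_mm, half_extents_mm) {
  stopifnot(length(center_mm) == 3L, length(half_extents_mm) == 3L)
  if (any(half_extents_mm <= 0)) stop("half extents must be positive", call. = FALSE)
  structure(
    list(center_mm = as.numeric(center_mm),
         half_extents_mm = as.numeric(half_extents_mm)),
    class = "roi"
  )
}

roi_values <- function(volume, r) {
  stopifnot(inherits(volume, "us_volume"), inherits(r, "roi"))
  ix <- which(abs(volume$x_mm - r$center_mm[1]) <= r$half_extents_mm[1])
  iy <- which(abs(volume$y_mm - r$center_mm[2]) <= r$half_extents_mm[2])
  iz <- which(abs(volume$z_mm - r$center_mm[3]) <= r$half_extents_mm[3])
  if (!length(ix) || !length(iy) || !length(iz)) {
    stop("ROI contains no voxels", call. = FALSE)
  }
  if (!all(volume$mask[ix, iy, iz])) {
    stop("ROI touches masked (out-of-wedge) voxels", call. = FALSE)
  }
  as.numeric(volume$intensity[ix, iy, iz])
}

rois_overlap <- function(a, b) {
  all(abs(a$center_mm - b$center_mm) < a$half_extents_mm + b$half_extents_mm)
}

#' Contrast-to-noise ratio between a target and a background region
#'
#' `CNR = |St - Sb| / sqrt(vt + vb)` on linear intensities, where `St`, `Sb`
#' are the region means and `vt`, `vb` the region variances. Contrast is
#' additionally reported in dB as `20 log10(max(St, Sb) / min(St, Sb))`.
#'
#' @param volume A `us_volume`.
#' @param target_roi,background_roi Non-overlapping [roi()]s lying entirely
#'   inside valid voxels.
#' @return A `cnr_report`: `mean_target`, `mean_background`, `var_target`,
#'   `var_background`, `contrast_db`, `cnr`.
#' @examples
#' # closed form: St = 10, Sb = 2, vt = vb = 2 -> CNR = 8 / sqrt(4) = 4
#' @export
cnr <- function(volume, target_roi, background_roi) {
  if (rois_overlap(target_roi, background_roi)) {
    stop("target and background ROIs overlap", call. = FALSE)
  }
  vt <- roi_values(volume, target_roi)
  vb <- roi_values(volume, background_roi)
  cnr_from_samples(vt, vb)
}

#' @rdname cnr
#' @param target_values,background_values Raw linear intensity samples, for
#'   computing the statistics without a volume container.
#' @export
cnr_from_samples <- function(target_values, background_values) {
  st <- mean(target_values)
  sb <- mean(background_values)
  vt <- var(target_values)
  vb <- var(background_values)
  structure(
    list(
      mean_target = st, mean_background = sb,
      var_target = vt, var_background = vb,
      contrast_db = 20 * log10(max(st, sb) / min(st, sb)),
      cnr = abs(st - sb) / sqrt(vt + vb)
    ),
    class = "cnr_report"
  )
}

#' @export
print.cnr_report <- function(x, ...) {
  cat(sprintf(
    "CNR %.3f, contrast %.2f dB (St = %.4g, Sb = %.4g)\n",
    x$cnr, x$contrast_db, x$mean_target, x$mean_background
  ))
  invisible(x)
}

#' Full width at half maximum of a profile
#'
#' Width between the half-maximum crossings around the highest peak, with
#' linear interpolation between samples. Errors with "unresolved" when the
#' profile does not drop below half maximum on both sides.
#'
#' @param positions_mm Sample positions (mm), strictly increasing.
#' @param intensities Non-negative profile values.
#' @return FWHM in mm.
#' @examples
#' x <- seq(-5, 5, by = 0.05)
#' fwhm(x, exp(-x^2 / 2)) # ~2.355 for sigma = 1
#' @export
fwhm <- function(positions_mm, intensities) {
  stopifnot(length(positions_mm) == length(intensities), length(positions_mm) >= 3L)
  i <- which.max(intensities)
  half <- intensities[i] / 2
  below_l <- which(intensities[seq_len(i - 1)] < half)
  below_r <- which(intensities[(i + 1):length(intensities)] < half) + i
  if (!length(below_l) || !length(below_r)) {
    stop("unresolved: profile does not cross half maximum on both sides",
      call. = FALSE
    )
  }
  il <- max(below_l)
  left <- approx(
    x = intensities[c(il, il + 1)], y = positions_mm[c(il, il + 1)],
    xout = half
  )$y
  ir <- min(below_r)
  right <- approx(
    x = intensities[c(ir - 1, ir)], y = positions_mm[c(ir - 1, ir)],
    xout = half
  )$y
  right - left
}

#' Root-mean-square intensity of a signal
#'
#' `sqrt(mean(x^2))`, optionally after zero-phase low-pass filtering
#' (4th-order Butterworth via `signal::filtfilt`) and windowing, matching
#' how raw channel signals are reduced to an intensity value.
#'
#' @param x Signal samples (non-empty).
#' @param fs_hz Sampling rate, required when `cutoff_hz` is given.
#' @param cutoff_hz Optional low-pass cutoff (Hz).
#' @param window `"none"` or `"hann"` applied before the rms.
#' @return rms value.
#' @export
rms_intensity <- function(x, fs_hz = NULL, cutoff_hz = NULL,
                          window = c("none", "hann")) {
  if (!length(x)) stop("empty signal", call. = FALSE)
  window <- match.arg(window)
  if (!is.null(cutoff_hz)) {
    if (is.null(fs_hz)) stop("`fs_hz` is required for filtering", call. = FALSE)
    bf <- signal::butter(4, cutoff_hz / (fs_hz / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  if (window == "hann") {
    n <- length(x)
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  sqrt(mean(x^2))
}

#' Elevational profile of a volume at a lateral/axial location
#'
#' Convenience extractor for resolution measurements: intensity along `y`
#' at the voxel column nearest to `(x, z)`.
#'
#' @param volume A `us_volume`.
#' @param x_mm,z_mm Location (mm).
#' @return List with `y_mm` and `intensity` (NA outside the wedge removed).
#' @export
elevational_profile <- function(volume, x_mm = 0, z_mm) {
  ix <- which.min(abs(volume$x_mm - x_mm))
  iz <- which.min(abs(volume$z_mm - z_mm))
  v <- volume$intensity[ix, , iz]
  ok <- !is.na(v)
  list(y_mm = volume$y_mm[ok], intensity = v[ok])
}

#' Intensity-weighted centroids of wire cross sections
#'
#' Segments the volume around each expected wire position (within a window
#' in `y` and `z`, summing over the wire axis `x`) and returns the
#' intensity-weighted centroid of the voxels above a -6 dB threshold
#' relative to the local peak.
#'
#' @param volume A `us_volume` of a wire phantom (wires along `x`).
#' @param expected_y_mm,expected_z_mm Nominal wire positions (mm).
#' @param window_mm Half-window around the nominal position (mm).
#' @param threshold_db Segmentation threshold below the local peak (dB).
#' @return Data frame with columns `y_mm`, `z_mm` (one row per wire).
#' @export
wire_centroids <- function(volume, expected_y_mm, expected_z_mm,
                           window_mm = 1.2, threshold_db = -6) {
  stopifnot(length(expected_y_mm) == length(expected_z_mm))
  res <- data.frame(y_mm = numeric(0), z_mm = numeric(0))
  img <- apply(volume$intensity, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  })
  thr <- 10^(threshold_db / 20)
  for (w in seq_along(expected_y_mm)) {
    iy <- which(abs(volume$y_mm - expected_y_mm[w]) <= window_mm)
    iz <- which(abs(volume$z_mm - expected_z_mm[w]) <= window_mm)
    sub <- img[iy, iz, drop = FALSE]
    if (all(is.na(sub))) {
      res[w, ] <- c(NA_real_, NA_real_)
      next
    }
    pk <- max(sub, na.rm = TRUE)
    wgt <- ifelse(!is.na(sub) & sub >= thr * pk, sub, 0)
    Y <- matrix(volume$y_mm[iy], length(iy), length(iz))
    Z <- matrix(volume$z_mm[iz], length(iy), length(iz), byrow = TRUE)
    res[w, ] <- c(sum(wgt * Y) / sum(wgt), sum(wgt * Z) / sum(wgt))
  }
  res
}

#' Write metric rows to CSV
#'
#' @param df Data frame of metric rows (e.g. depth, mode, seed, value).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
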