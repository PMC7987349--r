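# Scan conversion of per-plane B-mode frames into a Cartesian 3-D volume:
# each frame's (x, d) pixels live at (y, z) = (d sin(alpha), d cos(alpha)),
# and the regular grid is filled by linear interpolation across the
# (nonuniformly spaced) scan angles and bilinearly in-plane.

#' Scan-convert a polar sample to Cartesian coordinates
#'
#' `(y, z) = (d sin(alpha), d cos(alpha))` with the origin at the mirror
#' plate centre; the lateral coordinate is unchanged by scan conversion.
#'
#' @param depth_mm Depth(s) from the mirror centre (mm, >= 0).
#' @param scan_alpha_deg Scan angle(s) in degrees.
#' @return Matrix with columns `y` and `z` (mm).
#' @examples
#' scan_convert_point(20, 30) # y = 10, z = 17.32
#' @export
scan_convert_point <- function(depth_mm, scan_alpha_deg) {
  if (any(depth_mm < 0)) stop("`depth_mm` must be >= 0", call. = FALSE)
  a <- deg2rad(scan_alpha_deg)
  cbind(y = depth_mm * sin(a), z = depth_mm * cos(a))
}

#' Field-of-view extent of the swept wedge
#'
#' The scan angle spans twice the total tilt range (law of reflection), so
#' `angle_range = 2 * (2 A)`; the chord subtended at a given depth is
#' `2 d sin(angle_range / 2)`.
#'
#' @param depth_mm Depth at which the chord is evaluated (mm, > 0).
#' @param kin A [mirror_kinematics()] object.
#' @return List with `angle_range_deg` and `chord_mm`.
#' @examples
#' fov_extent(25, mirror_kinematics(11.95, 250)) # ~48 deg, ~20 mm
#' @export
fov_extent <- function(depth_mm, kin) {
  stop_if_not_scalar_pos(depth_mm, "depth_mm")
  stopifnot(inherits(kin, "mirror_kinematics"))
  angle_range <- 2 * (2 * kin$half_range_deg)
  list(
    angle_range_deg = angle_range,
    chord_mm = 2 * depth_mm * sin(deg2rad(angle_range) / 2)
  )
}

#' Reconstruct a Cartesian 3-D volume from a sweep of B-mode frames
#'
#' Frames (all sharing the same lateral and depth pixel axes) are placed at
#' their scan angles and resampled onto a regular Cartesian grid: linear
#' interpolation in the scan angle `alpha` (not in sample index, since the
#' sinusoidal sweep makes plane position a nonlinear function of time) and
#' linear interpolation in depth; the lateral axis is carried over unchanged.
#' Voxels outside the sampled wedge are `NA` and flagged in an explicit
#' validity mask. Frames sharing an angle (the double coverage of the
#' even-ratio regime) are combined first.
#'
#' @param frames List of `bmode_frame`s spanning at least two distinct scan
#'   angles.
#' @param grid_spec Optional list with `y_mm` and `z_mm` voxel-centre
#'   vectors and/or `voxel_mm` spacing (default 0.1 mm). The lateral axis is
#'   always the frames' `x_mm`.
#' @param duplicate_policy How to combine frames at the same angle:
#'   `"mean"`, `"first"` or `"last"`.
#' @return A `us_volume`: `intensity` (x by y by z array, linear units, `NA`
#'   outside the wedge), `mask` (same shape, `TRUE` where valid), axis
#'   vectors `x_mm`, `y_mm`, `z_mm`, `spacing_mm`, `origin_mm` (the mirror
#'   plate centre at `(0, 0, 0)`), and the sampled `angles_deg`.
#' @export
reconstruct_volume <- function(frames, grid_spec = NULL,
                               duplicate_policy = c("mean", "first", "last")) {
  duplicate_policy <- match.arg(duplicate_policy)
  if (!length(frames)) stop("no frames", call. = FALSE)
  ref <- frames[[1]]
  for (f in frames[-1]) {
    if (!isTRUE(all.equal(f$x_mm, ref$x_mm)) ||
        !isTRUE(all.equal(f$d_mm, ref$d_mm))) {
      stop("frames must share the pixel grid", call. = FALSE)
    }
  }
  alphas_raw <- vapply(frames, `[[`, numeric(1), "scan_alpha_deg")
  key <- round(alphas_raw, 6)
  groups <- split(seq_along(frames), key)
  alphas <- as.numeric(names(groups))
  envs <- lapply(groups, function(idx) {
    if (length(idx) == 1L || duplicate_policy == "first") {
      frames[[idx[1]]]$envelope
    } else if (duplicate_policy == "last") {
      frames[[idx[length(idx)]]]$envelope
    } else {
      Reduce(`+`, lapply(idx, function(i) frames[[i]]$envelope)) / length(idx)
    }
  })
  ord <- order(alphas)
  alphas <- alphas[ord]
  envs <- envs[ord]
  if (length(alphas) < 2L) {
    stop("cannot interpolate elevationally: fewer than 2 distinct scan angles",
      call. = FALSE
    )
  }

  daxis <- ref$d_mm
  dmin <- min(daxis)
  dmax <- max(daxis)
  amax <- max(abs(alphas))
  if (is.null(grid_spec)) grid_spec <- list()
  voxel <- if (!is.null(grid_spec$voxel_mm)) grid_spec$voxel_mm else 0.1
  y_mm <- if (!is.null(grid_spec$y_mm)) grid_spec$y_mm else {
    ylim <- dmax * sin(deg2rad(range(alphas)))
    seq(ylim[1], ylim[2], by = voxel)
  }
  z_mm <- if (!is.null(grid_spec$z_mm)) grid_spec$z_mm else {
    seq(dmin * cos(deg2rad(amax)), dmax, by = voxel)
  }
  x_mm <- ref$x_mm
  nx <- length(x_mm)
  ny <- length(y_mm)
  nz <- length(z_mm)
  nd <- length(daxis)

  Y <- matrix(y_mm, ny, nz)
  Z <- matrix(z_mm, ny, nz, byrow = TRUE)
  D <- sqrt(Y^2 + Z^2)
  A <- rad2deg(atan2(Y, Z))
  eps <- 1e-9
  valid <- A >= alphas[1] - eps & A <= alphas[length(alphas)] + eps &
    D >= dmin - eps & D <= dmax + eps
  k <- findInterval(A, alphas, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(alphas) - 1L)

  vol_mat <- matrix(NA_real_, nx, ny * nz)
  sel_all <- which(valid)
  for (kk in unique(k[sel_all])) {
    sel <- sel_all[k[sel_all] == kk]
    if (!length(sel)) next
    w <- (A[sel] - alphas[kk]) / (alphas[kk + 1] - alphas[kk])
    dsel <- pmin(pmax(D[sel], dmin), dmax)
    id <- findInterval(dsel, daxis, rightmost.closed = TRUE)
    id <- pmin(pmax(id, 1L), nd - 1L)
    fd <- (dsel - daxis[id]) / (daxis[id + 1] - daxis[id])
    E1 <- envs[[kk]]
    E2 <- envs[[kk + 1]]
    F1 <- E1[id, , drop = FALSE] * (1 - fd) + E1[id + 1L, , drop = FALSE] * fd
    F2 <- E2[id, , drop = FALSE] * (1 - fd) + E2[id + 1L, , drop = FALSE] * fd
    vol_mat[, sel] <- t(F1 * (1 - w) + F2 * w)
  }

  intensity <- array(vol_mat, dim = c(nx, ny, nz))
  mask <- array(rep(valid, each = nx), dim = c(nx, ny, nz))
  structure(
    list(
      intensity = intensity, mask = mask,
      x_mm = x_mm, y_mm = y_mm, z_mm = z_mm,
      spacing_mm = c(
        if (nx > 1) x_mm[2] - x_mm[1] else 1,
        if (ny > 1) y_mm[2] - y_mm[1] else 1,
        if (nz > 1) z_mm[2] - z_mm[1] else 1
      ),
      origin_mm = c(0, 0, 0),
      angles_deg = alphas,
      duplicate_policy = duplicate_policy
    ),
    class = "us_volume"
  )
}

#' @export
print.us_volume <- function(x, ...) {
  cat(sprintf(
    "Volume: %d x %d x %d voxels (x,y,z), %.0f%% inside the wedge, %d angles\n",
    length(x$x_mm), length(x$y_mm), length(x$z_mm),
    100 * mean(x$mask), length(x$angles_deg)
  ))
  invisible(x)
}

#' Stack a mechanical-translation sweep into a Cartesian volume
#'
#' Frames acquired at zero scan angle and known elevational positions are
#' resampled onto a regular grid with linear interpolation between adjacent
#' positions (depth maps directly to `z`).
#'
#' @param sweep A `translation_sweep` from [translate_scan()].
#' @param grid_spec Optional list with `y_mm`, `z_mm` and/or `voxel_mm` as in
#'   [reconstruct_volume()].
#' @return A `us_volume`.
#' @export
stack_translation_volume <- function(sweep, grid_spec = NULL) {
  stopifnot(inherits(sweep, "translation_sweep"))
  frames <- sweep$frames
  ys <- sweep$y_mm
  if (length(frames) < 2L) {
    stop("cannot interpolate elevationally: fewer than 2 positions", call. = FALSE)
  }
  ord <- order(ys)
  ys <- ys[ord]
  frames <- frames[ord]
  ref <- frames[[1]]
  daxis <- ref$d_mm
  if (is.null(grid_spec)) grid_spec <- list()
  voxel <- if (!is.null(grid_spec$voxel_mm)) grid_spec$voxel_mm else 0.1
  y_mm <- if (!is.null(grid_spec$y_mm)) grid_spec$y_mm else {
    seq(min(ys), max(ys), by = voxel)
  }
  z_mm <- if (!is.null(grid_spec$z_mm)) grid_spec$z_mm else {
    seq(min(daxis), max(daxis), by = voxel)
  }
  x_mm <- ref$x_mm
  nx <- length(x_mm)
  ny <- length(y_mm)
  nz <- length(z_mm)
  nd <- length(daxis)

  # depth interpolation of each frame onto the z grid, once
  zc <- pmin(pmax(z_mm, min(daxis)), max(daxis))
  id <- pmin(pmax(findInterval(zc, daxis, rightmost.closed = TRUE), 1L), nd - 1L)
  fd <- (zc - daxis[id]) / (daxis[id + 1] - daxis[id])
  interp_z <- function(E) E[id, , drop = FALSE] * (1 - fd) + E[id + 1L, , drop = FALSE] * fd
  slabs <- lapply(frames, function(f) interp_z(f$envelope)) # nz x nx each

  valid_z <- z_mm >= min(daxis) - 1e-9 & z_mm <= max(daxis) + 1e-9
  intensity <- array(NA_real_, dim = c(nx, ny, nz))
  valid_y <- ys[1] - 1e-9 <= y_mm & y_mm <= ys[length(ys)] + 1e-9
  ky <- pmin(pmax(findInterval(y_mm, ys, rightmost.closed = TRUE), 1L),
    length(ys) - 1L
  )
  for (iy in which(valid_y)) {
    kk <- ky[iy]
    w <- (y_mm[iy] - ys[kk]) / (ys[kk + 1] - ys[kk])
    B <- slabs[[kk]] * (1 - w) + slabs[[kk + 1]] * w # nz x nx
    B[!valid_z, ] <- NA_real_
    intensity[, iy, ] <- t(B)
  }
  mask_yz <- outer(valid_y, valid_z, `&`)
  mask <- array(rep(mask_yz, each = nx), dim = c(nx, ny, nz))
  structure(
    list(
      intensity = intensity, mask = mask,
      x_mm = x_mm, y_mm = y_mm, z_mm = z_mm,
      spacing_mm = c(
        if (nx > 1) x_mm[2] - x_mm[1] else 1,
        if (ny > 1) y_mm[2] - y_mm[1] else 1,
        if (nz > 1) z_mm[2] - z_mm[1] else 1
      ),
      origin_mm = c(0, 0, 0),
      angles_deg = numeric(0),
      duplicate_policy = "mean"
    ),
    class = "us_volume"
  )
}

#' Write a volume to NIfTI
#'
#' Intensity (NA outside the wedge stored as NaN) and the validity mask are
#' written as a pair of NIfTI files with voxel spacing in the header and the
#' grid origin in a JSON sidecar.
#'
#' @param volume A `us_volume`.
#' @param path Output path (`.nii` or `.nii.gz`); the mask gets a `_mask`
#'   suffix.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "us_volume"))
  img <- RNifti::asNifti(volume$intensity)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  msk <- RNifti::asNifti(array(as.integer(volume$mask), dim = dim(volume$mask)))
  RNifti::pixdim(msk) <- volume$spacing_mm
  RNifti::writeNifti(msk, mask_path)
  jsonlite::write_json(
    list(
      origin_mm = volume$origin_mm, spacing_mm = volume$spacing_mm,
      axes = c("x lateral", "y elevational", "z axial"),
      angles_deg = volume$angles_deg, mask = basename(mask_path)
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a volume as multi-page TIFF with a JSON sidecar
#'
#' One page per `z` slice (rows `y`, columns `x`), normalised to `[0, 1]`
#' with the scale recorded in the sidecar; invalid voxels are written as 0
#' and the mask stored as a companion multi-page TIFF.
#'
#' @param volume A `us_volume`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "us_volume"))
  m <- max(volume$intensity, na.rm = TRUE)
  scale <- if (is.finite(m) && m > 0) m else 1
  pages <- lapply(seq_along(volume$z_mm), function(iz) {
    sl <- t(volume$intensity[, , iz]) / scale
    sl[is.na(sl)] <- 0
    sl
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  mask_pages <- lapply(seq_along(volume$z_mm), function(iz) {
    t(volume$mask[, , iz]) * 1
  })
  tiff::writeTIFF(mask_pages, sub("\\.tiff?$", "_mask.tif", path))
  jsonlite::write_json(
    list(
      scale = scale, origin_mm = volume$origin_mm,
      spacing_mm = volume$spacing_mm, n_slices = length(volume$z_mm),
      axes = c("rows y elevational", "cols x lateral", "pages z axial")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
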