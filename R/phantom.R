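# Synthetic scatterer scenes: wire targets and speckle blocks with anechoic
# cavities. Positions are mm in the mirror-centred frame (x lateral,
# y elevational, z axial/depth).

new_phantom <- function(positions, amplitude, label) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  if (any(amplitude < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  colnames(positions) <- c("x", "y", "z")
  structure(
    list(positions = positions, amplitude = as.numeric(amplitude), label = label),
    class = "us_phantom"
  )
}

#' @export
print.us_phantom <- function(x, ...) {
  cat(sprintf(
    "Phantom '%s': %d scatterers, z in [%.2f, %.2f] mm\n",
    x$label, nrow(x$positions),
    if (nrow(x$positions)) min(x$positions[, "z"]) else NA,
    if (nrow(x$positions)) max(x$positions[, "z"]) else NA
  ))
  invisible(x)
}

#' Wire phantom
#'
#' Parallel wires along the lateral (`x`) direction, separated along the
#' elevational (`y`) direction and centred on `y = 0`. Each wire is a dense
#' line of point scatterers so that it appears continuous in beamformed
#' frames; the default point spacing is a quarter wavelength at 15.625 MHz in
#' water. Optional depth jitter emulates wires not strictly aligned at the
#' same depth.
#'
#' @param n_wires Number of wires (>= 1).
#' @param spacing_mm Elevational gap between adjacent wires (mm, > 0).
#' @param depth_mm Nominal wire depth from the mirror centre (mm).
#' @param wire_length_mm Length of each wire along `x` (mm).
#' @param point_spacing_mm Scatterer spacing along the wire (mm).
#' @param depth_jitter_mm Standard deviation of per-wire depth jitter (mm).
#' @param seed Optional integer seed (used for the jitter).
#' @return A `us_phantom`.
#' @examples
#' ph <- make_wire_phantom(4, 3, 15)
#' @export
make_wire_phantom <- function(n_wires = 4L, spacing_mm = 3, depth_mm = 15,
                              wire_length_mm = 10, point_spacing_mm = 0.025,
                              depth_jitter_mm = 0, seed = NULL) {
  if (n_wires < 1) stop("`n_wires` must be >= 1", call. = FALSE)
  if (spacing_mm <= 0) stop("`spacing_mm` must be positive", call. = FALSE)
  stop_if_not_scalar_pos(depth_mm, "depth_mm")
  if (!is.null(seed)) set.seed(seed)
  y <- (seq_len(n_wires) - (n_wires + 1) / 2) * spacing_mm
  z <- depth_mm + if (depth_jitter_mm > 0) rnorm(n_wires, 0, depth_jitter_mm) else 0
  x <- seq(-wire_length_mm / 2, wire_length_mm / 2, by = point_spacing_mm)
  pos <- cbind(
    x = rep(x, times = n_wires),
    y = rep(y, each = length(x)),
    z = rep(z, each = length(x))
  )
  ph <- new_phantom(pos, rep(1, nrow(pos)), sprintf("%d wires", n_wires))
  ph$wire_y_mm <- y
  ph$wire_z_mm <- rep(z, length.out = n_wires)
  ph
}

#' Speckle phantom with anechoic cavities
#'
#' Fills a rectangular block with uniformly distributed point scatterers whose
#' amplitudes follow a Rayleigh distribution scaled to unit mean (fully
#' developed speckle), then removes every scatterer falling inside any of the
#' spherical cavities.
#'
#' @param x_range_mm,y_range_mm,z_range_mm Length-2 extents of the block (mm).
#' @param cavity_centers_mm List of length-3 numeric centres (mm); may be
#'   empty for a pure speckle block.
#' @param cavity_radius_mm Cavity radius (mm); recycled over centres.
#' @param density_per_mm3 Expected scatterer density (per mm^3, > 0).
#' @param amplitude Either `"rayleigh"` (unit-mean Rayleigh) or `"unit"`
#'   (all amplitudes 1).
#' @param seed Optional integer seed.
#' @return A `us_phantom`.
#' @examples
#' ph <- make_cyst_phantom(c(-2, 2), c(-2, 2), c(15, 19),
#'   cavity_centers_mm = list(c(0, 0, 17)), cavity_radius_mm = 1.5,
#'   density_per_mm3 = 20, seed = 1
#' )
#' @export
make_cyst_phantom <- function(x_range_mm = c(-4, 4), y_range_mm = c(-3, 3),
                              z_range_mm = c(14, 26),
                              cavity_centers_mm = list(c(0, 0, 17), c(0, 0, 23)),
                              cavity_radius_mm = 1.5,
                              density_per_mm3 = 200,
                              amplitude = c("rayleigh", "unit"),
                              seed = NULL) {
  amplitude <- match.arg(amplitude)
  stop_if_not_scalar_pos(density_per_mm3, "density_per_mm3")
  dims <- c(diff(x_range_mm), diff(y_range_mm), diff(z_range_mm))
  if (any(dims <= 0)) stop("zero-volume phantom: each range must have positive extent", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vol <- prod(dims)
  n <- round(density_per_mm3 * vol)
  pos <- cbind(
    x = runif(n, x_range_mm[1], x_range_mm[2]),
    y = runif(n, y_range_mm[1], y_range_mm[2]),
    z = runif(n, z_range_mm[1], z_range_mm[2])
  )
  keep <- rep(TRUE, n)
  radii <- rep(cavity_radius_mm, length.out = length(cavity_centers_mm))
  for (i in seq_along(cavity_centers_mm)) {
    ctr <- cavity_centers_mm[[i]]
    d2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2 + (pos[, 3] - ctr[3])^2
    keep <- keep & d2 > radii[i]^2
  }
  pos <- pos[keep, , drop = FALSE]
  amp <- if (amplitude == "rayleigh") {
    # Rayleigh(sigma) has mean sigma * sqrt(pi/2); scale for unit mean
    sigma <- sqrt(2 / pi)
    sigma * sqrt(-2 * log(runif(nrow(pos))))
  } else {
    rep(1, nrow(pos))
  }
  ph <- new_phantom(pos, amp, "speckle block with cavities")
  ph$cavity_centers_mm <- cavity_centers_mm
  ph$cavity_radius_mm <- radii
  ph
}

#' Save / load a phantom as CSV
#'
#' Plain-text persistence: one row per scatterer (`x`, `y`, `z` in mm and
#' `amplitude`), with the label stored in a header comment.
#'
#' @param phantom A `us_phantom`.
#' @param path File path.
#' @return `path` (write) or a `us_phantom` (read).
#' @export
write_phantom_csv <- function(phantom, path) {
  stopifnot(inherits(phantom, "us_phantom"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# planesweep phantom: %s", phantom$label), con)
  write.csv(
    data.frame(
      x = phantom$positions[, 1], y = phantom$positions[, 2],
      z = phantom$positions[, 3], amplitude = phantom$amplitude
    ),
    con,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_phantom_csv
#' @export
read_phantom_csv <- function(path) {
  header <- readLines(path, n = 1L)
  label <- sub("^# planesweep phantom: ", "", header)
  df <- read.csv(path, comment.char = "#")
  new_phantom(as.matrix(df[, c("x", "y", "z")]), df$amplitude, label)
}
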