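# Scan conversion and Cartesian gridding of the swept wedge.

test_that("scan conversion follows the polar closed form and round-trips", {
  expect_equal(scan_convert_point(17, 0), cbind(y = 0, z = 17))
  expect_equal(scan_convert_point(25, 90), cbind(y = 25, z = 0),
    tolerance = 1e-12
  )
  expect_equal(scan_convert_point(20, 30), cbind(y = 10, z = 10 * sqrt(3)),
    tolerance = 1e-9
  )
  expect_error(scan_convert_point(-1, 0), ">= 0")

  # round trip depth/angle -> (y, z) -> depth/angle to 1e-12
  set.seed(5)
  d <- runif(200, 1, 30)
  a <- runif(200, -90, 90)
  yz <- scan_convert_point(d, a)
  d_back <- sqrt(yz[, "y"]^2 + yz[, "z"]^2)
  a_back <- atan2(yz[, "y"], yz[, "z"]) * 180 / pi
  expect_equal(d_back, d, tolerance = 1e-12)
  expect_equal(a_back, a, tolerance = 1e-12)
  # conservation: y^2 + z^2 = d^2
  expect_equal(yz[, "y"]^2 + yz[, "z"]^2, d^2, tolerance = 1e-12)
})

test_that("FOV extent doubles the tilt range and bounds the chord", {
  kin <- mirror_kinematics(11.95, 250)
  fov <- fov_extent(25, kin)
  expect_equal(fov$angle_range_deg, 47.8)
  expect_equal(fov$chord_mm, 20.257, tolerance = 1e-4)
  expect_equal(fov_extent(25, mirror_kinematics(0, 250))$chord_mm, 0)
  # chord is shorter than the arc
  arc <- 25 * fov$angle_range_deg * pi / 180
  expect_lt(fov$chord_mm, arc)
})

test_that("constant fields reconstruct exactly inside the wedge", {
  kin <- mirror_kinematics(12, 250)
  rows <- first_complete_volume(test_acq(prf_hz = 1062.5, duration_s = 0.033), kin)
  frames <- lapply(rows$scan_deg, function(a) constant_frame(3.7, a))
  vol <- reconstruct_volume(frames, list(voxel_mm = 0.25))
  inside <- vol$intensity[vol$mask]
  expect_gt(length(inside), 1000)
  expect_true(all(abs(inside - 3.7) < 1e-12))
  expect_true(all(is.na(vol$intensity[!vol$mask])))
})

test_that("the wedge mask depends on geometry, not image content", {
  kin <- mirror_kinematics(12, 250)
  rows <- first_complete_volume(test_acq(prf_hz = 1000, duration_s = 0.02), kin)
  f1 <- lapply(rows$scan_deg, function(a) constant_frame(1, a))
  set.seed(9)
  f2 <- lapply(rows$scan_deg, function(a) {
    f <- constant_frame(1, a)
    f$envelope[] <- runif(length(f$envelope))
    f
  })
  v1 <- reconstruct_volume(f1, list(voxel_mm = 0.3))
  v2 <- reconstruct_volume(f2, list(voxel_mm = 0.3))
  expect_identical(v1$mask, v2$mask)
})

test_that("fewer than two distinct angles cannot be gridded", {
  frames <- list(constant_frame(1, 5), constant_frame(1, 5))
  expect_error(reconstruct_volume(frames), "cannot interpolate elevationally")
})

test_that("up-sweep and down-sweep volumes agree for a static scene", {
  tx <- test_transducer(32L)
  acq <- test_acq(prf_hz = 2000, duration_s = 0.02, imaging_depth_mm = 20)
  kin <- mirror_kinematics(11.95, 250)
  rate <- volume_rate(2000, kin) # r = 8: 5 planes per half-sweep
  sch <- partition_into_volumes(build_schedule(acq, kin), rate)
  ids <- complete_volume_ids(sch)[1:2]
  ph <- make_wire_phantom(2, 3, 15, wire_length_mm = 2)
  grid <- list(x_mm = seq(-1, 1, by = 0.1), d_mm = seq(13, 17, by = 0.05))
  gs <- list(y_mm = seq(-5, 5, by = 0.1), z_mm = seq(13.5, 16.5, by = 0.1))
  vols <- lapply(ids, function(vid) {
    rows <- sch[sch$volume_id == vid, ]
    expect_equal(nrow(rows), 5L)
    reconstruct_volume(image_sweep(ph, tx, acq, rows, grid = grid), gs)
  })
  expect_identical(vols[[1]]$mask, vols[[2]]$mask)
  expect_equal(vols[[1]]$intensity, vols[[2]]$intensity, tolerance = 1e-9)
})

test_that("duplicate-coverage policies combine co-located planes as stated", {
  f_lo <- constant_frame(1, 10)
  f_hi <- constant_frame(3, 10)
  f_other <- constant_frame(2, -10)
  gs <- list(voxel_mm = 0.3)
  v_mean <- reconstruct_volume(list(f_lo, f_hi, f_other), gs, "mean")
  v_first <- reconstruct_volume(list(f_lo, f_hi, f_other), gs, "first")
  v_last <- reconstruct_volume(list(f_lo, f_hi, f_other), gs, "last")
  # probe a voxel strictly on the +10 degree side
  probe <- function(v) {
    iy <- which.min(abs(v$y_mm - 15 * sin(10 * pi / 180)))
    iz <- which.min(abs(v$z_mm - 15 * cos(10 * pi / 180)))
    v$intensity[1, iy, iz]
  }
  expect_equal(probe(v_mean), 2, tolerance = 0.05)
  expect_equal(probe(v_first), 1, tolerance = 0.05)
  expect_equal(probe(v_last), 3, tolerance = 0.05)
})

test_that("volumes serialise to NIfTI and TIFF with geometry intact", {
  kin <- mirror_kinematics(12, 250)
  rows <- first_complete_volume(test_acq(prf_hz = 1000, duration_s = 0.02), kin)
  frames <- lapply(rows$scan_deg, function(a) constant_frame(2, a))
  vol <- reconstruct_volume(frames, list(voxel_mm = 0.5))
  dir <- withr::local_tempdir()
  nii <- file.path(dir, "vol.nii.gz")
  write_volume_nifti(vol, nii)
  img <- RNifti::readNifti(nii)
  expect_equal(dim(img), dim(vol$intensity))
  expect_equal(RNifti::pixdim(img), vol$spacing_mm, tolerance = 1e-6)
  msk <- RNifti::readNifti(file.path(dir, "vol_mask.nii.gz"))
  expect_equal(as.array(msk) == 1, vol$mask)

  tif <- file.path(dir, "vol.tif")
  write_volume_tiff(vol, tif)
  pages <- tiff::readTIFF(tif, all = TRUE)
  expect_equal(length(pages), length(vol$z_mm))
  sidecar <- jsonlite::read_json(paste0(tif, ".json"))
  expect_equal(sidecar$scale, 2)
})
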