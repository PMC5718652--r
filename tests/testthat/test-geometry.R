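test_that("solve_linear_map interpolates its pairs and round-trips a known map", {
  # identity and pure scaling
  I2 <- solve_linear_map(rbind(c(100, 0), c(0, 100)), rbind(c(100, 0), c(0, 100)))
  expect_equal(I2, diag(2), tolerance = 1e-12)
  S <- solve_linear_map(rbind(c(100, 0), c(0, 100)), rbind(c(50, 0), c(0, 50)))
  expect_equal(S, 0.5 * diag(2), tolerance = 1e-12)
  # forward-compose a known map, then recover it
  M <- recompose_transform(1, 7, 0, 10)
  beam <- rbind(c(100, 0), c(0, 100))
  plate <- beam %*% t(M)
  expect_equal(solve_linear_map(beam, plate), M, tolerance = 1e-12)
  # exact interpolation of the input pairs
  M2 <- solve_linear_map(rbind(c(80, 10), c(-5, 120)), rbind(c(40, 3), c(7, 61)))
  expect_lt(max(abs(M2 %*% c(80, 10) - c(40, 3))), 1e-10)
  expect_lt(max(abs(M2 %*% c(-5, 120) - c(7, 61))), 1e-10)
})

test_that("solve_linear_map rejects degenerate plate vectors naming the points", {
  expect_error(
    solve_linear_map(rbind(c(100, 0), c(0, 100)), rbind(c(10, 0), c(20, 0))),
    "degenerate control points.*10, 0.*20, 0")
})

test_that("control point sets reject collinear or coincident points", {
  expect_error(control_point_set(c(0, 0), c(0, 0), c(10, 0)), "degenerate")
  expect_error(control_point_set(c(0, 0), c(10, 0), c(20, 0)), "collinear|degenerate")
  expect_error(control_point_set(c(0, 0), c(10, 0), c(0, 10), axis_length_mm = -5),
               "positive")
})

test_that("decompose_transform recovers factors and honors its conventions", {
  # pure zoomed rotation: no tilt
  p <- decompose_transform(2 * portalreg:::rot2(30))
  expect_equal(unname(p), c(2, 30, 0, 0), tolerance = 1e-9)
  # axis-aligned stretch: zoom is the smaller singular value, 1/cos(60) = 2
  p2 <- decompose_transform(diag(c(1, 2)))
  expect_equal(p2[["zoom_b"]], 1, tolerance = 1e-9)
  expect_equal(p2[["theta_deg"]], 0, tolerance = 1e-9)
  expect_equal(p2[["tilt_deg"]], 60, tolerance = 1e-9)
  M_back <- recompose_transform(p2[["zoom_b"]], p2[["theta_deg"]],
                                p2[["phi_deg"]], p2[["tilt_deg"]])
  expect_equal(M_back, diag(c(1, 2)), tolerance = 1e-9)
  # orientation-reversing maps are rejected
  expect_error(decompose_transform(diag(c(1, -1))), "orientation-reversing")
})

test_that("decomposition recomposes random maps to 1e-9 relative error", {
  set.seed(42)
  worst <- 0; tilt_ok <- TRUE
  for (i in 1:1000) {
    M <- matrix(stats::rnorm(4), 2, 2)
    if (abs(det(M)) < 1e-3) next
    if (det(M) < 0) M[, 1] <- -M[, 1]
    p <- decompose_transform(M)
    Mb <- recompose_transform(p[["zoom_b"]], p[["theta_deg"]],
                              p[["phi_deg"]], p[["tilt_deg"]])
    worst <- max(worst, max(abs(Mb - M)) / max(abs(M)))
    tilt_ok <- tilt_ok && p[["tilt_deg"]] >= 0 && p[["tilt_deg"]] < 90
  }
  expect_lt(worst, 1e-9)
  expect_true(tilt_ok)
})

test_that("forward distortion stretches the direction normal to the tilt axis", {
  tr <- planar_transform(recompose_transform(1, 0, 0, 10))
  # identity on the tilt-axis direction
  expect_equal(forward_distort(c(100, 0), tr), c(100, 0), tolerance = 1e-9)
  # 1/cos(10 deg) stretch on the normal direction
  expect_equal(forward_distort(c(0, 100), tr), c(0, 100 / cos(10 * pi / 180)),
               tolerance = 1e-6)
  # identity parameters give the identity map
  id <- planar_transform(diag(2), c(3, -4))
  expect_equal(forward_distort(c(12, -7), id), c(15, -11), tolerance = 1e-12)
})

test_that("forward then inverse distortion is the identity on points", {
  tr <- planar_transform(recompose_transform(1.07, 12, 35, 25), c(14.2, -3.7))
  set.seed(7)
  pts <- matrix(stats::runif(60, -120, 120), ncol = 2)
  back <- invert_distort(forward_distort(pts, tr), tr)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("correct_image undoes a known plate distortion on a smooth image", {
  # portal as seen on the plate: analytic scene sampled at inverse-mapped
  # plate coordinates, so the only error left after correction is bilinear.
  # M maps beam mm -> plate px; zoom 0.55 px/mm, 8 deg in-plane, 12 deg tilt.
  n <- 96; sp <- 2
  ctr <- (n - 1) / 2
  tr <- planar_transform(recompose_transform(0.55, 8, 30, 12), c(ctr, -ctr))
  cols <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  rows <- matrix(seq_len(n) - 1, n, n)
  beam <- invert_distort(
    portalreg:::px_to_plate(cbind(as.vector(cols), as.vector(rows))), tr)
  plate_img <- image_grid(matrix(smooth_field(beam[, 1], beam[, 2]), n), 1,
                          frame = "plate")
  target <- image_grid(matrix(0, n, n), sp, frame = "beam")
  corrected <- correct_image(plate_img, tr, target = target)
  truth <- smooth_grid(n, sp)
  interior <- corrected$mask
  interior[c(1:6, (n - 5):n), ] <- FALSE
  interior[, c(1:6, (n - 5):n)] <- FALSE
  err <- corrected$intensities[interior] - truth$intensities[interior]
  rng <- diff(range(truth$intensities))
  expect_lt(sqrt(mean(err^2)) / rng, 0.01)
})

test_that("correct_image keeps coordinate bookkeeping under pure scaling", {
  # 2 mm/px plate: a tick 50 px right of the isocenter sits at 100 mm
  n <- 121
  plate <- matrix(0, n, n)
  plate[61, 61 + 50] <- 1  # isocenter at (60,60) 0-based
  pg <- image_grid(plate, 1, c(60, 60), frame = "plate")
  tr <- planar_transform(0.5 * diag(2), c(60, -60))  # 1 mm -> 0.5 px
  target <- image_grid(matrix(0, 201, 201), 1, c(100, 100), frame = "beam")
  out <- correct_image(pg, tr, target)
  hit <- which(out$intensities == max(out$intensities), arr.ind = TRUE)
  # brightest output pixel at beam (100, 0) mm = col 200, row 100 (1-based +1)
  expect_equal(unname(hit[1, ]), c(101, 201))
  # identity transform reproduces the input up to the resampling grid
  tr_id <- planar_transform(diag(2), c(60, -60))
  same <- correct_image(pg, tr_id,
                        image_grid(matrix(0, n, n), 1, c(60, 60), frame = "beam"))
  expect_equal(same$intensities, plate, tolerance = 1e-12)
})

test_that("working area is the closed box through the axis control points", {
  cps <- control_point_set(c(256, 256), c(456, 256), c(256, 56), 100)
  expect_true(working_area(cps, c(50, 50)))
  expect_false(working_area(cps, c(150, 150)))
  expect_true(working_area(cps, c(100, 0)))    # boundary is inside
  expect_true(working_area(cps, c(-100, 100))) # corner
  expect_false(working_area(cps, c(-100.001, 0)))
  expect_equal(working_area(cps, rbind(c(0, 0), c(101, 0))), c(TRUE, FALSE))
})

test_that("control point sidecars round-trip through JSON", {
  cps <- control_point_set(c(880.5, 879.25), c(1080.5, 879.25), c(880.5, 679.25), 100)
  f <- tempfile(fileext = ".json")
  write_control_points(cps, f)
  back <- read_control_points(f)
  expect_equal(back$isocenter, cps$isocenter)
  expect_equal(back$axis_point_x, cps$axis_point_x)
  expect_equal(back$axis_length_mm, 100)
  expect_error(read_control_points(tempfile()), "not found")
})

test_that("transform_from_control_points recovers scale and rotation", {
  # portal plate at 0.8 px/mm, rotated 5 degrees
  L <- 100
  M_true <- 0.8 * portalreg:::rot2(5)
  iso <- c(300, 310)
  ax <- iso + portalreg:::plate_to_px(drop(M_true %*% c(L, 0)))
  ay <- iso + portalreg:::plate_to_px(drop(M_true %*% c(0, L)))
  cps_p <- control_point_set(iso, ax, ay, L)
  cps_d <- control_point_set(c(256, 256), c(456, 256), c(256, 56), L)
  tr <- transform_from_control_points(cps_p, cps_d)
  expect_equal(tr$linear, M_true, tolerance = 1e-9)
  expect_equal(tr$zoom_b, 0.8, tolerance = 1e-9)
  expect_equal(tr$theta_deg, 5, tolerance = 1e-9)
  expect_equal(tr$tilt_deg, 0, tolerance = 1e-6)
  expect_equal(control_point_spacing(cps_d), 0.5, tolerance = 1e-12)
})
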