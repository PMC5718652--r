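test_that("scenes are deterministic, bounded, and kind-appropriate", {
  s1 <- make_scene("chest", seed = 5)
  s2 <- make_scene("chest", seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, make_scene("chest", seed = 6)))
  expect_true(all(abs(s1$cx) <= attr(s1, "extent_mm")))
  expect_true(all(abs(s1$cy) <= attr(s1, "extent_mm")))
  expect_error(make_scene("abdomen"), "arg")
  # chest scenes carry stronger intensity gradients than pelvis scenes
  grad <- function(g) {
    m <- g$intensities
    mean(abs(diff(m))) + mean(abs(t(diff(t(m)))))
  }
  g_chest <- grad(render_drr(make_scene("chest", 1), 256, 1))
  g_pelvis <- grad(render_drr(make_scene("pelvis", 1), 256, 1))
  expect_gt(g_chest, g_pelvis)
})

test_that("the DRR carries field border, graticule ticks and isocenter", {
  drr <- render_drr(make_scene("chest", 1), 256, 1, field_size_mm = 100,
                    tick_spacing_mm = 10)
  at <- function(x_mm, y_mm) {
    cr <- round(portalreg:::beam_to_px(drr, c(x_mm, y_mm)))
    drr$intensities[cr[2] + 1, cr[1] + 1]
  }
  # ticks every 10 mm along both axes
  for (k in setdiff(-5:5, 0)) {
    expect_equal(at(k * 10, 0), 1023)
    expect_equal(at(0, k * 10), 1023)
  }
  # field corners at (+/-50, +/-50)
  for (sx in c(-50, 50)) for (sy in c(-50, 50)) expect_equal(at(sx, sy), 1023)
  # isocenter cross present
  expect_equal(at(0, 0), 1023)
  # anatomy elsewhere stays below the burn-in level
  expect_lt(at(33, 27), 1023)
})

test_that("portal anatomy shifts by the true offset while the graticule stays", {
  scene <- make_scene("chest", 3)
  cs0 <- synthetic_case("a", c(0, 0))
  cs5 <- synthetic_case("b", c(5, 0))
  p0 <- render_portal(scene, cs0, 128, 1)
  p5 <- render_portal(scene, cs5, 128, 1)
  drr <- render_drr(scene, 128, 1)
  # zero offset, no degradation: anatomy aligns with the DRR exactly
  expect_equal(p0$intensities, drr$intensities, tolerance = 1e-12)
  # cross-correlation of the anatomy (burn-in pixels excluded, since the
  # graticule deliberately stays put) peaks at a +5 px (=5 mm) lag
  row_band <- 30:98
  lags <- -8:8
  score <- sapply(lags, function(l) {
    cols_a <- 30:98; cols_b <- cols_a + l
    a <- as.vector(p5$intensities[row_band, cols_b])
    b <- as.vector(drr$intensities[row_band, cols_a])
    keep <- a < 1023 & b < 1023
    stats::cor(a[keep], b[keep])
  })
  expect_equal(lags[which.max(score)], 5)
  # the graticule stays at nominal positions: tick pixels identical
  tick_px <- round(portalreg:::beam_to_px(drr, cbind(setdiff(-5:5, 0) * 10, 0)))
  expect_equal(p5$intensities[cbind(tick_px[, 2] + 1, tick_px[, 1] + 1)],
               rep(1023, nrow(tick_px)))
})

test_that("contrast compression narrows the anatomy histogram proportionally", {
  scene <- make_scene("chest", 3)
  sd_at <- function(ct) {
    cs <- synthetic_case("c", c(0, 0), contrast = ct)
    p <- render_portal(scene, cs, 128, 1)
    stats::sd(p$intensities[p$intensities < 1023])  # exclude burned graphics
  }
  expect_equal(sd_at(1) / sd_at(0.2), 5, tolerance = 0.05)
})

test_that("case construction enforces the study design bounds", {
  expect_error(synthetic_case("x", c(12, 0)), "10 mm")
  expect_error(synthetic_case("x", c(1, 1), contrast = 0), "contrast")
  expect_error(synthetic_case("x", c(1, 1), noise_sigma = -1), "non-negative")
  expect_error(synthetic_case("x", c(1, 1),
                              tilt_params = list(tilt_deg = 50)), "45")
})

test_that("case lists present each offset twice, shuffled, within bounds", {
  cl <- make_case_list("chest", n_offsets = 5, seed = 9)
  expect_length(cl, 10)
  ids <- vapply(cl, `[[`, "", "case_id")
  expect_equal(sort(table(ids)), structure(rep(2L, 5), dim = 5,
               dimnames = list(sort(unique(ids)))), ignore_attr = TRUE)
  offs <- t(vapply(cl, `[[`, numeric(2), "true_offset"))
  expect_true(all(abs(offs) <= 10))
  # repeats of a case share offset and noise seed (same physical image)
  for (id in unique(ids)) {
    reps <- cl[ids == id]
    expect_equal(reps[[1]]$true_offset, reps[[2]]$true_offset)
    expect_identical(reps[[1]]$noise_seed, reps[[2]]$noise_seed)
  }
  # different shuffle seeds permute the same multiset of cases
  key <- function(cl) sort(vapply(cl, function(c)
    paste(c$case_id, c$repeat_index, paste(round(c$true_offset, 9), collapse = ","))
    , ""))
  cl_b <- make_case_list("chest", n_offsets = 5, seed = 9)
  expect_identical(key(cl), key(cl_b))
  # rendering is reproducible from the case alone
  scene <- make_scene("chest", 1)
  expect_identical(render_portal(scene, cl[[1]], 64, 2),
                   render_portal(scene, cl[[1]], 64, 2))
})

test_that("zero-tilt perspective projection is a pure magnification", {
  pts <- rbind(c(0, 0), c(100, 0), c(0, 100), c(-30, 45))
  uv <- perspective_project(pts, tilt_deg = 0, source_mm = 1000, plate_mm = 400)
  expect_equal(uv, pts * 1.4, tolerance = 1e-9)
})

test_that("tilt foreshortens the axis normal to the tilt axis", {
  # tilt about the x axis: the projected y axis length changes, x does not
  ux <- perspective_project(c(100, 0), 10, 0, 1000, 400)
  uy <- perspective_project(c(0, 100), 10, 0, 1000, 400)
  expect_equal(ux[1], 140, tolerance = 1e-9)
  expect_equal(ux[2], 0, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(uy[2], 140)))
})

test_that("simulate_tilted_plate returns exact control points for correction", {
  g <- smooth_grid(96, 2)
  res <- simulate_tilted_plate(g, tilt_deg = 10, azimuth_deg = 0,
                               source_mm = 1000, plate_mm = 400)
  expect_s3_class(res$control_points, "control_point_set")
  expect_equal(res$magnification, 1.4)
  # projected isocenter sits at the plate image center
  expect_equal(res$control_points$isocenter,
               c((ncol(res$image$intensities) - 1) / 2,
                 (nrow(res$image$intensities) - 1) / 2), tolerance = 1e-9)
  # correcting with the affine solved from the control points restores the
  # isocenter neighbourhood of the original image
  tr <- transform_from_control_points(res$control_points)
  target <- image_grid(matrix(0, 96, 96), 2, frame = "beam")
  corr <- correct_image(res$image, tr, target)
  ctr <- 38:58
  err <- corr$intensities[ctr, ctr] - g$intensities[ctr, ctr]
  expect_lt(sqrt(mean(err^2)) / diff(range(g$intensities)), 0.02)
})

test_that("post-correction residual is smaller inside the working area", {
  res <- run_tilt_experiment(tilt_deg = 10)
  expect_equal(res$placement, c("inside", "outside"))
  expect_lt(res$residual_mm[1], res$residual_mm[2])
})
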