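# Shared in-code fixtures: everything is generated, nothing read from disk.

# Analytic smooth scene: sum of gaussian blobs, evaluated at arbitrary
# beam-frame coordinates (so "rendered" images have no resampling error).
smooth_field <- function(x, y) {
  0.8 * exp(-((x - 10)^2 + (y + 5)^2) / (2 * 30^2)) +
    0.6 * exp(-((x + 25)^2 + (y - 20)^2) / (2 * 18^2)) +
    0.4 * exp(-((x - 5)^2 + (y - 40)^2) / (2 * 12^2))
}

# Render the analytic field on a beam-frame grid.
smooth_grid <- function(size_px = 64, spacing_mm = 2) {
  g <- image_grid(matrix(0, size_px, size_px), spacing_mm, frame = "beam")
  cols <- matrix(seq_len(size_px) - 1, size_px, size_px, byrow = TRUE)
  rows <- matrix(seq_len(size_px) - 1, size_px, size_px)
  x <- (cols - g$iso_px[1]) * spacing_mm
  y <- -(rows - g$iso_px[2]) * spacing_mm
  image_grid(matrix(smooth_field(x, y), size_px), spacing_mm, g$iso_px,
             frame = "beam")
}

# Grid from a plain matrix of intensities (beam frame, unit spacing).
grid_of <- function(m, spacing_mm = 1, frame = "beam")
  image_grid(m, spacing_mm, frame = frame)

# Exhaustive integer-mm grid search of the MI objective: the independent
# optimizer oracle. Returns the argmax offset over [-r, r]^2.
grid_search_mi <- function(portal, drr, r = 10, n_bins = 64,
                           working_area_mm = 100) {
  spec <- histogram_spec(n_bins, range_a = c(0, 1), range_b = c(0, 1))
  pw <- apply_window_level(portal)
  dw <- apply_window_level(drr)
  bc <- portalreg:::beam_coords(drr)
  region <- abs(bc$x) <= working_area_mm & abs(bc$y) <= working_area_mm
  best <- c(NA, NA); best_mi <- -Inf
  for (dx in -r:r) for (dy in -r:r) {
    moved <- portalreg:::resample_rigid(pw, -dx, -dy, 0)
    mi <- mutual_information(moved, dw, spec, region)
    if (mi > best_mi) { best_mi <- mi; best <- c(dx, dy) }
  }
  list(offset = best, mi = best_mi)
}

# Chest pair at reduced resolution for optimizer tests. 192 px at 1 mm/px
# keeps the burned-in graticule's pixel share close to the full-scale
# renders, so the MI landscape stays unimodal along the coarse-to-fine path.
small_chest_pair <- function(offset, contrast = 1, noise_sigma = 0,
                             seed = 3, size_px = 192, spacing_mm = 1) {
  scene <- make_scene("chest", seed = seed)
  drr <- render_drr(scene, size_px, spacing_mm)
  cs <- synthetic_case("t", offset, contrast = contrast,
                       noise_sigma = noise_sigma, noise_seed = seed + 100)
  portal <- render_portal(scene, cs, size_px, spacing_mm)
  list(portal = portal, drr = drr)
}
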