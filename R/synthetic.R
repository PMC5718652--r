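#' Analytic phantom scene
#'
#' Builds a 2D anatomy-like scene from analytic primitives (soft-edged
#' ellipses, bars and Gaussian blobs with attenuation weights), standing in
#' for the anthropomorphic thorax and pelvis phantoms. Chest scenes carry
#' high-contrast, partly periodic rib and vertebra structure plus
#' aperiodic features (heart shadow, clavicles); pelvis scenes are built
#' from broad low-gradient blobs (iliac wings, sacrum), which is what makes
#' their megavoltage portal registration fragile once contrast is
#' compressed.
#'
#' @param kind `"chest"` or `"pelvis"`.
#' @param seed integer seed controlling the small placement jitter;
#'   identical seeds give identical scenes.
#' @param extent_mm half-extent of the scene in mm (structures stay inside).
#' @return object of class `phantom_scene`: a data frame of primitives plus
#'   attributes `kind`, `seed`, `extent_mm`.
#' @export
make_scene <- function(kind = c("chest", "pelvis"), seed = 1, extent_mm = 130) {
  kind <- match.arg(kind)
  prim <- function(type, cx, cy, a, b, angle = 0, w = 1, soft = 1)
    data.frame(type = type, cx = cx, cy = cy, a = a, b = b,
               angle = angle, w = w, soft = soft, stringsAsFactors = FALSE)
  scene <- with_seed(seed, {
    if (kind == "chest") {
      jit <- function(s) stats::runif(1, -s, s)
      # broad low-frequency anatomy first: thoracic outline, graded lung
      # fields, diaphragm domes, cardiac silhouette and mediastinum. These
      # large structures dominate a real AP chest radiograph and give the
      # MI objective its wide capture range; the ribs and vertebrae add
      # the high-contrast periodic detail on top.
      rows <- list(
        prim("ellipse", 0, 0, 120, 125, 0, 0.25, 8),          # thorax outline
        prim("gauss", 0, 30, 120, 90, 0, 0.20, 1),            # upper soft tissue
        prim("ellipse", -55, 15, 45, 70, 8, -0.22, 10),       # left lung field
        prim("ellipse", 55, 15, 45, 70, -8, -0.22, 10),       # right lung field
        prim("ellipse", -48 + jit(3), -92, 62, 42, 5, 0.45, 8),  # diaphragm domes
        prim("ellipse", 48 + jit(3), -98, 62, 42, -4, 0.40, 8),
        prim("ellipse", -18, -45 + jit(3), 45, 42, 20, 0.30, 10), # cardiac silhouette
        prim("bar", 2, 20, 16, 95, 0, 0.22, 6),               # mediastinum column
        prim("gauss", -12, 52, 16, 14, 0, 0.18, 1),           # aortic knob
        prim("bar", -45, 95 + jit(2), 42, 4, 12, 0.4, 0.8),   # clavicles
        prim("bar", 45, 95 + jit(2), 42, 4, -12, 0.4, 0.8)
      )
      # vertebral column: distinct block sizes break strict periodicity
      vy <- seq(-110, 110, by = 14)
      for (i in seq_along(vy))
        rows[[length(rows) + 1L]] <-
          prim("bar", jit(1), vy[i] + jit(2), 9 + (i %% 3), 5.5, 0, 0.55, 0.6)
      # rib pairs, slightly tilted, spacing jittered per rib
      ry <- seq(-85, 85, by = 19)
      for (i in seq_along(ry)) {
        yy <- ry[i] + jit(2.5)
        rows[[length(rows) + 1L]] <- prim("bar", -52, yy, 44, 3.2, 7, 0.35, 0.7)
        rows[[length(rows) + 1L]] <- prim("bar", 52, yy + jit(2), 44, 3.2, -7, 0.35, 0.7)
      }
      do.call(rbind, rows)
    } else {
      jit <- function(s) stats::runif(1, -s, s)
      rows <- list(
        prim("gauss", 0, -10, 95, 85, 0, 0.30, 1),          # pelvic mass
        prim("gauss", -55 + jit(3), 25, 38, 48, 15, 0.22, 1),   # iliac wings
        prim("gauss", 55 + jit(3), 25, 38, 48, -15, 0.22, 1),
        prim("gauss", 0, 15 + jit(3), 18, 32, 0, 0.18, 1),  # sacrum
        prim("gauss", -35, -60, 22, 26, 0, 0.15, 1),        # femoral heads
        prim("gauss", 35, -60, 22, 26, 0, 0.15, 1),
        prim("ellipse", 0, 0, 125, 120, 0, 0.12, 25)        # soft-tissue disc
      )
      do.call(rbind, rows)
    }
  })
  scene$cx <- pmin(pmax(scene$cx, -extent_mm), extent_mm)
  scene$cy <- pmin(pmax(scene$cy, -extent_mm), extent_mm)
  structure(scene, kind = kind, seed = seed, extent_mm = extent_mm,
            class = c("phantom_scene", "data.frame"))
}

# Evaluate the scene's attenuation at beam-frame coordinates (vectors).
scene_values <- function(scene, x, y) {
  v <- numeric(length(x))
  for (i in seq_len(nrow(scene))) {
    p <- scene[i, ]
    a <- p$angle * pi / 180
    xr <- cos(a) * (x - p$cx) + sin(a) * (y - p$cy)
    yr <- -sin(a) * (x - p$cx) + cos(a) * (y - p$cy)
    if (p$type == "gauss") {
      v <- v + p$w * exp(-0.5 * ((xr / p$a)^2 + (yr / p$b)^2))
    } else {
      q <- if (p$type == "ellipse") sqrt((xr / p$a)^2 + (yr / p$b)^2)
           else pmax(abs(xr) / p$a, abs(yr) / p$b)
      # soft edge: logistic falloff of width ~soft (in units of the
      # normalized radius scaled by the primitive size)
      width <- p$soft / min(p$a, p$b)
      v <- v + p$w / (1 + exp((q - 1) / max(width, 1e-6)))
    }
  }
  v
}

#' One phantom trial
#'
#' Describes a single synthetic portal acquisition: the true x-y setup
#' offset, the presentation repeat index, the megavoltage contrast factor,
#' additive noise level, optional plate tilt, and the noise seed. Repeats
#' of the same case share the noise seed, so the two presentations are the
#' same image (as when one physical portal film is shown twice).
#'
#' @param case_id character id.
#' @param true_offset length-2 `(x0, y0)` mm, each within +/-10 mm.
#' @param repeat_index 1 or 2.
#' @param contrast scalar in (0, 1]: 1 keeps the DRR-level contrast,
#'   smaller values compress the anatomy histogram toward its mean.
#' @param noise_sigma additive Gaussian noise SD in intensity units
#'   (0..1023 scale).
#' @param noise_seed integer seed for the noise field.
#' @param tilt_params optional list `(tilt_deg, azimuth_deg, source_mm,
#'   plate_mm)` applying projective plate tilt.
#' @return object of class `synthetic_case`.
#' @export
synthetic_case <- function(case_id, true_offset, repeat_index = 1L,
                           contrast = 1, noise_sigma = 0,
                           noise_seed = 1L, tilt_params = NULL) {
  if (any(abs(true_offset) > 10 + 1e-9))
    stop("true offsets must lie within +/-10 mm per axis")
  if (contrast <= 0 || contrast > 1) stop("`contrast` must be in (0, 1]")
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative")
  if (!is.null(tilt_params) && tilt_params$tilt_deg >= 45)
    stop("plate tilt of 45 degrees or more is not supported")
  structure(list(case_id = as.character(case_id),
                 true_offset = as.numeric(true_offset),
                 repeat_index = as.integer(repeat_index),
                 contrast = contrast, noise_sigma = noise_sigma,
                 noise_seed = as.integer(noise_seed),
                 tilt_params = tilt_params),
            class = "synthetic_case")
}

# Burn the treatment field border, graticule ticks and isocenter cross into
# an intensity matrix (values on the 0..1023 scale), at nominal beam-frame
# positions. Returns the modified matrix.
burn_graticule <- function(mat, grid, field_size_mm = 100, tick_spacing_mm = 10,
                           value = 1023) {
  put <- function(m, xy) {
    cr <- round(beam_to_px(grid, xy))
    keep <- cr[, 1] >= 0 & cr[, 1] <= ncol(m) - 1 & cr[, 2] >= 0 & cr[, 2] <= nrow(m) - 1
    m[cbind(cr[keep, 2] + 1, cr[keep, 1] + 1)] <- value
    m
  }
  h <- field_size_mm / 2
  s <- min(grid$spacing_mm)
  edge <- seq(-h, h, by = s / 2)
  mat <- put(mat, cbind(edge, h)); mat <- put(mat, cbind(edge, -h))
  mat <- put(mat, cbind(h, edge)); mat <- put(mat, cbind(-h, edge))
  ticks <- setdiff(seq(-h, h, by = tick_spacing_mm), 0)
  dash <- seq(-1.5, 1.5, by = s / 2)
  for (t in ticks) {
    mat <- put(mat, cbind(t, dash))   # ticks on the x axis
    mat <- put(mat, cbind(dash, t))   # ticks on the y axis
  }
  cross <- seq(-3, 3, by = s / 2)
  mat <- put(mat, cbind(cross, 0)); mat <- put(mat, cbind(0, cross))
  mat
}

# Anatomy mapping onto the 10-bit scale: scene values stay below ~2, so
# floor + 2*scale must remain under the 1023 burn-in level to keep the
# anatomy histogram free of clipping.
.anatomy_scale <- 430
.anatomy_floor <- 60

render_anatomy <- function(scene, grid, offset = c(0, 0)) {
  bc <- beam_coords(grid)
  v <- scene_values(scene, as.vector(bc$x) - offset[1], as.vector(bc$y) - offset[2])
  matrix(.anatomy_floor + .anatomy_scale * v, nrow(grid$intensities))
}

empty_grid <- function(size_px, spacing_mm) {
  image_grid(matrix(0, size_px, size_px), spacing_mm, frame = "beam")
}

#' Render the planning DRR of a phantom scene
#'
#' Orthographic projection of the scene onto a beam-frame grid, with the
#' square treatment field border and graticule tick marks every centimeter
#' burned in about the isocenter, as a planning system would.
#'
#' @param scene a [make_scene()] result.
#' @param size_px output image side in pixels.
#' @param spacing_mm pixel spacing in mm.
#' @param field_size_mm burned-in square field side (default 10 cm).
#' @param tick_spacing_mm graticule tick spacing (default 1 cm).
#' @return an [image_grid()] in beam frame, intensities on the 0..1023
#'   scale.
#' @export
render_drr <- function(scene, size_px = 512, spacing_mm = 0.5,
                       field_size_mm = 100, tick_spacing_mm = 10) {
  grid <- empty_grid(size_px, spacing_mm)
  mat <- render_anatomy(scene, grid)
  mat <- burn_graticule(mat, grid, field_size_mm, tick_spacing_mm)
  image_grid(pmin(pmax(mat, 0), 1023), grid$spacing_mm, grid$iso_px, frame = "beam")
}

#' Render a synthetic portal image for one case
#'
#' The anatomy is rendered shifted by the case's true offset while the
#' field border and graticule are burned at the nominal (unshifted)
#' position — the portal's graphics are anchored to the beam, the patient
#' moved. Megavoltage contrast loss is modeled as linear histogram
#' compression of the anatomy toward its mean by the contrast factor,
#' followed by seeded additive Gaussian noise. Optional projective plate
#' tilt is applied through [simulate_tilted_plate()].
#'
#' @param scene a [make_scene()] result.
#' @param case a [synthetic_case()].
#' @inheritParams render_drr
#' @return an [image_grid()] (beam frame, or plate frame with attached
#'   `control_points` attribute when tilt is applied).
#' @export
render_portal <- function(scene, case, size_px = 512, spacing_mm = 0.5,
                          field_size_mm = 100, tick_spacing_mm = 10) {
  if (!inherits(case, "synthetic_case")) stop("`case` must be a synthetic_case")
  grid <- empty_grid(size_px, spacing_mm)
  mat <- render_anatomy(scene, grid, offset = case$true_offset)
  m0 <- mean(mat)
  mat <- m0 + case$contrast * (mat - m0)
  if (case$noise_sigma > 0)
    mat <- mat + with_seed(case$noise_seed,
                           matrix(stats::rnorm(length(mat), 0, case$noise_sigma),
                                  nrow(mat)))
  mat <- burn_graticule(mat, grid, field_size_mm, tick_spacing_mm)
  out <- image_grid(pmin(pmax(mat, 0), 1023), grid$spacing_mm, grid$iso_px,
                    frame = "beam")
  if (!is.null(case$tilt_params)) {
    tp <- case$tilt_params
    out <- simulate_tilted_plate(out, tp$tilt_deg, tp$azimuth_deg,
                                 tp$source_mm, tp$plate_mm)$image
  }
  out
}

#' Build the shuffled phantom case list
#'
#' Draws `n_offsets` true offsets uniformly within +/-10 mm per axis,
#' presents each twice (repeats share the rendered image), and shuffles
#' the presentation order with a derived seed. Chest cases default to
#' moderate contrast compression and mild noise; pelvis cases to the
#' heavy contrast loss typical of thick-anatomy megavoltage portals.
#'
#' @param kind `"chest"` or `"pelvis"`.
#' @param n_offsets number of distinct true offsets (default 5).
#' @param seed integer seed for offsets, noise seeds and shuffling.
#' @param contrast,noise_sigma degradation settings; `NULL` picks the
#'   per-kind defaults (chest 0.5 / 15, pelvis 0.15 / 15).
#' @param tilt_params optional tilt applied to every case.
#' @return object of class `case_list`: a list of [synthetic_case()]s with
#'   attributes `kind` and `seed`.
#' @export
make_case_list <- function(kind = c("chest", "pelvis"), n_offsets = 5, seed = 1,
                           contrast = NULL, noise_sigma = NULL,
                           tilt_params = NULL) {
  kind <- match.arg(kind)
  if (n_offsets < 1) stop("`n_offsets` must be at least 1")
  if (is.null(contrast)) contrast <- if (kind == "chest") 0.5 else 0.15
  if (is.null(noise_sigma)) noise_sigma <- 15
  offsets <- with_seed(derive_seed(seed, 1),
                       matrix(stats::runif(2 * n_offsets, -10, 10), ncol = 2))
  cases <- list()
  for (i in seq_len(n_offsets)) {
    for (rep_i in 1:2) {
      cases[[length(cases) + 1L]] <- synthetic_case(
        case_id = sprintf("%s-%02d", kind, i),
        true_offset = offsets[i, ],
        repeat_index = rep_i,
        contrast = contrast, noise_sigma = noise_sigma,
        noise_seed = derive_seed(seed, 100 + i),  # shared across repeats
        tilt_params = tilt_params)
    }
  }
  ord <- with_seed(derive_seed(seed, 2), sample(length(cases)))
  structure(cases[ord], kind = kind, seed = seed, class = "case_list")
}

#' @export
print.case_list <- function(x, ...) {
  cat(sprintf("<case_list %s, %d presentations of %d cases>\n",
              attr(x, "kind"), length(x),
              length(unique(vapply(x, `[[`, "", "case_id")))))
  invisible(x)
}

# Plate geometry for the perspective projection: source on the beam axis at
# +source_mm above the isocenter, plate centered at -plate_mm below it,
# tilted by tilt_deg about the in-plane axis at azimuth_deg.
plate_geometry <- function(tilt_deg, azimuth_deg, source_mm, plate_mm) {
  if (tilt_deg < 0 || tilt_deg >= 45) stop("plate tilt must lie in [0, 45) degrees")
  if (source_mm <= 0 || plate_mm <= 0) stop("distances must be positive")
  az <- azimuth_deg * pi / 180; ti <- tilt_deg * pi / 180
  axis <- c(cos(az), sin(az), 0)                      # tilt axis, in-plane
  n0 <- c(0, 0, 1)
  # Rodrigues rotation of the plate normal about the tilt axis
  n <- n0 * cos(ti) + c(axis[2] * n0[3] - axis[3] * n0[2],
                        axis[3] * n0[1] - axis[1] * n0[3],
                        axis[1] * n0[2] - axis[2] * n0[1]) * sin(ti) +
    axis * sum(axis * n0) * (1 - cos(ti))
  e2 <- c(n[2] * axis[3] - n[3] * axis[2],  # cross(n, axis)
          n[3] * axis[1] - n[1] * axis[3],
          n[1] * axis[2] - n[2] * axis[1])
  list(S = c(0, 0, source_mm), C = c(0, 0, -plate_mm),
       n = n, e1 = axis, e2 = e2)
}

#' Perspective projection of beam-frame points onto a tilted plate
#'
#' Traces the ray from the point source through each isocenter-plane point
#' `(x, y, 0)` to its intersection with the (possibly tilted) imaging
#' plate, and returns in-plate 2D coordinates in mm (plate axes: the tilt
#' axis and its in-plane normal). With zero tilt this is a pure scaling by
#' `(source_mm + plate_mm) / source_mm`.
#'
#' @param points_mm n x 2 matrix (or length-2 vector) of beam-frame points.
#' @param tilt_deg plate tilt in degrees, `[0, 45)`.
#' @param azimuth_deg azimuth of the tilt axis.
#' @param source_mm source-to-isocenter distance.
#' @param plate_mm isocenter-to-plate distance.
#' @return n x 2 matrix of plate coordinates in mm.
#' @export
perspective_project <- function(points_mm, tilt_deg, azimuth_deg = 0,
                                source_mm = 1000, plate_mm = 400) {
  g <- plate_geometry(tilt_deg, azimuth_deg, source_mm, plate_mm)
  p <- rbind2mat(points_mm)
  out <- matrix(NA_real_, nrow(p), 2)
  num <- sum((g$C - g$S) * g$n)
  for (i in seq_len(nrow(p))) {
    d <- c(p[i, 1], p[i, 2], 0) - g$S
    den <- sum(d * g$n)
    if (abs(den) < 1e-12) stop("geometric degeneracy: ray parallel to plate")
    q <- g$S + (num / den) * d - g$C
    out[i, ] <- c(sum(q * g$e1), sum(q * g$e2))
  }
  if (is.null(dim(points_mm))) drop(out) else out
}

#' Image a beam-frame grid through a tilted plate (full perspective)
#'
#' Projects an isocenter-plane image onto a tilted imaging plate by true
#' perspective projection (not the affine approximation used for
#' correction), returning the plate image and the exact plate pixel
#' positions of the isocenter and graticule axis points for downstream
#' control-point-based correction.
#'
#' @param grid an [image_grid()] in beam frame.
#' @param tilt_deg,azimuth_deg,source_mm,plate_mm plate geometry, see
#'   [perspective_project()].
#' @param axis_length_mm control-point distance along each axis.
#' @param out_spacing_mm plate pixel spacing (default: input spacing times
#'   the zero-tilt magnification, so resolution is comparable).
#' @return list with `image` (plate-frame [image_grid()]),
#'   `control_points` (a [control_point_set()] of exact projected pixel
#'   positions) and `magnification`.
#' @export
simulate_tilted_plate <- function(grid, tilt_deg, azimuth_deg = 0,
                                  source_mm = 1000, plate_mm = 400,
                                  axis_length_mm = 100, out_spacing_mm = NULL) {
  stopifnot_image_grid(grid)
  g <- plate_geometry(tilt_deg, azimuth_deg, source_mm, plate_mm)
  mag <- (source_mm + plate_mm) / source_mm
  if (is.null(out_spacing_mm)) out_spacing_mm <- min(grid$spacing_mm) * mag
  nr <- nrow(grid$intensities); nc <- ncol(grid$intensities)
  out_nc <- nc; out_nr <- nr
  iso_uv <- perspective_project(c(0, 0), tilt_deg, azimuth_deg, source_mm, plate_mm)
  # plate image centered on the projected isocenter
  iso_px <- c((out_nc - 1) / 2, (out_nr - 1) / 2)
  # inverse map: plate pixel -> plate mm -> ray -> isocenter plane -> source px
  cols <- matrix(seq_len(out_nc) - 1, out_nr, out_nc, byrow = TRUE)
  rows <- matrix(seq_len(out_nr) - 1, out_nr, out_nc)
  u <- iso_uv[1] + (cols - iso_px[1]) * out_spacing_mm
  v <- iso_uv[2] - (rows - iso_px[2]) * out_spacing_mm
  Q1 <- g$C[1] + as.vector(u) * g$e1[1] + as.vector(v) * g$e2[1]
  Q2 <- g$C[2] + as.vector(u) * g$e1[2] + as.vector(v) * g$e2[2]
  Q3 <- g$C[3] + as.vector(u) * g$e1[3] + as.vector(v) * g$e2[3]
  s <- g$S[3]
  tt <- s / (s - Q3)
  x <- tt * Q1; y <- tt * Q2
  cr_c <- grid$iso_px[1] + x / grid$spacing_mm[1]
  cr_r <- grid$iso_px[2] - y / grid$spacing_mm[2]
  samp <- bilinear_sample(grid$intensities, grid$mask, cr_c, cr_r)
  img <- image_grid(matrix(samp$values, out_nr, out_nc),
                    out_spacing_mm, iso_px,
                    matrix(samp$valid, out_nr, out_nc), frame = "plate")
  cp_beam <- rbind(c(0, 0), c(axis_length_mm, 0), c(0, axis_length_mm))
  uv <- perspective_project(cp_beam, tilt_deg, azimuth_deg, source_mm, plate_mm)
  to_px <- function(uvrow)
    c(iso_px[1] + (uvrow[1] - iso_uv[1]) / out_spacing_mm,
      iso_px[2] - (uvrow[2] - iso_uv[2]) / out_spacing_mm)
  cps <- control_point_set(to_px(uv[1, ]), to_px(uv[2, ]), to_px(uv[3, ]),
                           axis_length_mm)
  list(image = img, control_points = cps, magnification = mag)
}
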