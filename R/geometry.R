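#' Control points anchoring the beam frame on one image
#'
#' The operator designates three points on each image using the burned-in
#' graticule: the isocenter and one point on each orthogonal axis, usually
#' 10 cm from the isocenter. These three points determine the scale,
#' rotation and out-of-plane tilt of the plate relative to the beam's-eye
#' view.
#'
#' @param isocenter,axis_point_x,axis_point_y continuous 0-based `(col, row)`
#'   pixel coordinates of the isocenter and of the points on the +x and +y
#'   graticule axes.
#' @param axis_length_mm physical distance from the isocenter to each axis
#'   point (default 100 mm, i.e. the 10 cm tick).
#' @return an object of class `control_point_set`.
#' @export
control_point_set <- function(isocenter, axis_point_x, axis_point_y,
                              axis_length_mm = 100) {
  pts <- list(isocenter = as.numeric(isocenter),
              axis_point_x = as.numeric(axis_point_x),
              axis_point_y = as.numeric(axis_point_y))
  for (nm in names(pts))
    if (length(pts[[nm]]) != 2L || any(!is.finite(pts[[nm]])))
      stop(sprintf("`%s` must be a finite (col, row) pair", nm))
  if (!is.finite(axis_length_mm) || axis_length_mm <= 0)
    stop("`axis_length_mm` must be positive")
  vx <- pts$axis_point_x - pts$isocenter
  vy <- pts$axis_point_y - pts$isocenter
  d <- vx[1] * vy[2] - vx[2] * vy[1]
  if (sqrt(sum(vx^2)) < 1e-9 || sqrt(sum(vy^2)) < 1e-9 || abs(d) < 1e-9)
    stop(paste0("degenerate control points: isocenter (",
                toString(round(pts$isocenter, 3)), "), axis_point_x (",
                toString(round(pts$axis_point_x, 3)), "), axis_point_y (",
                toString(round(pts$axis_point_y, 3)),
                ") are collinear or coincident"))
  structure(c(pts, list(axis_length_mm = axis_length_mm)),
            class = "control_point_set")
}

# Plate-frame coordinates: math convention (x right, y up) in pixel units,
# obtained from image (col,row) pixels by negating the row axis. All plate
# vectors in transforms below live in this frame.
px_to_plate <- function(colrow) {
  colrow <- rbind2mat(colrow)
  cbind(colrow[, 1], -colrow[, 2])
}

plate_to_px <- function(uv) {
  uv <- rbind2mat(uv)
  cbind(uv[, 1], -uv[, 2])
}

#' Solve the 2x2 linear map from paired vectors
#'
#' Finds the matrix taking beam-frame mm vectors to plate-frame vectors
#' exactly on two (or more, least-squares) given pairs. With a
#' [control_point_set()] on each image the pairs are the isocenter-to-axis
#' vectors and the full [planar_transform()] adds the isocenter translation.
#'
#' @param beam_vectors,plate_vectors n x 2 matrices of corresponding vectors
#'   (rows), n >= 2, taken relative to the isocenter.
#' @return 2x2 matrix `M` with `plate = M %*% beam` on the pairs.
#' @export
solve_linear_map <- function(beam_vectors, plate_vectors) {
  B <- t(rbind2mat(beam_vectors)); P <- t(rbind2mat(plate_vectors))
  if (ncol(B) < 2L || !identical(dim(B), dim(P)))
    stop("need at least two corresponding vector pairs of matching shape")
  if (abs(det(P[, 1:2])) < 1e-12 * max(1, max(abs(P))))
    stop(paste0("degenerate control points: plate vectors (",
                toString(round(P[, 1], 3)), ") and (",
                toString(round(P[, 2], 3)), ") are linearly dependent"))
  if (abs(det(B[, 1:2])) < 1e-12 * max(1, max(abs(B))))
    stop("beam-frame vectors are linearly dependent")
  if (ncol(B) == 2L) P %*% solve(B) else t(qr.solve(t(B), t(P)))
}

#' Portal-to-DRR planar transform
#'
#' The map from beam-frame mm coordinates (about the isocenter) to plate
#' pixel coordinates: `plate = M %*% beam + translation`, where the linear
#' part factors as `M = b * Rot(theta) * Rot(phi) * St(tilt) * Rot(-phi)`
#' with `St(t) = diag(1, 1/cos t)`. `b` is the zoom ratio (the smaller
#' singular value of `M`), `theta` the in-plane rotation about the beam
#' axis, `phi` the azimuth of the tilt axis (the unstretched in-plane
#' direction), and `tilt` the out-of-plane plate rotation producing the
#' `1/cos` stretch.
#'
#' @param linear 2x2 matrix with positive determinant.
#' @param translation length-2 plate-frame offset of the isocenter
#'   (pixel units, y up).
#' @return object of class `planar_transform` with fields `linear`,
#'   `translation`, `zoom_b`, `theta_deg`, `phi_deg`, `tilt_deg`.
#' @export
planar_transform <- function(linear, translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (!all(is.finite(linear))) stop("`linear` must be finite")
  if (det(linear) <= 0)
    stop("orientation-reversing map: det(M) must be positive")
  p <- decompose_transform(linear)
  structure(list(linear = linear, translation = as.numeric(translation),
                 zoom_b = p[["zoom_b"]], theta_deg = p[["theta_deg"]],
                 phi_deg = p[["phi_deg"]], tilt_deg = p[["tilt_deg"]]),
            class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf(
    "<planar_transform zoom=%.4g rot=%.3g deg tilt=%.3g deg (axis azimuth %.3g deg) shift=(%.2f, %.2f)>\n",
    x$zoom_b, x$theta_deg, x$tilt_deg, x$phi_deg,
    x$translation[1], x$translation[2]))
  invisible(x)
}

rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Factor a 2x2 map into zoom, rotation, tilt azimuth and tilt
#'
#' Decomposes `M` (det > 0) as `b * Rot(theta) * Rot(phi) * St(tilt) *
#' Rot(-phi)` with `St(t) = diag(1, 1/cos t)`, via the polar/singular-value
#' factorization: `b` is the smaller singular value, `cos(tilt)` the ratio
#' of smaller to larger singular value, `phi + 90` the azimuth of the
#' stretched right-singular direction, and `theta` the residual rotation.
#' Equal singular values (no tilt) return `tilt = 0`, `phi = 0` by
#' convention; `phi` is reported in (-90, 90] (the azimuth is a line, not a
#' direction).
#'
#' @param M 2x2 matrix with positive determinant.
#' @return named numeric vector `(zoom_b, theta_deg, phi_deg, tilt_deg)`.
#' @export
decompose_transform <- function(M) {
  M <- matrix(as.numeric(M), 2, 2)
  if (det(M) <= 0)
    stop("orientation-reversing map: det(M) must be positive")
  e <- eigen(crossprod(M), symmetric = TRUE)
  s_max <- sqrt(max(e$values)); s_min <- sqrt(min(e$values))
  b <- s_min
  if ((s_max - s_min) <= 1e-12 * s_max) {
    tilt <- 0; phi <- 0
    R <- M / b
  } else {
    tilt <- acos(s_min / s_max) * 180 / pi
    v_max <- e$vectors[, which.max(e$values)]  # stretched direction
    phi <- atan2(v_max[2], v_max[1]) * 180 / pi - 90
    phi <- ((phi + 90) %% 180) - 90
    if (phi == -90) phi <- 90
    P <- rot2(phi) %*% diag(c(1, s_max / s_min)) %*% rot2(-phi)
    R <- M %*% solve(b * P)
  }
  theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  c(zoom_b = b, theta_deg = theta, phi_deg = phi, tilt_deg = tilt)
}

#' Recompose the linear part from its factors
#'
#' Inverse of [decompose_transform()]: returns
#' `b * Rot(theta) * Rot(phi) * diag(1, 1/cos(tilt)) * Rot(-phi)`.
#'
#' @param zoom_b positive zoom ratio.
#' @param theta_deg in-plane rotation, degrees.
#' @param phi_deg azimuth of the tilt axis, degrees.
#' @param tilt_deg out-of-plane tilt in [0, 90), degrees.
#' @return 2x2 matrix.
#' @export
recompose_transform <- function(zoom_b, theta_deg, phi_deg, tilt_deg) {
  if (zoom_b <= 0) stop("`zoom_b` must be positive")
  if (tilt_deg < 0 || tilt_deg >= 90) stop("`tilt_deg` must lie in [0, 90)")
  st <- diag(c(1, 1 / cos(tilt_deg * pi / 180)))
  zoom_b * rot2(theta_deg) %*% rot2(phi_deg) %*% st %*% rot2(-phi_deg)
}

#' Apply the forward plate distortion to beam-frame points
#'
#' Maps beam-frame mm points (about the isocenter) to plate-frame
#' coordinates through the transform's linear part, then adds the
#' translation.
#'
#' @param point_mm length-2 vector or n x 2 matrix of beam-frame points.
#' @param transform a [planar_transform()].
#' @return point(s) in plate-frame coordinates, same shape as input.
#' @export
forward_distort <- function(point_mm, transform) {
  p <- rbind2mat(point_mm)
  out <- p %*% t(transform$linear)
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  if (is.null(dim(point_mm))) drop(out) else out
}

#' Invert the plate distortion
#'
#' Recovers beam-frame mm coordinates from plate-frame coordinates, i.e.
#' applies `M^-1 (u - t)`; this is the reverse process used to correct the
#' distorted portal image.
#'
#' @inheritParams forward_distort
#' @param point_plate plate-frame point(s).
#' @return beam-frame point(s) in mm.
#' @export
invert_distort <- function(point_plate, transform) {
  u <- rbind2mat(point_plate)
  u[, 1] <- u[, 1] - transform$translation[1]
  u[, 2] <- u[, 2] - transform$translation[2]
  out <- u %*% t(solve(transform$linear))
  if (is.null(dim(point_plate))) drop(out) else out
}

#' Build the portal-to-beam transform from two control-point sets
#'
#' The DRR's control points define the beam frame: its isocenter-to-axis
#' vectors are by definition `(L, 0)` and `(0, L)` mm with `L =
#' axis_length_mm`. The portal's control points give the corresponding
#' plate-frame pixel vectors, from which the 2x2 linear part is solved and
#' factorized.
#'
#' @param cps_portal [control_point_set()] clicked on the portal image.
#' @param cps_drr [control_point_set()] clicked on the DRR image (used for
#'   the beam-frame axis length; its pixel scale is recovered separately).
#' @return a [planar_transform()] mapping beam mm to portal plate pixels.
#' @export
transform_from_control_points <- function(cps_portal, cps_drr = NULL) {
  if (!inherits(cps_portal, "control_point_set"))
    stop("`cps_portal` must be a control_point_set")
  L <- if (is.null(cps_drr)) cps_portal$axis_length_mm else cps_drr$axis_length_mm
  iso <- px_to_plate(cps_portal$isocenter)
  ux <- px_to_plate(cps_portal$axis_point_x) - iso
  uy <- px_to_plate(cps_portal$axis_point_y) - iso
  M <- solve_linear_map(rbind(c(L, 0), c(0, L)), rbind(ux, uy))
  planar_transform(M, drop(iso))
}

#' Pixel spacing implied by a control-point set
#'
#' `axis_length_mm` divided by the mean pixel distance from the isocenter to
#' the two axis points. Used to calibrate images whose metadata carries no
#' spacing.
#'
#' @param cps a [control_point_set()].
#' @return spacing in mm per pixel.
#' @export
control_point_spacing <- function(cps) {
  if (!inherits(cps, "control_point_set"))
    stop("`cps` must be a control_point_set")
  dx <- sqrt(sum((cps$axis_point_x - cps$isocenter)^2))
  dy <- sqrt(sum((cps$axis_point_y - cps$isocenter)^2))
  cps$axis_length_mm / mean(c(dx, dy))
}

#' Resample a portal image into the DRR beam frame
#'
#' Inverse-maps every output beam-frame pixel through the transform to a
#' plate position and samples the portal there with bilinear interpolation.
#' Output pixels that pull from outside the portal footprint are flagged
#' background in the mask (not given a fake zero intensity).
#'
#' @param portal an [image_grid()] in plate frame.
#' @param transform the portal [planar_transform()] (beam mm to plate px).
#' @param target an [image_grid()] whose shape/spacing/isocenter define the
#'   output beam frame (typically the DRR), or `NULL` to reuse the portal's
#'   shape with spacing from the transform zoom.
#' @return corrected [image_grid()] in the beam frame.
#' @export
correct_image <- function(portal, transform, target = NULL) {
  stopifnot_image_grid(portal)
  if (!inherits(transform, "planar_transform"))
    stop("`transform` must be a planar_transform")
  if (is.null(target)) {
    sp <- portal$spacing_mm / transform$zoom_b
    target <- image_grid(matrix(0, nrow(portal$intensities), ncol(portal$intensities)),
                         sp, portal$iso_px, frame = "beam")
  }
  stopifnot_image_grid(target)
  nr <- nrow(target$intensities); nc <- ncol(target$intensities)
  bc <- beam_coords(target)
  uv <- forward_distort(cbind(as.vector(bc$x), as.vector(bc$y)), transform)
  cr <- plate_to_px(uv)
  s <- bilinear_sample(portal$intensities, portal$mask, cr[, 1], cr[, 2])
  image_grid(matrix(s$values, nr, nc), target$spacing_mm, target$iso_px,
             matrix(s$valid, nr, nc), frame = "beam")
}

#' Is a beam-frame point inside the working area?
#'
#' The working area is the region spanned by the control points, formalized
#' as the closed axis-aligned box `[-L, L] x [-L, L]` mm about the
#' isocenter with `L = axis_length_mm`. The plate-tilt correction is exact
#' at the control points and degrades away from them, so alignment
#' judgements (and, optionally, the mutual-information computation) should
#' be confined to this box.
#'
#' @param cps a [control_point_set()].
#' @param point_mm length-2 vector or n x 2 matrix of beam-frame points.
#' @return logical: `TRUE` for inside (boundary included).
#' @export
working_area <- function(cps, point_mm) {
  if (!inherits(cps, "control_point_set"))
    stop("`cps` must be a control_point_set")
  p <- rbind2mat(point_mm)
  L <- cps$axis_length_mm
  inside <- abs(p[, 1]) <= L & abs(p[, 2]) <= L
  if (is.null(dim(point_mm))) inside[[1]] else inside
}

#' Read or write a control-point JSON sidecar
#'
#' Control points are stored next to each image as a small JSON file with
#' fields `isocenter`, `axis_point_x`, `axis_point_y` (0-based (col,row)
#' pixels) and `axis_length_mm`.
#'
#' @param path JSON file path.
#' @param cps a [control_point_set()] (for writing).
#' @return `read_control_points` returns a [control_point_set()];
#'   `write_control_points` returns `path` invisibly.
#' @export
read_control_points <- function(path) {
  if (!file.exists(path)) stop(sprintf("control-point file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  control_point_set(j$isocenter, j$axis_point_x, j$axis_point_y,
                    if (is.null(j$axis_length_mm)) 100 else j$axis_length_mm)
}

#' @rdname read_control_points
#' @export
write_control_points <- function(cps, path) {
  if (!inherits(cps, "control_point_set"))
    stop("`cps` must be a control_point_set")
  jsonlite::write_json(unclass(cps), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
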