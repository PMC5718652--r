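#' Tilted-plate correction residuals inside vs outside the working area
#'
#' Replays the plate-tilt verification: the beam-frame graticule is imaged
#' onto a plate tilted about the horizontal axis by true perspective
#' projection, the three control points (isocenter and the two axis
#' points) are read off the plate exactly, the affine correction is solved
#' from them, and the residual between a test point's true beam-frame
#' position and its corrected position is measured. Because the affine
#' correction is exact only at the control points, the residual is small
#' for a test point inside the working area and grows outside it.
#'
#' @param tilt_deg plate tilt (degrees, default 10).
#' @param azimuth_deg tilt-axis azimuth (0 = horizontal axis).
#' @param source_mm source-to-isocenter distance.
#' @param plate_mm isocenter-to-plate distance.
#' @param axis_length_mm control-point distance (working-area half-width).
#' @param inside_mm,outside_mm beam-frame test points; defaults 5 cm along
#'   both axes (inside) and its mirrored 15 cm placement (outside).
#' @return data frame with one row per test point: placement, the point,
#'   and the post-correction residual in mm.
#' @export
run_tilt_experiment <- function(tilt_deg = 10, azimuth_deg = 0,
                                source_mm = 1000, plate_mm = 400,
                                axis_length_mm = 100,
                                inside_mm = c(50, 50),
                                outside_mm = c(150, 150)) {
  proj <- function(p) perspective_project(p, tilt_deg, azimuth_deg,
                                          source_mm, plate_mm)
  cp_beam <- rbind(c(0, 0), c(axis_length_mm, 0), c(0, axis_length_mm))
  uv <- proj(cp_beam)
  # affine correction solved from the three projected control points,
  # exactly as transform_from_control_points does on clicked pixels
  M <- solve_linear_map(rbind(c(axis_length_mm, 0), c(0, axis_length_mm)),
                        rbind(uv[2, ] - uv[1, ], uv[3, ] - uv[1, ]))
  tr <- planar_transform(M, uv[1, ])
  residual <- function(p) {
    est <- invert_distort(proj(rbind(p))[1, ], tr)
    offset_distance(est, p)
  }
  cps <- control_point_set(c(0, 0), c(axis_length_mm, 0), c(0, -axis_length_mm),
                           axis_length_mm)
  out <- data.frame(
    placement = c(ifelse(working_area(cps, rbind(inside_mm)), "inside", "outside"),
                  ifelse(working_area(cps, rbind(outside_mm)), "inside", "outside")),
    x_mm = c(inside_mm[1], outside_mm[1]),
    y_mm = c(inside_mm[2], outside_mm[2]),
    residual_mm = c(residual(inside_mm), residual(outside_mm)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
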