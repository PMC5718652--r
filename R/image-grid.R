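#' Planar image on a physical grid
#'
#' The basic raster container used throughout the package. Intensities are
#' stored as a numeric matrix in conventional image order (row 1 is the top
#' of the image, columns run left to right). The grid carries a physical
#' pixel spacing in mm per axis, the continuous (col,row) pixel position of
#' the isocenter, a per-pixel validity mask, and a frame tag: `"beam"` for
#' images already resampled into the beam's-eye-view (BEV) frame, `"plate"`
#' for raw detector/plate pixels.
#'
#' Beam-frame coordinates are mm about the isocenter with +x to the right
#' and +y up, so the row axis is negated: `x = (col - iso_col) * sx`,
#' `y = -(row - iso_row) * sy`. Pixel coordinates are continuous and
#' 0-based.
#'
#' @param intensities numeric matrix of non-negative finite intensities
#'   (10-bit scanned sources are stored as-is, e.g. 0..1023).
#' @param spacing_mm pixel spacing in mm, length 1 (isotropic) or 2 `(sx, sy)`.
#' @param iso_px continuous 0-based `(col, row)` pixel position of the
#'   isocenter; defaults to the grid center.
#' @param mask logical matrix of valid pixels, same shape as `intensities`;
#'   default all valid. Invalid pixels are background (outside the source
#'   footprint after resampling) and are excluded from statistics.
#' @param frame `"beam"` or `"plate"`.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(intensities, spacing_mm = c(1, 1), iso_px = NULL,
                       mask = NULL, frame = c("beam", "plate")) {
  frame <- match.arg(frame)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix")
  if (!all(is.finite(intensities)))
    stop("`intensities` must be finite")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be one or two positive finite values")
  if (is.null(iso_px))
    iso_px <- c((ncol(intensities) - 1) / 2, (nrow(intensities) - 1) / 2)
  if (length(iso_px) != 2L || any(!is.finite(iso_px)))
    stop("`iso_px` must be a finite (col, row) pair")
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(intensities), ncol(intensities))
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(intensities)))
      stop("`mask` must be a logical matrix with the same shape as `intensities`")
  }
  structure(
    list(intensities = intensities, spacing_mm = as.numeric(spacing_mm),
         iso_px = as.numeric(iso_px), mask = mask, frame = frame),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %dx%d px, %.3gx%.3g mm/px, frame=%s, iso=(%.1f, %.1f), %d%% valid>\n",
              nrow(x$intensities), ncol(x$intensities),
              x$spacing_mm[1], x$spacing_mm[2], x$frame,
              x$iso_px[1], x$iso_px[2], round(100 * mean(x$mask))))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$intensities)

is_image_grid <- function(x) inherits(x, "image_grid")

stopifnot_image_grid <- function(x, arg = deparse(substitute(x))) {
  if (!is_image_grid(x)) stop(sprintf("`%s` must be an image_grid", arg))
  invisible(x)
}

#' Convert between beam-frame mm and pixel coordinates
#'
#' @param grid an [image_grid()].
#' @param xy n x 2 matrix (or length-2 vector) of beam-frame mm coordinates
#'   (for `beam_to_px`) or 0-based `(col, row)` pixel coordinates (for
#'   `px_to_beam`).
#' @return n x 2 matrix in the other coordinate system.
#' @keywords internal
beam_to_px <- function(grid, xy) {
  xy <- rbind2mat(xy)
  cbind(grid$iso_px[1] + xy[, 1] / grid$spacing_mm[1],
        grid$iso_px[2] - xy[, 2] / grid$spacing_mm[2])
}

#' @rdname beam_to_px
#' @keywords internal
px_to_beam <- function(grid, xy) {
  xy <- rbind2mat(xy)
  cbind((xy[, 1] - grid$iso_px[1]) * grid$spacing_mm[1],
        -(xy[, 2] - grid$iso_px[2]) * grid$spacing_mm[2])
}

rbind2mat <- function(xy) {
  if (is.null(dim(xy))) matrix(xy, ncol = 2L) else as.matrix(xy)
}

#' Beam-frame coordinate matrices of every pixel center
#' @keywords internal
beam_coords <- function(grid) {
  nr <- nrow(grid$intensities); nc <- ncol(grid$intensities)
  x <- (seq_len(nc) - 1 - grid$iso_px[1]) * grid$spacing_mm[1]
  y <- -(seq_len(nr) - 1 - grid$iso_px[2]) * grid$spacing_mm[2]
  list(x = matrix(x, nr, nc, byrow = TRUE), y = matrix(y, nr, nc))
}

# Bilinear sampling at continuous 0-based (col,row) coordinates.
# Returns values and a validity flag; a sample is valid only when all four
# surrounding pixels are inside the image and mask-valid.
bilinear_sample <- function(mat, mask, cc, rr) {
  nr <- nrow(mat); nc <- ncol(mat)
  c0 <- floor(cc); r0 <- floor(rr)
  fc <- cc - c0; fr <- rr - r0
  # clamp the upper neighbour so exact-boundary samples stay valid
  at_right <- c0 == nc - 1 & fc == 0
  at_bottom <- r0 == nr - 1 & fr == 0
  c1 <- ifelse(at_right, c0, c0 + 1)
  r1 <- ifelse(at_bottom, r0, r0 + 1)
  inb <- c0 >= 0 & r0 >= 0 & c1 <= nc - 1 & r1 <= nr - 1
  c0i <- pmax(pmin(c0, nc - 1), 0); c1i <- pmax(pmin(c1, nc - 1), 0)
  r0i <- pmax(pmin(r0, nr - 1), 0); r1i <- pmax(pmin(r1, nr - 1), 0)
  i00 <- c0i * nr + r0i + 1; i01 <- c1i * nr + r0i + 1
  i10 <- c0i * nr + r1i + 1; i11 <- c1i * nr + r1i + 1
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc); w11 <- fr * fc
  val <- w00 * mat[i00] + w01 * mat[i01] + w10 * mat[i10] + w11 * mat[i11]
  ok <- inb & mask[i00] & mask[i01] & mask[i10] & mask[i11]
  val[!ok] <- 0
  list(values = val, valid = ok)
}

# Rigid resampling in the beam frame: the image CONTENT is translated by
# (dx,dy) mm and rotated by rot_deg (counter-clockwise, about the isocenter).
# Output pixel at beam coordinate p samples the input at Rot(-rot) (p - d).
# Integer-pixel pure translations take an exact shift fast path.
resample_rigid <- function(grid, dx_mm = 0, dy_mm = 0, rot_deg = 0) {
  stopifnot_image_grid(grid)
  if (dx_mm == 0 && dy_mm == 0 && rot_deg == 0) return(grid)
  nr <- nrow(grid$intensities); nc <- ncol(grid$intensities)
  sx <- grid$spacing_mm[1]; sy <- grid$spacing_mm[2]
  if (rot_deg == 0) {
    dc <- dx_mm / sx; dr <- -dy_mm / sy  # content shift in pixels
    if (abs(dc - round(dc)) < 1e-12 && abs(dr - round(dr)) < 1e-12) {
      dc <- round(dc); dr <- round(dr)
      out <- matrix(0, nr, nc); msk <- matrix(FALSE, nr, nc)
      src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
      keep_r <- src_r >= 1 & src_r <= nr; keep_c <- src_c >= 1 & src_c <= nc
      if (any(keep_r) && any(keep_c)) {
        out[which(keep_r), which(keep_c)] <-
          grid$intensities[src_r[keep_r], src_c[keep_c]]
        msk[which(keep_r), which(keep_c)] <-
          grid$mask[src_r[keep_r], src_c[keep_c]]
      }
      return(image_grid(out, grid$spacing_mm, grid$iso_px, msk, grid$frame))
    }
  }
  bc <- beam_coords(grid)
  a <- rot_deg * pi / 180
  xs <- bc$x - dx_mm; ys <- bc$y - dy_mm
  xr <- cos(a) * xs + sin(a) * ys
  yr <- -sin(a) * xs + cos(a) * ys
  cc <- grid$iso_px[1] + xr / sx
  rr <- grid$iso_px[2] - yr / sy
  s <- bilinear_sample(grid$intensities, grid$mask, cc, rr)
  out <- matrix(s$values, nr, nc)
  msk <- matrix(s$valid, nr, nc)
  image_grid(out, grid$spacing_mm, grid$iso_px, msk, grid$frame)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729 + 13) %% 2147483629)
}
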