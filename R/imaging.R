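#' Load a raster image as an image_grid
#'
#' Reads PNG, TIFF or JPEG rasters. Intensities are rescaled from the
#' reader's [0,1] range back to integer levels of the container bit depth
#' (8- or 16-bit), so a 10-bit scan stored in a 16-bit container keeps its
#' native 0..1023 values. Multichannel images are reduced to luminance by
#' channel averaging. Pixel spacing is not carried by these formats; it is
#' deferred to control-point calibration (see [control_point_spacing()])
#' unless supplied here.
#'
#' @param path image file path.
#' @param format_hint optional format override (`"png"`, `"tiff"`,
#'   `"jpeg"`); default from the file extension.
#' @param spacing_mm optional pixel spacing to stamp on the grid.
#' @return an [image_grid()] in plate frame.
#' @export
load_image <- function(path, format_hint = NULL, spacing_mm = c(1, 1)) {
  if (!file.exists(path)) stop(sprintf("cannot read image, no such file: %s", path))
  fmt <- tolower(if (is.null(format_hint)) tools::file_ext(path) else format_hint)
  arr <- switch(fmt,
    png = {
      r <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop(sprintf("unreadable PNG file %s: %s",
                                                     path, conditionMessage(e))))
      depth <- attr(r, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      unclass(r) * (2^depth - 1)
    },
    tif = ,
    tiff = {
      r <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) stop(sprintf("unreadable TIFF file %s: %s",
                                                     path, conditionMessage(e))))
      depth <- attr(r, "bits.per.sample")
      if (is.null(depth)) depth <- 16L
      unclass(r) * (2^depth - 1)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop(sprintf("JPEG support requires the EBImage package (file: %s)", path))
      r <- tryCatch(EBImage::readImage(path),
                    error = function(e) stop(sprintf("unreadable JPEG file %s: %s",
                                                     path, conditionMessage(e))))
      a <- EBImage::imageData(r) * 255
      if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
      t(a)  # EBImage stores x-major; transpose to row-major
    },
    stop(sprintf("unsupported image format '%s' for file %s (supported: png, tiff, jpeg)",
                 fmt, path))
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  arr <- matrix(as.numeric(arr), nrow(arr), ncol(arr))  # drop reader metadata
  image_grid(arr, spacing_mm = spacing_mm, frame = "plate")
}

#' Write an image or fusion composite as PNG
#'
#' Grayscale grids are rescaled to their masked min/max; fusion views are
#' written as RGB. 8-bit output, for display and reporting only.
#'
#' @param x an [image_grid()] or [fuse_complementary()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (inherits(x, "fusion_view")) {
    png::writePNG(x$rgb, path)
  } else {
    stopifnot_image_grid(x)
    v <- x$intensities
    rng <- range(v[x$mask])
    if (diff(rng) == 0) rng[2] <- rng[1] + 1
    png::writePNG(pmin(pmax((v - rng[1]) / diff(rng), 0), 1), path)
  }
  invisible(path)
}

#' Automatic window/level from the intensity histogram
#'
#' The display window spans the 1st to 99th percentile of the masked
#' intensities (robust to the burned-in graticule extremes), with the level
#' at its midpoint. A constant image gets a minimal window of one intensity
#' unit centered on its value.
#'
#' @param img an [image_grid()].
#' @return object of class `window_level` with fields `window` (width) and
#'   `level` (center), in intensity units.
#' @export
auto_window_level <- function(img) {
  stopifnot_image_grid(img)
  v <- img$intensities[img$mask]
  if (length(v) == 0L) stop("empty mask: no valid pixels to window")
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  if (diff(q) <= 0) return(window_level(1, q[1]))
  window_level(diff(q), mean(q))
}

#' Construct a window/level pair
#' @param window positive window width, intensity units.
#' @param level window center, intensity units.
#' @export
window_level <- function(window, level) {
  if (!is.finite(window) || window <= 0) stop("`window` must be positive")
  structure(list(window = as.numeric(window), level = as.numeric(level)),
            class = "window_level")
}

#' Apply a window/level mapping
#'
#' Linear display mapping: `level - window/2` maps to 0, `level + window/2`
#' to 1, clipped to [0,1]. Mask and geometry are preserved.
#'
#' @param img an [image_grid()].
#' @param wl a [window_level()]; default [auto_window_level()].
#' @return an [image_grid()] with intensities in [0,1].
#' @export
apply_window_level <- function(img, wl = NULL) {
  stopifnot_image_grid(img)
  if (is.null(wl)) wl <- auto_window_level(img)
  if (!inherits(wl, "window_level")) stop("`wl` must be a window_level")
  v <- (img$intensities - (wl$level - wl$window / 2)) / wl$window
  image_grid(pmin(pmax(v, 0), 1), img$spacing_mm, img$iso_px, img$mask, img$frame)
}

#' Shift and rotate an image about the isocenter
#'
#' Rigid manual adjustment of the (corrected, beam-frame) portal relative
#' to the stationary DRR: the image content moves by `(dx, dy)` mm in
#' beam-frame axes (+x right, +y up) and rotates counter-clockwise by
#' `rot_deg` about the isocenter, with bilinear resampling. Pixels pulled
#' from outside the source are flagged background.
#'
#' @param img an [image_grid()] in beam frame.
#' @param dx_mm,dy_mm content translation in mm.
#' @param rot_deg counter-clockwise rotation in degrees.
#' @return the resampled [image_grid()].
#' @export
shift_rotate <- function(img, dx_mm = 0, dy_mm = 0, rot_deg = 0) {
  stopifnot_image_grid(img)
  if (img$frame != "beam")
    stop("`img` must be in the beam frame (run correct_image first)")
  resample_rigid(img, dx_mm, dy_mm, rot_deg)
}

.color_pairs <- list(
  "red-cyan"      = list(a = 1L, b = c(2L, 3L)),
  "green-magenta" = list(a = 2L, b = c(1L, 3L)),
  "blue-yellow"   = list(a = 3L, b = c(1L, 2L))
)

#' Fuse two images in complementary colors
#'
#' The first (windowed) image drives one color channel set and the second
#' the complementary set — e.g. red-cyan assigns A to the red channel and B
#' to green+blue. Wherever the two windowed images are equal the composite
#' is a level of gray; misalignments show as color shadows.
#'
#' @param img_a,img_b [image_grid()]s in the same frame and shape, with
#'   intensities already windowed to [0,1] (see [apply_window_level()]).
#' @param color_pair one of `"red-cyan"`, `"green-magenta"`, `"blue-yellow"`.
#' @return object of class `fusion_view` with fields `rgb` (H x W x 3
#'   array), `color_pair` and `components`.
#' @export
fuse_complementary <- function(img_a, img_b, color_pair = "red-cyan") {
  stopifnot_image_grid(img_a); stopifnot_image_grid(img_b)
  if (!identical(dim(img_a$intensities), dim(img_b$intensities)))
    stop("fusion inputs must have identical shape")
  if (!identical(img_a$frame, img_b$frame))
    stop("fusion inputs must share a frame")
  cp <- .color_pairs[[match.arg(color_pair, names(.color_pairs))]]
  a <- pmin(pmax(img_a$intensities, 0), 1)
  b <- pmin(pmax(img_b$intensities, 0), 1)
  rgb <- array(0, c(nrow(a), ncol(a), 3L))
  rgb[, , cp$a] <- a
  for (ch in cp$b) rgb[, , ch] <- b
  structure(list(rgb = rgb, color_pair = color_pair,
                 components = list(a = img_a, b = img_b)),
            class = "fusion_view")
}

#' @export
print.fusion_view <- function(x, ...) {
  cat(sprintf("<fusion_view %dx%d px, %s>\n",
              dim(x$rgb)[1], dim(x$rgb)[2], x$color_pair))
  invisible(x)
}
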