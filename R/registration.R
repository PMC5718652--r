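#' Histogram specification for entropy and mutual information
#'
#' Intensities are binned into `n_bins` equal-width bins over each image's
#' range (by default the windowed [0,1] display range). 64 bins is a
#' practical compromise for deep-bit images: raw 1024 x 1024 joint bins
#' would be far too sparse at typical overlap sizes.
#'
#' @param n_bins number of histogram bins per image (>= 2).
#' @param range_a,range_b intensity bounds `(lo, hi)` per image; `NULL`
#'   means use that image's observed min/max over the evaluation mask.
#' @return object of class `histogram_spec`.
#' @export
histogram_spec <- function(n_bins = 64L, range_a = NULL, range_b = NULL) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("`n_bins` must be at least 2")
  chk <- function(r, nm) {
    if (!is.null(r) && (length(r) != 2L || !all(is.finite(r)) || r[2] <= r[1]))
      stop(sprintf("`%s` must be an increasing (lo, hi) pair", nm))
    r
  }
  structure(list(n_bins = n_bins, range_a = chk(range_a, "range_a"),
                 range_b = chk(range_b, "range_b")),
            class = "histogram_spec")
}

bin_indices <- function(v, rng, n) {
  if (is.null(rng)) rng <- range(v)
  if (rng[2] <= rng[1]) return(rep(1L, length(v)))
  pmin.int(pmax.int(floor((v - rng[1]) / (rng[2] - rng[1]) * n) + 1L, 1L), n)
}

#' Shannon entropy of a binned image
#'
#' `H = sum_i p_i log2(1/p_i)` over the histogram of valid pixels;
#' zero-probability bins contribute nothing. Reported in bits.
#'
#' @param img an [image_grid()].
#' @param spec a [histogram_spec()] (`range_a` applies).
#' @param region_mask optional extra logical matrix restricting the pixels
#'   used (e.g. the working-area box).
#' @return entropy in bits.
#' @export
entropy <- function(img, spec = histogram_spec(), region_mask = NULL) {
  stopifnot_image_grid(img)
  m <- img$mask
  if (!is.null(region_mask)) m <- m & region_mask
  v <- img$intensities[m]
  if (length(v) == 0L) stop("empty overlap: no valid pixels for entropy")
  p <- tabulate(bin_indices(v, spec$range_a, spec$n_bins), spec$n_bins)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}

#' Joint entropy of two images over their valid overlap
#'
#' `H(A,B) = -sum_ij p(i,j) log2 p(i,j)` from the 2D joint histogram of
#' same-position pixel pairs, restricted to pixels valid in both masks.
#'
#' @param img_a,img_b [image_grid()]s of identical shape.
#' @inheritParams entropy
#' @return joint entropy in bits.
#' @export
joint_entropy <- function(img_a, img_b, spec = histogram_spec(),
                          region_mask = NULL) {
  jh <- joint_counts(img_a, img_b, spec, region_mask)
  p <- jh$counts[jh$counts > 0] / jh$n
  -sum(p * log2(p))
}

joint_counts <- function(img_a, img_b, spec, region_mask = NULL) {
  stopifnot_image_grid(img_a); stopifnot_image_grid(img_b)
  if (!identical(dim(img_a$intensities), dim(img_b$intensities)))
    stop("images must have identical shape")
  m <- img_a$mask & img_b$mask
  if (!is.null(region_mask)) m <- m & region_mask
  n <- sum(m)
  if (n == 0L) stop("empty overlap: no jointly valid pixels")
  nb <- spec$n_bins
  ia <- bin_indices(img_a$intensities[m], spec$range_a, nb)
  ib <- bin_indices(img_b$intensities[m], spec$range_b, nb)
  counts <- tabulate((ia - 1L) * nb + ib, nb * nb)
  list(counts = counts, n = n, nb = nb)
}

#' Mutual information of two images
#'
#' `I(A,B) = H(A) + H(B) - H(A,B)`, all three entropies computed over the
#' jointly valid overlap (so `I(A,A) = H(A)` holds exactly and `I >= 0` up
#' to rounding). Reported in bits.
#'
#' @inheritParams joint_entropy
#' @return mutual information in bits.
#' @export
mutual_information <- function(img_a, img_b, spec = histogram_spec(),
                               region_mask = NULL) {
  jh <- joint_counts(img_a, img_b, spec, region_mask)
  jm <- matrix(jh$counts, jh$nb, jh$nb)  # rows: B bins, cols: A bins
  pa <- colSums(jm) / jh$n
  pb <- rowSums(jm) / jh$n
  pj <- jh$counts[jh$counts > 0] / jh$n
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h(pa) + h(pb) - h(pj)
}

#' Optimizer settings for automatic registration
#'
#' The shift search starts at a relatively large step (4 mm) to avoid
#' local maxima, then halves the step until the final resolution (1 mm by
#' default; set lower for submillimeter accuracy). Steps must halve exactly
#' from initial to final. Rotation, when enabled, is searched by a 1D
#' two-neighbor climb alternating with the shift search.
#'
#' @param initial_step_mm,final_step_mm shift step schedule; `initial`
#'   must be `final * 2^k` for integer `k >= 0`.
#' @param rot_enabled search in-plane rotation as well as shift.
#' @param rot_initial_step_deg,rot_final_step_deg rotation step schedule.
#' @param rot_range_deg rotation clamp, degrees about zero.
#' @param max_outer_iterations cap on shift/rotation alternations per level.
#' @param restrict_to_working_area evaluate MI only inside the working-area
#'   box spanned by the control points (reduces the influence of poorly
#'   corrected regions far from them).
#' @param n_bins histogram bins for the MI objective.
#' @return object of class `registration_config`.
#' @export
registration_config <- function(initial_step_mm = 4, final_step_mm = 1,
                                rot_enabled = TRUE,
                                rot_initial_step_deg = 2,
                                rot_final_step_deg = 0.25,
                                rot_range_deg = 5,
                                max_outer_iterations = 50L,
                                restrict_to_working_area = TRUE,
                                n_bins = 64L) {
  if (final_step_mm <= 0 || initial_step_mm < final_step_mm)
    stop("need initial_step_mm >= final_step_mm > 0")
  k <- log2(initial_step_mm / final_step_mm)
  if (abs(k - round(k)) > 1e-9)
    stop("`initial_step_mm` must equal `final_step_mm` times a power of two")
  if (rot_final_step_deg <= 0 || rot_initial_step_deg < rot_final_step_deg)
    stop("need rot_initial_step_deg >= rot_final_step_deg > 0")
  structure(list(initial_step_mm = initial_step_mm,
                 final_step_mm = final_step_mm,
                 rot_enabled = isTRUE(rot_enabled),
                 rot_initial_step_deg = rot_initial_step_deg,
                 rot_final_step_deg = rot_final_step_deg,
                 rot_range_deg = rot_range_deg,
                 max_outer_iterations = as.integer(max_outer_iterations),
                 restrict_to_working_area = isTRUE(restrict_to_working_area),
                 n_bins = as.integer(n_bins)),
            class = "registration_config")
}

#' Setup-error estimate
#'
#' The beam's-eye-view field shift in mm (+x right, +y up) and in-plane
#' rotation in degrees, with the mutual information at the optimum.
#'
#' @param dx_mm,dy_mm,rot_deg estimated offset components.
#' @param mi_score mutual information (bits) at this offset.
#' @param n_evals number of MI evaluations spent (0 if not tracked).
#' @return object of class `offset_estimate`.
#' @export
offset_estimate <- function(dx_mm = 0, dy_mm = 0, rot_deg = 0,
                            mi_score = NA_real_, n_evals = 0L) {
  structure(list(dx_mm = dx_mm, dy_mm = dy_mm, rot_deg = rot_deg,
                 mi_score = mi_score, n_evals = as.integer(n_evals)),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("<offset_estimate dx=%.3f mm dy=%.3f mm rot=%.3f deg (MI %.4f bits, %d evals)>\n",
              x$dx_mm, x$dy_mm, x$rot_deg, x$mi_score, x$n_evals))
  invisible(x)
}

# Shared MI evaluation context: windows both images once, precomputes the
# region mask and a memo table so repeated candidate offsets are not
# re-evaluated. Candidate (dx,dy,rot) means: the portal anatomy is believed
# displaced by +(dx,dy) and +rot relative to the DRR, so the portal is
# moved back by the negation before scoring.
mi_context <- function(portal, drr, config, working_area_mm = NULL) {
  stopifnot_image_grid(portal); stopifnot_image_grid(drr)
  if (!identical(dim(portal$intensities), dim(drr$intensities)))
    stop("portal and DRR must share the beam-frame grid (run correct_image)")
  spec <- histogram_spec(config$n_bins, range_a = c(0, 1), range_b = c(0, 1))
  pw <- apply_window_level(portal)
  dw <- apply_window_level(drr)
  region <- NULL
  if (config$restrict_to_working_area && !is.null(working_area_mm)) {
    bc <- beam_coords(drr)
    region <- abs(bc$x) <= working_area_mm & abs(bc$y) <= working_area_mm
  }
  memo <- new.env(parent = emptyenv())
  evals <- 0L
  score <- function(dx, dy, rot) {
    key <- paste(dx, dy, rot, sep = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    moved <- resample_rigid(pw, -dx, -dy, -rot)
    v <- mutual_information(moved, dw, spec, region)
    memo[[key]] <- v
    evals <<- evals + 1L
    v
  }
  list(score = score, n_evals = function() evals)
}

#' One fixed-step mutual-information hill climb over x-y shift
#'
#' From the starting offset, repeatedly evaluates the four axial neighbors
#' (+x, -x, +y, -y, in that fixed tie-break order) at the given step and
#' moves to a neighbor only if its MI is strictly higher; stops when the
#' current shift already yields the highest MI. The result's MI is never
#' below the start's.
#'
#' @param portal,drr [image_grid()]s on the same beam-frame grid.
#' @param start an [offset_estimate()] to start from.
#' @param step_mm fixed step size in mm.
#' @param config a [registration_config()] (histogram and masking options).
#' @param working_area_mm half-width of the working-area box, or `NULL`.
#' @param max_moves iteration guard; exceeding it is an error.
#' @param context internal: reuse an existing MI context.
#' @return an [offset_estimate()] at the local optimum.
#' @export
hill_climb_shift <- function(portal, drr, start = offset_estimate(),
                             step_mm, config = registration_config(),
                             working_area_mm = NULL, max_moves = 10000L,
                             context = NULL) {
  ctx <- if (is.null(context)) mi_context(portal, drr, config, working_area_mm) else context
  cur <- c(start$dx_mm, start$dy_mm)
  rot <- start$rot_deg
  best <- ctx$score(cur[1], cur[2], rot)
  moves <- 0L
  repeat {
    nb <- list(c(step_mm, 0), c(-step_mm, 0), c(0, step_mm), c(0, -step_mm))
    improved <- FALSE
    best_nb <- NULL; best_nb_mi <- best
    for (d in nb) {
      mi <- ctx$score(cur[1] + d[1], cur[2] + d[2], rot)
      if (mi > best_nb_mi) { best_nb_mi <- mi; best_nb <- d; improved <- TRUE }
    }
    if (!improved) break
    cur <- cur + best_nb
    best <- best_nb_mi
    moves <- moves + 1L
    if (moves > max_moves)
      stop(sprintf("shift hill climb did not converge within %d moves", max_moves))
  }
  offset_estimate(cur[1], cur[2], rot, best, ctx$n_evals())
}

# 1D rotation hill climb at fixed rotation step, range-clamped.
hill_climb_rot <- function(ctx, start, step_deg, range_deg, max_moves = 10000L) {
  cur <- start$rot_deg
  best <- ctx$score(start$dx_mm, start$dy_mm, cur)
  moves <- 0L
  repeat {
    cands <- c(cur + step_deg, cur - step_deg)
    cands <- cands[abs(cands) <= range_deg + 1e-12]
    improved <- FALSE
    for (r in cands) {
      mi <- ctx$score(start$dx_mm, start$dy_mm, r)
      if (mi > best) { best <- mi; cur <- r; improved <- TRUE; break }
    }
    if (!improved) break
    moves <- moves + 1L
    if (moves > max_moves)
      stop(sprintf("rotation hill climb did not converge within %d moves", max_moves))
  }
  offset_estimate(start$dx_mm, start$dy_mm, cur, best, ctx$n_evals())
}

#' Automatic setup-error estimation by multiresolution MI hill climbing
#'
#' Locates the x-y shift (and optionally in-plane rotation) of the portal
#' image relative to the DRR that maximizes their mutual information. The
#' best shift is first located at the initial step size; the step is then
#' halved and the climb repeated, down to the final step. When rotation is
#' enabled, shift and rotation searches alternate at each level until
#' neither improves. The algorithm is deterministic: identical inputs and
#' configuration always produce the identical estimate.
#'
#' @param portal,drr [image_grid()]s on the same beam-frame grid (the
#'   portal already corrected into the DRR frame).
#' @param config a [registration_config()].
#' @param start optional [offset_estimate()] starting point (default zero).
#' @param working_area_mm half-width in mm of the working-area box used to
#'   restrict the MI computation when
#'   `config$restrict_to_working_area` is set; default the conventional
#'   100 mm control-point distance.
#' @return an [offset_estimate()]: the estimated field shift, rotation, and
#'   the MI at the optimum.
#' @export
auto_register <- function(portal, drr, config = registration_config(),
                          start = offset_estimate(),
                          working_area_mm = 100) {
  ctx <- mi_context(portal, drr, config, working_area_mm)
  est <- start
  step <- config$initial_step_mm
  rot_step <- config$rot_initial_step_deg
  repeat {
    outer <- 0L
    repeat {
      before <- c(est$dx_mm, est$dy_mm, est$rot_deg)
      est <- hill_climb_shift(NULL, NULL, est, step, config, context = ctx)
      if (config$rot_enabled)
        est <- hill_climb_rot(ctx, est, rot_step, config$rot_range_deg)
      outer <- outer + 1L
      if (identical(before, c(est$dx_mm, est$dy_mm, est$rot_deg))) break
      if (outer >= config$max_outer_iterations) break
    }
    at_final <- step <= config$final_step_mm * (1 + 1e-12) &&
      (!config$rot_enabled || rot_step <= config$rot_final_step_deg * (1 + 1e-12))
    if (at_final) break
    step <- max(config$final_step_mm, step / 2)
    if (config$rot_enabled)
      rot_step <- max(config$rot_final_step_deg, rot_step / 2)
  }
  est
}
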