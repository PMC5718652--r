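#' Euclidean distance between estimated and actual offsets
#'
#' `sqrt((x - x0)^2 + (y - y0)^2)` in mm; the accuracy measure applied to
#' every estimate, human or automatic.
#'
#' @param est,actual length-2 offset vectors `(x, y)` in mm.
#' @return distance in mm.
#' @export
offset_distance <- function(est, actual) {
  if (any(!is.finite(est)) || any(!is.finite(actual)))
    stop("offsets must be finite")
  sqrt(sum((as.numeric(est) - as.numeric(actual))^2))
}

#' Consistency of two repeat estimates of one case
#'
#' The geometric distance between the two estimations of a single case by
#' the same observer or method; zero for a perfectly consistent method.
#'
#' @param est1,est2 length-2 estimated offsets in mm.
#' @param case_id1,case_id2 optional case ids, checked for equality.
#' @return distance in mm.
#' @export
consistency <- function(est1, est2, case_id1 = NULL, case_id2 = NULL) {
  if (!is.null(case_id1) && !is.null(case_id2) && !identical(case_id1, case_id2))
    stop(sprintf("consistency requires repeats of the same case (got '%s' and '%s')",
                 case_id1, case_id2))
  offset_distance(est1, est2)
}

#' Assemble an evaluation record table
#'
#' One row per presentation: case id, repeat index, method tag, true and
#' estimated offsets, and the recomputed distance.
#'
#' @param case_id character vector.
#' @param true_x,true_y,est_x,est_y numeric offset components in mm.
#' @param repeat_index integer vector (1 or 2).
#' @param method method tag (e.g. `"auto"`).
#' @return data frame of class `evaluation_records`.
#' @export
evaluation_records <- function(case_id, true_x, true_y, est_x, est_y,
                               repeat_index = 1L, method = "auto") {
  d <- data.frame(case_id = as.character(case_id),
                  repeat_index = as.integer(repeat_index),
                  method = as.character(method),
                  true_x = true_x, true_y = true_y,
                  est_x = est_x, est_y = est_y,
                  stringsAsFactors = FALSE)
  d$distance <- sqrt((d$est_x - d$true_x)^2 + (d$est_y - d$true_y)^2)
  class(d) <- c("evaluation_records", "data.frame")
  d
}

#' Summary statistics of an evaluation run
#'
#' Sample mean and standard deviation (n-1 denominator) of the per-record
#' distances, and of the per-case consistencies (distance between the two
#' repeat estimates of each case presented twice).
#'
#' @param records an [evaluation_records()] table with at least 2 rows.
#' @return list of class `summary_stats`: `mean_distance`, `sd_distance`,
#'   `mean_consistency`, `sd_consistency` (NA when no case has two
#'   repeats), `n`.
#' @export
summarize_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2L)
    stop("need at least two evaluation records")
  cons <- c()
  for (id in unique(records$case_id)) {
    r <- records[records$case_id == id, ]
    if (nrow(r) >= 2L) {
      r <- r[order(r$repeat_index), ]
      cons <- c(cons, offset_distance(c(r$est_x[1], r$est_y[1]),
                                      c(r$est_x[2], r$est_y[2])))
    }
  }
  structure(list(
    mean_distance = mean(records$distance),
    sd_distance = stats::sd(records$distance),
    mean_consistency = if (length(cons)) mean(cons) else NA_real_,
    sd_consistency = if (length(cons) > 1) stats::sd(cons) else NA_real_,
    n = nrow(records)), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d presentations\nmean distance   %.2f +/- %.2f mm\n",
              x$n, x$mean_distance, x$sd_distance))
  if (!is.na(x$mean_consistency))
    cat(sprintf("mean consistency %.2f +/- %.2f mm\n",
                x$mean_consistency, x$sd_consistency))
  invisible(x)
}

.bin_levels <- c("Good", "Fair", "Poor", "Terrible")

#' Classify a distance into accuracy bins
#'
#' Good (<= 2 mm), Fair (<= 5 mm), Poor (<= 10 mm), Terrible (> 10 mm),
#' with boundaries resolved to the smaller bin (half-open on the left,
#' closed on the right).
#'
#' @param d non-negative distance(s) in mm.
#' @return factor with levels Good, Fair, Poor, Terrible.
#' @export
bin_distance <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be non-negative")
  cut(d, breaks = c(-Inf, 2, 5, 10, Inf), labels = .bin_levels, right = TRUE)
}

#' Bin counts and percentages for a set of distances
#'
#' @param d distances in mm.
#' @return data frame with bin, count and percentage (of n) per row.
#' @export
bin_counts <- function(d) {
  tab <- table(bin_distance(d))
  data.frame(bin = factor(.bin_levels, levels = .bin_levels),
             count = as.integer(tab[.bin_levels]),
             percent = round(100 * as.integer(tab[.bin_levels]) / length(d)))
}

#' Paired t-test between two methods' distances
#'
#' Two-sided paired t-test of the null hypothesis that the population mean
#' of the within-pair differences is zero. Delegates to [stats::t.test()];
#' identical vectors (zero-variance differences) raise a degenerate-test
#' error rather than reporting a spurious p-value.
#'
#' @param distances_a,distances_b equal-length paired distance vectors,
#'   n >= 2.
#' @return list with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(distances_a, distances_b) {
  if (length(distances_a) != length(distances_b) || length(distances_a) < 2L)
    stop("need equal-length paired vectors of at least 2 observations")
  diffs <- distances_a - distances_b
  if (stats::sd(diffs) == 0)
    stop("degenerate paired t-test: the paired differences have zero variance")
  tt <- stats::t.test(distances_a, distances_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate))
}

#' Couch correction for a beam's-eye-view offset
#'
#' Maps a BEV field shift to the couch movement that cancels it, given the
#' gantry angle (collimator assumed at zero). Convention: the gantry
#' rotates about the patient's longitudinal axis; the BEV y component maps
#' to the longitudinal couch axis (`long = -dy`) and the BEV x component
#' splits between lateral and vertical (`lat = -dx cos(g)`,
#' `vert = +dx sin(g)`), so at gantry 0 the x shift is purely lateral and
#' at 90 degrees purely vertical.
#'
#' @param offset an [offset_estimate()] or length-2 `(dx, dy)` mm.
#' @param gantry_deg gantry angle in degrees.
#' @return named numeric vector `(lat, long, vert)` in mm.
#' @export
couch_correction <- function(offset, gantry_deg = 0) {
  if (inherits(offset, "offset_estimate")) offset <- c(offset$dx_mm, offset$dy_mm)
  g <- gantry_deg * pi / 180
  c(lat = -offset[1] * cos(g), long = -offset[2], vert = offset[1] * sin(g))
}

#' Run the synthetic phantom study end-to-end
#'
#' Reproduces the phantom experiment design in silico: build a scene,
#' render its DRR, draw a shuffled list of `n_offsets` true offsets (each
#' presented twice), render the degraded portal for every presentation,
#' estimate the offset with [auto_register()], and score the estimates.
#' Rotation search is off by default (the phantom study design considered
#' pure translations).
#'
#' @param kind `"chest"` or `"pelvis"`.
#' @param seed integer seed controlling scene jitter, offsets and noise.
#' @param n_offsets distinct offsets (default 5, i.e. 10 presentations).
#' @param size_px,spacing_mm rendering resolution.
#' @param contrast,noise_sigma degradation overrides (default per kind).
#' @param config a [registration_config()]; default 4 to 1 mm steps, no
#'   rotation search.
#' @return list with `records` ([evaluation_records()]), `summary`
#'   ([summarize_records()]), `cases`, and the rendered `drr`.
#' @export
run_phantom_study <- function(kind = c("chest", "pelvis"), seed = 1,
                              n_offsets = 5, size_px = 512, spacing_mm = 0.5,
                              contrast = NULL, noise_sigma = NULL,
                              config = registration_config(rot_enabled = FALSE)) {
  kind <- match.arg(kind)
  scene <- make_scene(kind, seed = derive_seed(seed, 11))
  drr <- render_drr(scene, size_px, spacing_mm)
  cases <- make_case_list(kind, n_offsets, seed = derive_seed(seed, 12),
                          contrast = contrast, noise_sigma = noise_sigma)
  rows <- vector("list", length(cases))
  est_cache <- new.env(parent = emptyenv())
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    est <- est_cache[[cs$case_id]]
    if (is.null(est)) {
      portal <- render_portal(scene, cs, size_px, spacing_mm)
      est <- auto_register(portal, drr, config)
      est_cache[[cs$case_id]] <- est  # repeats share the image, hence the estimate
    }
    rows[[i]] <- data.frame(case_id = cs$case_id,
                            repeat_index = cs$repeat_index,
                            true_x = cs$true_offset[1], true_y = cs$true_offset[2],
                            est_x = est$dx_mm, est_y = est$dy_mm,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  records <- evaluation_records(tab$case_id, tab$true_x, tab$true_y,
                                tab$est_x, tab$est_y, tab$repeat_index,
                                method = "auto")
  list(records = records, summary = summarize_records(records),
       cases = cases, drr = drr)
}
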