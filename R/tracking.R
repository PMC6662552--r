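#' Detect the animal position in one frame
#'
#' Single-target blob detection: the frame is polarity-corrected so the
#' animal is bright, thresholded with Otsu's method, and the largest
#' connected component (8-connectivity) is taken as the animal. Because the
#' animal covers a tiny fraction of a drop-plate frame, the Otsu threshold is
#' floored at a robust background ceiling (median + 4 MAD of the corrected
#' frame); without this guard Otsu splits the background noise mode when the
#' foreground class is almost empty. The returned position is the
#' intensity-weighted centroid of that component (weights = corrected
#' intensity above the threshold), in fractional 0-based pixel coordinates
#' (x = column, y = row, origin top-left). Deterministic for a fixed frame.
#'
#' @param frame A numeric matrix of intensities in `[0, 1]` (rows = y).
#' @param polarity `"dark"` for a dark animal on a light background (the
#'   drop-plate default) or `"light"` for the reverse.
#' @param min_area Minimum component area in pixels (default 5); smaller
#'   blobs are treated as noise.
#' @param frame_index Optional index attached to detection-failure errors.
#' @return A named numeric vector `c(x = , y = )`.
#' @export
detect_position <- function(frame, polarity = c("dark", "light"),
                            min_area = 5, frame_index = NA_integer_) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(frame), is.numeric(frame))
  corrected <- if (polarity == "dark") 1 - frame else frame
  fail <- function(msg) {
    abort(sprintf("Detection failure%s: %s",
                  if (is.na(frame_index)) "" else
                    sprintf(" (frame %d)", frame_index),
                  msg),
          class = "manipusel_error_detection", frame_index = frame_index)
  }
  if (diff(range(corrected)) < 1e-6) {
    fail("frame has no contrast (pure background).")
  }
  img <- EBImage::Image(t(corrected))
  thr <- EBImage::otsu(img, range = c(0, 1))
  floor_thr <- median(corrected) + 4 * stats::mad(corrected)
  thr <- max(thr, floor_thr)
  mask <- corrected > thr
  if (!any(mask)) fail("no pixels above the Otsu threshold.")
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  if (areas[biggest] < min_area) {
    fail(sprintf("largest component has area %d px < min_area %d px.",
                 areas[biggest], as.integer(min_area)))
  }
  idx <- which(lab == biggest, arr.ind = TRUE)
  w <- corrected[idx] - thr
  # pixel (row, col) 1-based has centre (x = col - 1, y = row - 1)
  c(x = sum(w * (idx[, "col"] - 1)) / sum(w),
    y = sum(w * (idx[, "row"] - 1)) / sum(w))
}

#' Call per-interval movement from a position sequence
#'
#' An interval is scored as moving if the displacement between its two
#' positions is at least `threshold_px` (inclusive, reading "at least"
#' literally; 5 px is roughly one copepod body length). Intervals adjacent to
#' a missing position are `NA` (missing), not `FALSE`.
#'
#' @param positions A data frame with columns `x`, `y` (possibly `NA` where
#'   detection failed), or a matrix with two columns.
#' @param threshold_px Movement threshold in pixels (default 5).
#' @param metric `"euclidean"` (default) or `"chebyshev"`.
#' @return A logical vector of length `nrow(positions) - 1`.
#' @export
call_movement <- function(positions, threshold_px = 5,
                          metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  if (is.matrix(positions)) {
    positions <- tibble(x = positions[, 1], y = positions[, 2])
  }
  positions <- as_tibble(positions)
  stopifnot(all(c("x", "y") %in% names(positions)))
  n <- nrow(positions)
  if (n < 2L) {
    abort("At least two positions are needed to call movement.",
          class = "manipusel_error_tracking")
  }
  dist_fun <- if (metric == "euclidean") euclid else cheby
  d <- dist_fun(positions$x[-n], positions$y[-n],
                positions$x[-1], positions$y[-1])
  d >= threshold_px
}

#' Proportion of intervals spent moving
#'
#' Missing (`NA`) intervals are excluded from both numerator and
#' denominator, keeping the statistic a proportion of observed intervals.
#'
#' @param moved Logical vector of per-interval movement flags.
#' @return A proportion in `[0, 1]`.
#' @export
activity_score <- function(moved) {
  ok <- !is.na(moved)
  if (!any(ok)) {
    abort("All intervals are missing; activity is undefined.",
          class = "manipusel_error_tracking")
  }
  sum(moved[ok]) / sum(ok)
}

#' Track one animal through a frame sequence
#'
#' Composition of [detect_position()], [call_movement()] and
#' [activity_score()] over the protocol window: frames sampled every
#' `interval_s` seconds for `window_s` seconds, starting `offset_s` seconds
#' after the simulated predator attack (defaults 2 s / 90 s / 10 s, so a full
#' recording is clipped to the `[10 s, 100 s]` window that excludes the
#' initial startle reaction). If the recording spans no more than `window_s`
#' it is assumed to be already extracted and is used whole. Detection
#' failures yield missing positions; intervals adjacent to a missing
#' position, or spanning a dropped frame (time gap larger than one sampling
#' step), are missing and excluded from the activity proportion.
#'
#' @param frames A `frame_sequence` (see [render_frames()],
#'   [read_frames_png()]), or a plain list of matrices with a `timestamps`
#'   attribute or accompanied by the `timestamps` argument.
#' @param timestamps Optional acquisition times (seconds) overriding the
#'   attribute.
#' @inheritParams detect_position
#' @inheritParams call_movement
#' @param interval_s Sampling interval in seconds (default 2).
#' @param window_s Analysis window length in seconds (default 90).
#' @param offset_s Window start relative to the drop (default 10).
#' @return An object of class `track_result`: `positions` (tibble `frame`,
#'   `t_s`, `x`, `y`, `detected`), `moved` (logical per interval, `NA` =
#'   missing), `activity`, `n_intervals` (non-missing intervals), and the
#'   tracking settings.
#' @examples
#' tr <- generate_trajectory(trajectory_params(p_move = 0.4, seed = 11))
#' frames <- render_frames(tr)
#' res <- track_sequence(frames)
#' all.equal(res$activity, tr$activity)
#' @export
track_sequence <- function(frames, timestamps = NULL,
                           polarity = c("dark", "light"),
                           threshold_px = 5, metric = c("euclidean",
                                                        "chebyshev"),
                           interval_s = 2, window_s = 90, offset_s = 10,
                           min_area = 5) {
  polarity <- match.arg(polarity)
  metric <- match.arg(metric)
  ts <- timestamps %||% attr(frames, "timestamps")
  if (is.null(ts)) ts <- (seq_along(frames) - 1) * interval_s
  if (length(ts) != length(frames)) {
    abort("`timestamps` must have one entry per frame.",
          class = "manipusel_error_tracking")
  }
  if (is.unsorted(ts, strictly = TRUE)) {
    abort("Timestamps must be strictly increasing.",
          class = "manipusel_error_tracking")
  }
  # protocol-window selection: only clip when the recording extends past the
  # window (e.g. a full 15-min video); an already-extracted sequence is used
  # whole
  keep <- if (max(ts) - min(ts) > window_s + interval_s / 2) {
    ts >= offset_s - 1e-9 & ts <= offset_s + window_s + 1e-9
  } else {
    rep(TRUE, length(ts))
  }
  ts <- ts[keep]
  frames <- frames[keep]
  if (length(frames) < 2L) {
    abort("Fewer than 2 frames in the analysis window.",
          class = "manipusel_error_tracking")
  }
  pos <- purrr::imap(frames, function(f, i) {
    tryCatch(detect_position(f, polarity = polarity, min_area = min_area,
                             frame_index = i),
             manipusel_error_detection = function(e) c(x = NA_real_,
                                                       y = NA_real_))
  })
  positions <- tibble(
    frame = seq_along(frames) - 1L,
    t_s = ts,
    x = map_dbl(pos, "x"),
    y = map_dbl(pos, "y")
  ) |> mutate(detected = !is.na(.data$x))
  moved <- call_movement(positions, threshold_px = threshold_px,
                         metric = metric)
  gap <- diff(ts) > interval_s * 1.5
  moved[gap] <- NA
  if (!any(!is.na(moved))) {
    abort("No usable intervals in the analysis window.",
          class = "manipusel_error_tracking")
  }
  structure(
    list(positions = positions, moved = moved,
         activity = activity_score(moved),
         n_intervals = sum(!is.na(moved)),
         settings = list(polarity = polarity, threshold_px = threshold_px,
                         metric = metric, interval_s = interval_s,
                         window_s = window_s, offset_s = offset_s,
                         min_area = min_area)),
    class = "track_result"
  )
}

#' @export
print.track_result <- function(x, ...) {
  cat("<track_result> ", nrow(x$positions), " frames, ",
      x$n_intervals, " usable intervals, activity ",
      format(x$activity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.track_result <- function(x, ...) {
  x$positions |>
    mutate(moved = c(x$moved, NA))
}

#' @export
glance.track_result <- function(x, ...) {
  tibble(activity = x$activity, n_frames = nrow(x$positions),
         n_intervals = x$n_intervals,
         n_detected = sum(x$positions$detected),
         threshold_px = x$settings$threshold_px)
}
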