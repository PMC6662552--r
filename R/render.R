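#' Render grayscale frames from animal positions
#'
#' Rasterizes one frame per position: a disc of `blob_radius` at the (possibly
#' fractional) position on a constant background, with edge-coverage
#' anti-aliasing (boundary pixels get intensity proportional to the covered
#' fraction, approximated by `clamp(radius + 0.5 - d, 0, 1)` at distance `d`
#' from the disc centre), plus optional i.i.d. Gaussian pixel noise. With
#' `noise_sd = 0` the intensity-weighted centroid of each rendered frame
#' matches the ground-truth position to within 0.5 px.
#'
#' @param positions A `trajectory` object from [generate_trajectory()], or a
#'   data frame with columns `x`, `y` (0-based pixel coordinates).
#' @param render A [render_params()] object.
#' @param arena_size Width and height in pixels; taken from the trajectory's
#'   params when `positions` is a trajectory.
#' @param seed Integer seed for the pixel-noise stream (one substream per
#'   frame, so rendering a subset of frames reproduces the full-run pixels).
#' @return A list of class `frame_sequence`: numeric matrices in `[0, 1]`
#'   (rows = y, columns = x), with attributes `timestamps` (seconds) and
#'   `render` (the parameters used).
#' @export
render_frames <- function(positions, render = render_params(),
                          arena_size = NULL, seed = 1L) {
  stopifnot(inherits(render, "render_params"))
  if (inherits(positions, "trajectory")) {
    arena_size <- positions$params$arena_size
    ts <- positions$positions$t_s
    pos <- positions$positions[, c("x", "y")]
  } else {
    pos <- as_tibble(positions)
    if (!all(c("x", "y") %in% names(pos))) {
      stop_params("`positions` must have columns `x` and `y`.")
    }
    ts <- if ("t_s" %in% names(pos)) pos$t_s else (seq_len(nrow(pos)) - 1) * 2
    if (is.null(arena_size)) {
      stop_params("`arena_size` is required when `positions` is not a trajectory.")
    }
  }
  if (nrow(pos) == 0L || anyNA(pos$x) || anyNA(pos$y)) {
    abort("Every frame needs an animal position; background-only frames are not rendered.",
          class = "manipusel_error_render")
  }
  w <- arena_size[1]; h <- arena_size[2]
  r <- render$blob_radius
  if (any(pos$x < r | pos$x > w - 1 - r | pos$y < r | pos$y > h - 1 - r)) {
    abort("Blob out of bounds: a position is closer than `blob_radius` to the arena edge.",
          class = "manipusel_error_render")
  }
  frames <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    f <- render_disc(pos$x[i], pos$y[i], w, h, render)
    if (render$noise_sd > 0) {
      f <- f + withr::with_seed(
        substream_seed(seed, 2L, i),
        matrix(rnorm(h * w, 0, render$noise_sd), nrow = h)
      )
      f <- clamp01(f)
    }
    frames[[i]] <- f
  }
  structure(frames, timestamps = ts, render = render,
            class = "frame_sequence")
}

render_disc <- function(x0, y0, w, h, render) {
  f <- matrix(render$background_intensity, nrow = h, ncol = w)
  r <- render$blob_radius
  rows <- max(1L, floor(y0 - r)):min(h, ceiling(y0 + r) + 2L)
  cols <- max(1L, floor(x0 - r)):min(w, ceiling(x0 + r) + 2L)
  # pixel (row, col) 1-based has centre (x = col - 1, y = row - 1)
  d <- sqrt(outer((rows - 1 - y0)^2, (cols - 1 - x0)^2, `+`))
  cov <- pmin(1, pmax(0, r + 0.5 - d))
  f[rows, cols] <- render$background_intensity +
    (render$blob_intensity - render$background_intensity) * cov
  f
}

#' Write a frame sequence as 8-bit grayscale PNG files
#'
#' Files are named `plate_<id>_frame_<k>.png` with `k` zero-padded and
#' 0-based.
#'
#' @param frames A `frame_sequence` from [render_frames()].
#' @param dir Output directory (created if needed).
#' @param plate_id Identifier used in the filenames.
#' @return Invisibly, a tibble with columns `frame`, `t_s`, `path`.
#' @export
write_frames_png <- function(frames, dir, plate_id = "p01") {
  stopifnot(inherits(frames, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- attr(frames, "timestamps")
  width <- max(4L, nchar(as.character(length(frames) - 1L)))
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    k <- sprintf(paste0("%0", width, "d"), i - 1L)
    paths[i] <- file.path(dir, sprintf("plate_%s_frame_%s.png", plate_id, k))
    png::writePNG(frames[[i]], paths[i])
  }
  invisible(tibble(frame = seq_along(frames) - 1L, t_s = ts, path = paths))
}

#' Read a directory (or vector) of grayscale PNG frames
#'
#' @param x A directory containing `*_frame_*.png` files, or a character
#'   vector of file paths. Frames are ordered by the zero-padded frame index
#'   in the filename (falling back to lexical order).
#' @param timestamps Optional vector of acquisition times in seconds; defaults
#'   to `offset_s + interval_s * frame_index`.
#' @param interval_s,offset_s Sampling interval and time of the first frame,
#'   used when `timestamps` is absent.
#' @return A `frame_sequence` (list of matrices with a `timestamps`
#'   attribute).
#' @export
read_frames_png <- function(x, timestamps = NULL, interval_s = 2,
                            offset_s = 0) {
  files <- if (length(x) == 1L && dir.exists(x)) {
    sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
  } else {
    as.character(x)
  }
  if (length(files) == 0L) {
    abort("No PNG frames found.", class = "manipusel_error_io")
  }
  idx <- suppressWarnings(
    as.integer(sub(".*_frame_([0-9]+)\\.png$", "\\1", basename(files)))
  )
  if (!anyNA(idx)) files <- files[order(idx)]
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  if (is.null(timestamps)) {
    timestamps <- offset_s + interval_s * (seq_along(frames) - 1)
  }
  structure(frames, timestamps = timestamps, class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x[[1]])
  cat("<frame_sequence> ", length(x), " frames of ", d[2], "x", d[1],
      " px\n", sep = "")
  invisible(x)
}
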