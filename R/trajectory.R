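#' Simulate a ground-truth single-animal trajectory
#'
#' Draws one copepod trajectory under the two-state interval model of
#' [trajectory_params()]: each of the `n_frames - 1` intervals is
#' independently moving (displacement `step_px` in a uniform random direction)
#' with probability `p_move`, otherwise jittering (displacement uniform on
#' `[0, jitter_px]`). Positions are reflected at the arena walls. The
#' ground-truth movement flag of interval `i` is defined from the realized
#' positions: `TRUE` iff the Euclidean displacement between frames `i` and
#' `i + 1` is at least `threshold_px`, so the flags (and the true activity,
#' their mean) can always be recomputed exactly from the emitted coordinates.
#'
#' @param params A [trajectory_params()] object.
#' @return A list of class `trajectory` with elements `positions` (tibble:
#'   `frame` 0-based, `t_s`, `x`, `y` in 0-based pixel coordinates, origin
#'   top-left, x = column, y = row), `moved` (logical, one per interval),
#'   `activity` (mean of `moved`) and `params`.
#' @examples
#' tr <- generate_trajectory(trajectory_params(p_move = 0.4, seed = 7))
#' tr$activity
#' @export
generate_trajectory <- function(params) {
  stopifnot(inherits(params, "trajectory_params"))
  n <- params$n_frames
  w <- params$arena_size[1]
  h <- params$arena_size[2]
  m <- params$margin_px
  pos <- matrix(NA_real_, nrow = n, ncol = 2)
  withr::with_seed(substream_seed(params$seed, 1L), {
    pos[1, ] <- c(runif(1, 0.25 * w, 0.75 * w), runif(1, 0.25 * h, 0.75 * h))
    moving <- runif(n - 1) < params$p_move
    theta <- runif(n - 1, 0, 2 * pi)
    mag <- ifelse(moving, params$step_px, runif(n - 1, 0, params$jitter_px))
    for (i in seq_len(n - 1)) {
      nxt <- pos[i, ] + mag[i] * c(cos(theta[i]), sin(theta[i]))
      pos[i + 1, ] <- c(reflect_into(nxt[1], w, m), reflect_into(nxt[2], h, m))
    }
  })
  d <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  moved <- d >= params$threshold_px
  list2trajectory(pos, moved, params)
}

list2trajectory <- function(pos, moved, params) {
  structure(
    list(
      positions = tibble(
        frame = seq_len(nrow(pos)) - 1L,
        t_s = (seq_len(nrow(pos)) - 1L) * params$frame_interval,
        x = pos[, 1], y = pos[, 2]
      ),
      moved = moved,
      activity = mean(moved),
      params = params
    ),
    class = "trajectory"
  )
}

# Reflect a coordinate into [margin, size - 1 - margin]; repeated folding
# handles overshoots larger than the arena (not reachable at sane step sizes,
# but safe). The margin keeps a rendered blob fully inside the frame.
reflect_into <- function(x, size, margin = 0) {
  lo <- margin
  hi <- size - 1 - margin
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$positions), " frames, true activity ",
      format(x$activity, digits = 4), "\n", sep = "")
  invisible(x)
}
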