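#' Parameters for a single-animal ground-truth trajectory
#'
#' Defines the random walk used to simulate one copepod in a drop-plate arena.
#' Each inter-frame interval is independently "moving" with probability
#' `p_move`; moving intervals displace the animal by `step_px` in a uniformly
#' random direction, non-moving intervals add sub-threshold positional jitter
#' of magnitude at most `jitter_px`. Positions are kept inside the arena by
#' reflection at the walls. Ground-truth movement flags are defined from the
#' realized positions (displacement at least `threshold_px`), so they are
#' exactly recomputable from the emitted coordinates.
#'
#' @param n_frames Number of frames (default 46: one frame every 2 s covering
#'   90 s inclusive of both endpoints, giving 45 intervals).
#' @param frame_interval Seconds between frames (default 2).
#' @param p_move Probability that an interval is a moving interval.
#' @param step_px Displacement magnitude (pixels) of a moving interval; must be
#'   at least `threshold_px`.
#' @param jitter_px Maximum positional noise (pixels) of a non-moving interval;
#'   must be strictly below `threshold_px`.
#' @param arena_size Arena width and height in pixels, length-2 numeric.
#' @param threshold_px Movement threshold in pixels (default 5, roughly one
#'   copepod body length).
#' @param margin_px Boundary margin (default 4): positions are reflected into
#'   `[margin_px, size - 1 - margin_px]` so a rendered blob stays fully
#'   inside the frame.
#' @param seed Integer seed for this trajectory's random stream.
#' @return An object of class `trajectory_params`.
#' @seealso [generate_trajectory()]
#' @export
trajectory_params <- function(n_frames = 46L,
                              frame_interval = 2,
                              p_move = 0.5,
                              step_px = 8,
                              jitter_px = 1.5,
                              arena_size = c(120, 120),
                              threshold_px = 5,
                              margin_px = 4,
                              seed = 1L) {
  n_frames <- assert_count(n_frames, "n_frames", min = 2L)
  assert_number(frame_interval, "frame_interval", min = 1e-9)
  assert_number(p_move, "p_move", min = 0, max = 1)
  assert_number(step_px, "step_px", min = 0)
  assert_number(jitter_px, "jitter_px", min = 0)
  assert_number(threshold_px, "threshold_px", min = 1e-9)
  if (length(arena_size) != 2L || any(arena_size <= 0)) {
    stop_params("`arena_size` must be two positive numbers (width, height).")
  }
  assert_number(margin_px, "margin_px", min = 0)
  if (any(arena_size - 1 - 2 * margin_px <= 2 * step_px)) {
    stop_params("`arena_size` is too small for `step_px` and `margin_px`.")
  }
  if (step_px < threshold_px) {
    stop_params("`step_px` must be >= `threshold_px`; otherwise a drawn moving interval could not reach the movement threshold and the ground truth would be ill-defined.")
  }
  if (jitter_px >= threshold_px) {
    stop_params("`jitter_px` must be < `threshold_px`; otherwise a non-moving interval could cross the movement threshold and the ground truth would be ill-defined.")
  }
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(n_frames = n_frames, frame_interval = frame_interval,
         p_move = p_move, step_px = step_px, jitter_px = jitter_px,
         arena_size = as.numeric(arena_size), threshold_px = threshold_px,
         margin_px = margin_px, seed = seed),
    class = "trajectory_params"
  )
}

#' Parameters for rendering frames from a trajectory
#'
#' Controls how a simulated copepod is rasterized: a disc of `blob_radius`
#' pixels at the animal's position, drawn with edge coverage weighting (partial
#' intensity on boundary pixels) on a constant background, plus optional
#' i.i.d. Gaussian pixel noise.
#'
#' @param blob_radius Disc radius in pixels (default 2.5, so the disc diameter
#'   matches the 5 px movement threshold / one body length).
#' @param blob_intensity Gray level of the animal, in `[0, 1]`.
#' @param background_intensity Gray level of the background, in `[0, 1]`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (gray levels, same `[0, 1]` scale).
#' @param bit_depth 8 or 16; used when frames are written as PNG.
#' @return An object of class `render_params`.
#' @seealso [render_frames()]
#' @export
render_params <- function(blob_radius = 2.5,
                          blob_intensity = 0.15,
                          background_intensity = 0.85,
                          noise_sd = 0,
                          bit_depth = 8L) {
  assert_number(blob_radius, "blob_radius", min = 0.5)
  assert_number(blob_intensity, "blob_intensity", min = 0, max = 1)
  assert_number(background_intensity, "background_intensity", min = 0, max = 1)
  assert_number(noise_sd, "noise_sd", min = 0)
  if (!bit_depth %in% c(8L, 16L)) stop_params("`bit_depth` must be 8 or 16.")
  structure(
    list(blob_radius = blob_radius, blob_intensity = blob_intensity,
         background_intensity = background_intensity, noise_sd = noise_sd,
         bit_depth = as.integer(bit_depth)),
    class = "render_params"
  )
}

#' Parameters for a synthetic behaviour cohort
#'
#' Defines the variance structure and stage effects of a simulated cohort of
#' copepods observed on days 6, 7, 8 (pre-infectivity, predation suppression)
#' and 13, 14, 15 (post-infectivity, predation enhancement). Per-record
#' activity is
#' `clamp01(baseline + replicate + individual + stage x infection + drift_per_day * day + trait term + residual)`.
#' Infected hosts additionally carry a latent manipulation-amplitude trait
#' `m ~ N(0, trait_sd^2)` expressed as `-m/2` during suppression and `+m/2`
#' during enhancement, so a host's manipulation score gains `+m`; this trait
#' (not the activity intercept, which cancels in a post-minus-pre score) is the
#' heritable target of selection, with parent-offspring regression slope `h2`.
#'
#' @param n_per_cell Copepods per line x infection-status cell, spread as
#'   evenly as possible over the replicates.
#' @param var_id Among-copepod variance of the activity intercept
#'   (default 0.0031).
#' @param var_replicate Among-replicate variance (default 0.0004).
#' @param var_resid Residual (within-copepod, between-day) variance
#'   (default 0.0231).
#' @param baseline Mean activity of uninfected hosts (default 0.5,
#'   mid-proportion so clamping to `[0, 1]` is rare at the default variances).
#' @param effect_suppression Additive activity shift in infected hosts on days
#'   6-8 (default -0.2; negative = predation suppression).
#' @param effect_enhancement Additive shift in infected hosts on days 13-15
#'   (default +0.1; positive = predation enhancement).
#' @param drift_per_day Habituation slope applied to every host (activity per
#'   day, default 0.002; chosen small so that, with the default variances and
#'   stage effects, clamping to `[0, 1]` stays below 1% of draws).
#' @param h2 Parent-offspring regression slope of the latent manipulation
#'   trait (default 0.5).
#' @param trait_sd SD of the latent manipulation-amplitude trait
#'   (default 0.07).
#' @param segregation_sd SD of within-family segregation noise added to
#'   offspring traits (default `trait_sd / sqrt(2)`, the infinitesimal-model
#'   convention of half the additive variance).
#' @param n_replicates Number of replicate populations (default 3, one per
#'   parasite family).
#' @param seed Master integer seed; per-copepod streams are derived from it by
#'   counter so that subsetting one copepod never shifts another's draws.
#' @return An object of class `cohort_params`.
#' @seealso [generate_cohort()], [generate_experiment()]
#' @export
cohort_params <- function(n_per_cell = 100L,
                          var_id = 0.0031,
                          var_replicate = 0.0004,
                          var_resid = 0.0231,
                          baseline = 0.5,
                          effect_suppression = -0.2,
                          effect_enhancement = 0.1,
                          drift_per_day = 0.002,
                          h2 = 0.5,
                          trait_sd = 0.07,
                          segregation_sd = NULL,
                          n_replicates = 3L,
                          seed = 1L) {
  n_per_cell <- assert_count(n_per_cell, "n_per_cell", min = 1L)
  assert_number(var_id, "var_id", min = 0)
  assert_number(var_replicate, "var_replicate", min = 0)
  assert_number(var_resid, "var_resid", min = 0)
  assert_number(baseline, "baseline", min = 0, max = 1)
  assert_number(effect_suppression, "effect_suppression", min = -1, max = 1)
  assert_number(effect_enhancement, "effect_enhancement", min = -1, max = 1)
  assert_number(drift_per_day, "drift_per_day", min = -1, max = 1)
  assert_number(h2, "h2", min = 0, max = 1)
  assert_number(trait_sd, "trait_sd", min = 0)
  if (is.null(segregation_sd)) segregation_sd <- trait_sd / sqrt(2)
  assert_number(segregation_sd, "segregation_sd", min = 0)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 1L)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(n_per_cell = n_per_cell, var_id = var_id,
         var_replicate = var_replicate, var_resid = var_resid,
         baseline = baseline, effect_suppression = effect_suppression,
         effect_enhancement = effect_enhancement,
         drift_per_day = drift_per_day, h2 = h2, trait_sd = trait_sd,
         segregation_sd = segregation_sd, n_replicates = n_replicates,
         seed = seed),
    class = "cohort_params"
  )
}

#' @export
print.trajectory_params <- function(x, ...) {
  cat("<trajectory_params> ", x$n_frames, " frames @ ", x$frame_interval,
      " s; p_move = ", x$p_move, ", step = ", x$step_px, " px, jitter = ",
      x$jitter_px, " px, threshold = ", x$threshold_px, " px\n", sep = "")
  invisible(x)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params> ", x$n_per_cell, " copepods / line x status over ",
      x$n_replicates, " replicates; var(id, repl, resid) = (",
      x$var_id, ", ", x$var_replicate, ", ", x$var_resid, ")\n", sep = "")
  invisible(x)
}
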