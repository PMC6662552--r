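test_that("detection recovers a rendered disc position to sub-pixel accuracy", {
  fr <- render_frames(tibble::tibble(x = 40, y = 25), render_params(),
                      arena_size = c(80, 50))
  pos <- detect_position(fr[[1]], polarity = "dark")
  expect_lt(abs(pos["x"] - 40), 0.5)
  expect_lt(abs(pos["y"] - 25), 0.5)
  # light-on-dark polarity on the inverted frame finds the same blob
  pos2 <- detect_position(1 - fr[[1]], polarity = "light")
  expect_lt(abs(pos2["x"] - 40), 0.5)
})

test_that("a featureless frame raises a detection failure", {
  flat <- matrix(0.85, nrow = 40, ncol = 40)
  expect_error(detect_position(flat, frame_index = 7L),
               class = "manipusel_error_detection")
  err <- tryCatch(detect_position(flat, frame_index = 7L),
                  manipusel_error_detection = identity)
  expect_identical(err$frame_index, 7L)
})

test_that("centroid error stays below a pixel at 5% contrast noise", {
  tr <- generate_trajectory(trajectory_params(seed = 41))
  contrast <- abs(render_params()$blob_intensity -
                    render_params()$background_intensity)
  fr <- render_frames(tr, render_params(noise_sd = 0.05 * contrast),
                      seed = 41)
  est <- purrr::map(fr, detect_position)
  err <- purrr::map2_dbl(est, seq_len(nrow(tr$positions)), function(p, i) {
    sqrt((p[["x"]] - tr$positions$x[i])^2 + (p[["y"]] - tr$positions$y[i])^2)
  })
  expect_lt(mean(err), 1)
})

test_that("the 5-pixel movement rule is inclusive and boundary-exact", {
  pos <- tibble::tibble(x = c(0, 3, 3, 6), y = c(0, 4, 4, 7.999))
  moved <- call_movement(pos, threshold_px = 5)
  expect_identical(moved, c(TRUE, FALSE, FALSE))  # 5 >= 5; 0 < 5; 4.999 < 5
  # chebyshev option: (0,0) -> (4,4.9) is 4.9 < 5 but euclid ~ 6.3
  diag_pos <- tibble::tibble(x = c(0, 4), y = c(0, 4.9))
  expect_false(call_movement(diag_pos, metric = "chebyshev"))
  expect_true(call_movement(diag_pos, metric = "euclidean"))
})

test_that("missing positions poison adjacent intervals only", {
  pos <- tibble::tibble(x = c(0, 10, NA, 30, 31), y = 0)
  moved <- call_movement(pos)
  expect_identical(moved, c(TRUE, NA, NA, FALSE))
  expect_equal(activity_score(moved), 0.5)
  expect_error(activity_score(c(NA, NA)),
               class = "manipusel_error_tracking")
})

test_that("activity is the proportion of observed moving intervals", {
  expect_equal(activity_score(rep(FALSE, 45)), 0)
  expect_equal(activity_score(rep(TRUE, 45)), 1)
  expect_equal(activity_score(c(rep(TRUE, 18), rep(FALSE, 27))), 0.4)
})

test_that("noise-free tracking reproduces ground truth exactly", {
  for (s in c(2, 14, 77)) {
    tr <- generate_trajectory(trajectory_params(p_move = 0.5, seed = s))
    res <- track_sequence(render_frames(tr))
    expect_identical(res$moved, tr$moved)
    expect_identical(res$activity, tr$activity)
  }
})

test_that("a dropped frame leaves 43 usable intervals", {
  tr <- generate_trajectory(trajectory_params(seed = 51))
  fr <- render_frames(tr)
  keep <- setdiff(seq_along(fr), 20)
  sub <- structure(fr[keep], timestamps = attr(fr, "timestamps")[keep],
                   class = "frame_sequence")
  res <- track_sequence(sub)
  expect_equal(res$n_intervals, 43)
  expect_true(is.na(res$moved[19]))  # the interval spanning the gap
  expect_equal(res$activity, mean(res$moved, na.rm = TRUE))
})

test_that("a long recording is clipped to the post-drop protocol window", {
  p <- trajectory_params(n_frames = 120, seed = 55)  # 0..238 s at 2 s
  tr <- generate_trajectory(p)
  fr <- render_frames(tr)
  res <- track_sequence(fr, window_s = 90, offset_s = 10)
  expect_equal(nrow(res$positions), 46)
  expect_equal(range(res$positions$t_s), c(10, 100))
  # ground truth restricted to the same window
  idx <- which(tr$positions$t_s >= 10 & tr$positions$t_s <= 100)
  truth <- flags_from_positions(tr$positions[idx, ], p$threshold_px)
  expect_identical(res$moved, truth)
})

test_that("raising the threshold never increases activity", {
  tr <- generate_trajectory(trajectory_params(p_move = 0.5, seed = 61,
                                              jitter_px = 3,
                                              threshold_px = 4))
  acts <- purrr::map_dbl(c(2, 4, 6, 9, 12), function(th) {
    activity_score(call_movement(tr$positions, threshold_px = th))
  })
  expect_true(all(diff(acts) <= 0))
})

test_that("tracking is bitwise deterministic", {
  tr <- generate_trajectory(trajectory_params(seed = 71))
  fr <- render_frames(tr, render_params(noise_sd = 0.02), seed = 3)
  expect_identical(track_sequence(fr), track_sequence(fr))
})

test_that("activity error stays small at contrast-to-noise 20", {
  errs <- purrr::map_dbl(c(5, 6, 7), function(s) {
    tr <- generate_trajectory(trajectory_params(seed = s))
    contrast <- abs(render_params()$blob_intensity -
                      render_params()$background_intensity)
    fr <- render_frames(tr, render_params(noise_sd = contrast / 20),
                        seed = s)
    abs(track_sequence(fr)$activity - tr$activity)
  })
  expect_lte(max(errs), 0.05)
})
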