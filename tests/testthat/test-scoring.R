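test_that("stage means are plain arithmetic over the two windows", {
  rec <- make_records(list(a = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)))
  sm <- stage_means(rec)
  expect_equal(sm$a_pre, 0.3)
  expect_equal(sm$a_post, 0.6)
  expect_equal(sm$n_pre, 3L)
  expect_equal(sm$n_post, 3L)

  same <- make_records(list(b = rep(0.4, 6)))
  sm2 <- stage_means(same)
  expect_equal(sm2$a_pre, sm2$a_post)
})

test_that("a missing day leaves the mean of the remaining days", {
  rec <- make_records(list(a = c(0.2, 0.4)), days = c(6, 7)) |>
    dplyr::bind_rows(make_records(list(a = c(0.5, 0.6, 0.7)),
                                  days = c(13, 14, 15)))
  sm <- stage_means(rec)
  expect_equal(sm$a_pre, 0.3)
  expect_equal(sm$n_pre, 2L)
  sc <- quiet_scores(rec, require_complete = FALSE)
  expect_equal(sc$score, 0.6 - 0.3)
  # strict mode excludes it
  strict <- quiet_scores(rec, require_complete = TRUE)
  expect_equal(nrow(strict), 0)
  expect_equal(attr(strict, "exclusions")$copepod_id, "a")
})

test_that("the manipulation score is post minus pre with a direction flag", {
  expect_equal(manipulation_score(0.5, 0.5), 0)
  expect_equal(manipulation_score(0.2, 0.6), 0.4)
  expect_equal(manipulation_score(0.2, 0.6, direction = "pre_minus_post"),
               -0.4)
  sc <- quiet_scores(make_records(list(a = c(0.2, 0.2, 0.2, 0.6, 0.6, 0.6))))
  expect_identical(attr(sc, "direction"), "post_minus_pre")
  expect_equal(sc$score, 0.4)
})

test_that("copepods dying before day 15 are excluded and logged", {
  rec <- dplyr::bind_rows(
    make_records(list(alive = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7))),
    make_records(list(dead_d10 = c(0.2, 0.3, 0.4)), days = c(6, 7, 8))
  )
  expect_message(sc <- score_table(rec), "excluded 1")
  expect_equal(sc$copepod_id, "alive")
  excl <- attr(sc, "exclusions")
  expect_equal(excl$copepod_id, "dead_d10")
  expect_match(excl$reason, "post stage")
})

test_that("uninfected copepods are scored identically", {
  rec <- make_records(list(u = c(0.3, 0.3, 0.3, 0.4, 0.4, 0.4)),
                      infected = FALSE)
  sc <- quiet_scores(rec)
  expect_false(sc$infected)
  expect_equal(sc$score, 0.1)
})

test_that("duplicate copepod x day records are an error, empty input is not", {
  rec <- make_records(list(a = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)))
  dup <- dplyr::bind_rows(rec, rec[1, ])
  expect_error(score_table(dup), class = "manipusel_error_records")
  empty <- quiet_scores(rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("scores are linear in a constant post-stage shift", {
  rec <- generate_cohort(cohort_params(n_per_cell = 15, seed = 3))
  sc0 <- quiet_scores(rec)
  shifted <- rec |>
    dplyr::mutate(activity = activity + ifelse(day >= 13, 0.05, 0))
  sc1 <- quiet_scores(shifted)
  expect_equal(sc1$score, sc0$score + 0.05)
})

test_that("scores ignore the order of days within a stage", {
  rec <- generate_cohort(cohort_params(n_per_cell = 10, seed = 5))
  shuffled <- rec |> dplyr::arrange(copepod_id, dplyr::desc(day))
  expect_equal(quiet_scores(shuffled) |> dplyr::arrange(copepod_id),
               quiet_scores(rec) |> dplyr::arrange(copepod_id),
               ignore_attr = TRUE)
})

test_that("an unmanipulated driftless cohort is centred on zero", {
  p <- cohort_params(n_per_cell = 250, effect_suppression = 0,
                     effect_enhancement = 0, drift_per_day = 0,
                     trait_sd = 0, seed = 9)
  sc <- quiet_scores(generate_cohort(p))
  se <- sd(sc$score) / sqrt(nrow(sc))
  expect_lt(abs(mean(sc$score)), 3 * se)
})
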