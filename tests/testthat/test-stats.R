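test_that("a zero between-individual variance is recovered as (near) zero", {
  p <- cohort_params(n_per_cell = 170, var_id = 0, var_replicate = 0,
                     trait_sd = 0, effect_suppression = 0,
                     effect_enhancement = 0, drift_per_day = 0, seed = 3)
  rec <- generate_cohort(p)  # > 2000 observations
  fit <- suppressMessages(
    fit_mixed(rec, activity ~ 1 + (1 | copepod_id))
  )
  v <- fit$var_components
  expect_lte(v$variance[v$group == "copepod_id"], 1e-4)
  expect_true(fit$boundary)
})

test_that("the activity-model variance components are recovered", {
  # study-scale components (id 0.0031, replicate 0.0004, residual 0.0231);
  # replicate variance needs many replicate levels to be estimable
  p <- cohort_params(n_per_cell = 160, var_id = 0.0031,
                     var_replicate = 0.0004, var_resid = 0.0231,
                     trait_sd = 0, drift_per_day = 0, n_replicates = 30,
                     seed = 7)
  rec <- generate_cohort(p) |>
    dplyr::mutate(stage = ifelse(day <= 8, "pre", "post"))
  fit <- fit_mixed(rec,
                   activity ~ stage * infected + (1 | copepod_id) +
                     (1 | replicate))
  v <- setNames(fit$var_components$variance, fit$var_components$group)
  expect_equal(unname(v["copepod_id"]), 0.0031, tolerance = 0.2)
  expect_equal(unname(v["Residual"]), 0.0231, tolerance = 0.2)
  expect_equal(unname(v["replicate"]), 0.0004, tolerance = 0.5)
})

test_that("an intercept-only fit on centred data has a null intercept", {
  rec <- generate_cohort(cohort_params(n_per_cell = 50, seed = 11)) |>
    dplyr::mutate(activity = activity - mean(activity))
  fit <- fit_mixed(rec, activity ~ 1 + (1 | copepod_id))
  expect_lt(abs(fit$fixed_effects[["(Intercept)"]]), 0.01)
})

test_that("rank-deficient fixed designs are refused", {
  rec <- generate_cohort(cohort_params(n_per_cell = 20, seed = 2)) |>
    dplyr::mutate(dup = as.numeric(infected))
  expect_error(
    fit_mixed(rec, activity ~ infected + dup + (1 | copepod_id)),
    class = "manipusel_error_fit"
  )
})

test_that("near-perfect consistency across days drives R to one", {
  d <- tidyr::expand_grid(copepod_id = sprintf("c%02d", 1:50),
                          day = 1:3) |>
    dplyr::mutate(activity = rep(seq(0.2, 0.69, by = 0.01), each = 3) +
                    withr::with_seed(1, stats::rnorm(150, 0, 1e-4)))
  # residual variance near machine zero: lmer warns about gradients
  r <- suppressWarnings(repeatability(d, nboot = 0))
  expect_gt(r$R, 0.99)
  expect_lt(r$p, 1e-6)
})

test_that("repeatability recovers its true value in a 500 x 3 design", {
  for (s in c(13, 29)) {
    p <- cohort_params(n_per_cell = 250, var_id = 0.0049,
                       var_resid = 0.0021, var_replicate = 0, trait_sd = 0,
                       effect_suppression = 0, effect_enhancement = 0,
                       drift_per_day = 0, seed = s)
    rec <- generate_cohort(p) |> dplyr::filter(day <= 8)
    r <- repeatability(rec, nboot = 0)
    expect_lt(abs(r$R - 0.7), 0.05)
  }
})

test_that("the fixed-effect-free ratio matches the activity-model components", {
  # with the study's activity-model components and no other structure the
  # intraclass ratio is 0.0031 / (0.0031 + 0.0231)
  p <- cohort_params(n_per_cell = 600, var_id = 0.0031,
                     var_replicate = 0, var_resid = 0.0231, trait_sd = 0,
                     effect_suppression = 0, effect_enhancement = 0,
                     drift_per_day = 0, seed = 17)
  rec <- generate_cohort(p)  # stage-pooled: all six days per copepod
  r <- repeatability(rec, nboot = 0)
  expect_equal(r$R, 0.0031 / (0.0031 + 0.0231), tolerance = 0.2)
})

test_that("repeatability is invariant to location and positive scale", {
  rec <- generate_cohort(cohort_params(n_per_cell = 60, var_id = 0.005,
                                       var_resid = 0.01, seed = 19)) |>
    dplyr::filter(day <= 8)
  r0 <- repeatability(rec, nboot = 0)$R
  r_shift <- repeatability(dplyr::mutate(rec, activity = activity + 0.17),
                           nboot = 0)$R
  r_scale <- repeatability(dplyr::mutate(rec, activity = activity * 3.2),
                           nboot = 0)$R
  expect_equal(r_shift, r0, tolerance = 1e-6)
  expect_equal(r_scale, r0, tolerance = 1e-6)
})

test_that("the bootstrap SE is seeded, reproducible and plausible", {
  rec <- generate_cohort(cohort_params(n_per_cell = 60, var_id = 0.005,
                                       var_resid = 0.005, seed = 23)) |>
    dplyr::filter(day <= 8)
  r1 <- repeatability(rec, nboot = 60, seed = 5)
  r2 <- repeatability(rec, nboot = 60, seed = 5)
  expect_identical(r1$boot, r2$boot)
  expect_gt(r1$se, 0)
  expect_lt(r1$se, 0.2)
})

test_that("singleton-only groupings are refused", {
  d <- tibble::tibble(copepod_id = sprintf("c%02d", 1:20),
                      activity = runif(20))
  expect_error(repeatability(d), class = "manipusel_error_stats")
})

test_that("likelihood-ratio arithmetic matches the chi-square reference", {
  fake <- function(ll, df, n) {
    structure(list(loglik = ll, df = df, aic = 2 * df - 2 * ll, n_obs = n),
              class = "mixed_vc")
  }
  same <- lrt_compare(fake(-10, 3, 100), fake(-10, 2, 100))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  crit <- lrt_compare(fake(-10 + 3.841 / 2, 3, 100), fake(-10, 2, 100))
  expect_equal(crit$p, 0.05, tolerance = 1e-3)
  expect_equal(crit$df, 1)
})

test_that("delta AIC obeys the chi2 - 2 df identity on real ML fits", {
  rec <- generate_cohort(cohort_params(n_per_cell = 40, seed = 29))
  full <- fit_mixed(rec, activity ~ infected + (1 | copepod_id))
  red <- fit_mixed(rec, activity ~ 1 + (1 | copepod_id))
  cmp <- lrt_compare(full, red)
  expect_gte(cmp$chi2, 0)
  expect_equal(cmp$delta_aic, cmp$chi2 - 2 * cmp$df, tolerance = 1e-8)
})

test_that("non-nested or mismatched comparisons are refused", {
  rec <- generate_cohort(cohort_params(n_per_cell = 40, seed = 29))
  full <- fit_mixed(rec, activity ~ infected + (1 | copepod_id))
  red <- fit_mixed(rec, activity ~ 1 + (1 | copepod_id))
  expect_error(lrt_compare(red, full), class = "manipusel_error_lrt")
  smaller <- fit_mixed(rec[rec$day <= 8, ],
                       activity ~ infected + (1 | copepod_id))
  expect_error(lrt_compare(smaller, red), class = "manipusel_error_lrt")
})

test_that("response summaries honour degenerate and divergent inputs", {
  const <- tibble::tibble(generation = "F1", line = "control",
                          score = rep(0.25, 8))
  s <- selection_response_summary(const, nboot = 100, seed = 1)
  expect_equal(s$lo, s$hi)
  expect_equal(s$mean, 0.25)

  lone <- tibble::tibble(generation = "F1", line = "susceptible",
                         score = 0.4)
  expect_message(s2 <- selection_response_summary(lone, nboot = 50),
                 "degenerate")
  expect_true(s2$degenerate)

  ex <- generate_experiment(cohort_params(n_per_cell = 120, seed = 31),
                            n_generations = 2)
  s3 <- selection_response_summary(ex$scores |>
                                     dplyr::filter(infected, !is.na(line)),
                                   nboot = 200, seed = 2)
  last <- s3 |> dplyr::filter(generation == "F1")
  expect_gt(last$mean[last$line == "susceptible"],
            last$mean[last$line == "resistant"])
})
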