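pool_tbl <- function(scores, replicate = 1L, ids = NULL) {
  tibble::tibble(
    copepod_id = ids %||% sprintf("c%03d", seq_along(scores)),
    replicate = replicate, score = scores
  )
}

test_that("founding assignment carves quarter / thirds as specified", {
  pool <- pool_tbl(seq(0.01, 0.12, by = 0.01))
  out <- assign_lines_f0(pool, seed = 2)
  expect_equal(sum(out$line == "control", na.rm = TRUE), 3)
  expect_equal(sum(out$line == "susceptible", na.rm = TRUE), 3)
  expect_equal(sum(out$line == "resistant", na.rm = TRUE), 3)
  expect_equal(sum(is.na(out$line)), 3)
  rest <- out |> dplyr::filter(is.na(line) | line != "control")
  # susceptible members outrank every non-control non-susceptible member
  expect_gt(min(rest$score[rest$line %in% "susceptible"]),
            max(rest$score[!rest$line %in% "susceptible"]))
  expect_lt(max(rest$score[rest$line %in% "resistant"]),
            min(rest$score[!rest$line %in% "resistant"]))
})

test_that("the smallest valid pool yields one copepod per band", {
  out <- assign_lines_f0(pool_tbl(c(0.1, 0.2, 0.3, 0.4)), seed = 1)
  expect_equal(sum(out$line == "control", na.rm = TRUE), 1)
  expect_equal(sum(out$line == "susceptible", na.rm = TRUE), 1)
  expect_equal(sum(out$line == "resistant", na.rm = TRUE), 1)
  expect_equal(sum(is.na(out$line)), 1)
  expect_error(assign_lines_f0(pool_tbl(c(0.1, 0.2, 0.3)), seed = 1),
               regexp = "Replicate", class = "manipusel_error_selection")
})

test_that("tied scores partition deterministically under a fixed seed", {
  pool <- pool_tbl(rep(0.3, 12))
  a <- assign_lines_f0(pool, seed = 5)
  b <- assign_lines_f0(pool, seed = 5)
  expect_identical(a, b)
  out <- select_generation(a |> dplyr::filter(!is.na(line)), seed = 5)
  expect_true(all(out$by_replicate$differential == 0))
})

test_that("truncation keeps the extremes and the differential is exact", {
  pool <- pool_tbl(seq(0.1, 0.6, by = 0.1))
  res <- select_line(pool, "resistant", cap = 2)
  expect_identical(res$copepod_id[res$selected], c("c001", "c002"))
  expect_equal(attr(res, "differential"), 0.15 - 0.35)
  expect_equal(selection_differential(c(0.1, 0.2), pool$score), -0.2)
  sus <- select_line(pool, "susceptible", cap = 2)
  expect_identical(sus$copepod_id[sus$selected], c("c005", "c006"))
})

test_that("boundary ties break by stable copepod id", {
  scores <- c(rep(0.5, 5), seq(0.6, 1.0, by = 0.05), rep(0.4, 1))
  pool <- pool_tbl(scores)  # 15 members, ties at the cap-10 boundary
  sus <- select_line(pool, "susceptible", cap = 10)
  sel <- sus$copepod_id[sus$selected]
  tied <- pool$copepod_id[pool$score == 0.5]
  # 9 strictly-above-tie members, so exactly one tied member enters: the
  # lexically first
  expect_identical(intersect(sel, tied), min(tied))
  expect_length(sel, 10)
})

test_that("a whole pool at or below the cap is kept and control is seeded", {
  pool <- pool_tbl(c(0.2, 0.4, 0.6))
  out <- select_line(pool, "control", cap = 10, seed = 3)
  expect_true(all(out$selected))
  expect_equal(attr(out, "differential"), 0)
  big <- pool_tbl(runif(30))
  c1 <- select_line(big, "control", cap = 10, seed = 9)
  c2 <- select_line(big, "control", cap = 10, seed = 9)
  expect_identical(c1, c2)
  expect_equal(sum(c1$selected), 10)
})

test_that("differential degenerate cases error cleanly", {
  expect_equal(selection_differential(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 0)
  expect_error(selection_differential(numeric(0), c(0.1)),
               class = "manipusel_error_selection")
  expect_error(select_line(pool_tbl(numeric(0)), "susceptible"),
               class = "manipusel_error_selection")
  expect_error(select_generation(pool_tbl(0.3, ids = "x") |>
                                   dplyr::mutate(line = "bogus")),
               class = "manipusel_error_selection")
})

test_that("regime signs and negation symmetry hold on random pools", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(11:40, 1)
      scores <- round(rnorm(n, 0.3, 0.15), 3)
      if (var(scores) == 0) next
      pool <- pool_tbl(scores)
      d_sus <- attr(select_line(pool, "susceptible"), "differential")
      d_res <- attr(select_line(pool, "resistant"), "differential")
      expect_gt(d_sus, 0)
      expect_lt(d_res, 0)
      neg <- pool_tbl(-scores)
      d_sus_neg <- attr(select_line(neg, "susceptible"), "differential")
      expect_equal(abs(d_res), d_sus_neg, tolerance = 1e-12)
    }
  })
})

test_that("selection matches the brute-force oracle on random small pools", {
  withr::with_seed(123, {
    for (i in 1:40) {
      n <- sample(2:12, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      pool <- pool_tbl(scores)
      for (regime in c("susceptible", "resistant")) {
        got <- select_line(pool, regime, cap = 10)
        want <- brute_select(scores, regime, cap = 10)
        expect_equal(sort(got$score[got$selected]), want$selected_scores)
        expect_equal(attr(got, "differential"), want$differential)
      }
    }
  })
})

test_that("every selection cell stays within one replicate", {
  scores <- generate_cohort(cohort_params(n_per_cell = 60, seed = 8)) |>
    quiet_scores() |>
    dplyr::filter(infected)
  out <- select_generation(scores, cap = 10, seed = 4)
  cells <- out$members |>
    dplyr::filter(selected) |>
    dplyr::distinct(line, replicate)
  expect_equal(nrow(cells), 9)  # 3 lines x 3 replicates, never pooled
})

test_that("founding differentials can be referenced to the whole pool", {
  pool <- pool_tbl(seq(0.05, 0.60, by = 0.05))  # 12 members
  labeled <- assign_lines_f0(pool, seed = 2)
  ref <- pool |> dplyr::select(replicate, score)
  out <- select_generation(labeled |> dplyr::filter(!is.na(line)),
                           cap = 10, seed = 2, reference = ref)
  sus <- out$by_line |> dplyr::filter(line == "susceptible")
  expect_equal(sus$pool_mean, mean(pool$score))
  expect_equal(sus$differential,
               mean(labeled$score[labeled$line %in% "susceptible"]) -
                 mean(pool$score))
})
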