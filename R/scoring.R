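#' Per-copepod stage means of activity
#'
#' Averages each copepod's activity within the pre-infectivity window (days
#' 6-8 post-infection, predation suppression) and the post-infectivity window
#' (days 13-15, predation enhancement).
#'
#' @param records A behaviour-record data frame with at least `copepod_id`,
#'   `day` and `activity` (see [generate_cohort()] for the schema).
#' @param pre_days,post_days Days defining the two stages (defaults 6:8 and
#'   13:15).
#' @return A tibble with one row per copepod: `copepod_id`, `a_pre`,
#'   `a_post`, `n_pre`, `n_post`. Stages with no observed day yield `NA`
#'   means and a zero count.
#' @export
stage_means <- function(records, pre_days = 6:8, post_days = 13:15) {
  records <- as_tibble(records)
  stopifnot(all(c("copepod_id", "day", "activity") %in% names(records)))
  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  records |>
    group_by(.data$copepod_id) |>
    summarise(
      a_pre = mean_or_na(.data$activity[.data$day %in% pre_days]),
      a_post = mean_or_na(.data$activity[.data$day %in% post_days]),
      n_pre = sum(.data$day %in% pre_days),
      n_post = sum(.data$day %in% post_days),
      .groups = "drop"
    )
}

#' Host-manipulation score
#'
#' The per-host manipulation statistic: mean activity after the parasite
#' becomes infective minus mean activity before (`a_post - a_pre`). The sign
#' convention makes infected hosts — suppressed early, enhanced late — score
#' positive. Uninfected hosts are scored identically and serve as the
#' no-manipulation reference.
#'
#' @param a_pre,a_post Stage mean activities (vectorized).
#' @param direction `"post_minus_pre"` (default, the convention above) or
#'   `"pre_minus_post"`.
#' @return Numeric score(s) in `[-1, 1]`.
#' @export
manipulation_score <- function(a_pre, a_post,
                               direction = c("post_minus_pre",
                                             "pre_minus_post")) {
  direction <- match.arg(direction)
  if (direction == "post_minus_pre") a_post - a_pre else a_pre - a_post
}

#' Score a behaviour-record table
#'
#' Computes one manipulation score per copepod, carrying the design labels
#' (replicate, line, generation, infection status) through. Copepods missing
#' the required days in either stage — e.g. animals that died before day 15 —
#' are excluded and logged.
#'
#' @inheritParams stage_means
#' @param require_complete If `TRUE` (default, matching the selection
#'   protocol, which used hosts surviving to day 15 with full schedules) a
#'   copepod needs all pre and post days; if `FALSE`, one day per stage
#'   suffices and stage means use the available days.
#' @param direction Passed to [manipulation_score()].
#' @return A tibble with one row per scored copepod: design labels, `a_pre`,
#'   `a_post`, `n_pre`, `n_post`, `score`. The excluded copepods and their
#'   reasons are attached as the `"exclusions"` attribute (a tibble with
#'   `copepod_id`, `reason`) and reported via a message; the scoring direction
#'   is attached as the `"direction"` attribute.
#' @examples
#' records <- generate_cohort(cohort_params(n_per_cell = 10, seed = 1))
#' scores <- score_table(records)
#' head(scores)
#' @export
score_table <- function(records, pre_days = 6:8, post_days = 13:15,
                        require_complete = TRUE,
                        direction = c("post_minus_pre", "pre_minus_post")) {
  direction <- match.arg(direction)
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    out <- tibble(copepod_id = character(), a_pre = double(),
                  a_post = double(), n_pre = integer(), n_post = integer(),
                  score = double())
    attr(out, "exclusions") <- tibble(copepod_id = character(),
                                      reason = character())
    attr(out, "direction") <- direction
    return(out)
  }
  dup <- records |>
    dplyr::count(.data$copepod_id, .data$day) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("Duplicate copepod x day records (e.g. %s, day %d).",
                  dup$copepod_id[1], dup$day[1]),
          class = "manipusel_error_records")
  }
  sm <- stage_means(records, pre_days, post_days)
  need_pre <- if (require_complete) length(pre_days) else 1L
  need_post <- if (require_complete) length(post_days) else 1L
  sm <- sm |>
    mutate(reason = dplyr::case_when(
      n_pre < need_pre & n_post < need_post ~ "incomplete both stages",
      n_pre < need_pre ~ "incomplete pre stage (days 6-8)",
      n_post < need_post ~ "incomplete post stage (days 13-15, e.g. died)",
      TRUE ~ NA_character_
    ))
  excl <- sm |> filter(!is.na(.data$reason)) |>
    select("copepod_id", "reason")
  if (nrow(excl) > 0L) {
    inform(sprintf("score_table: excluded %d copepod(s) with incomplete schedules.",
                   nrow(excl)))
  }
  labels <- records |>
    select(dplyr::any_of(c("copepod_id", "replicate", "line", "generation",
                           "infected", "exposed", "trait", "id_effect"))) |>
    distinct(.data$copepod_id, .keep_all = TRUE)
  out <- sm |>
    filter(is.na(.data$reason)) |>
    select(-"reason") |>
    left_join(labels, by = "copepod_id") |>
    mutate(score = manipulation_score(.data$a_pre, .data$a_post,
                                      direction = direction)) |>
    select(dplyr::any_of(c("copepod_id", "replicate", "line", "generation",
                           "infected", "exposed")),
           "a_pre", "a_post", "n_pre", "n_post", "score",
           dplyr::any_of(c("trait", "id_effect")))
  attr(out, "exclusions") <- excl
  attr(out, "direction") <- direction
  out
}
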