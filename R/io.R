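# CSV surfaces: RFC 4180, UTF-8, "." decimal via readr.

behavior_cols <- c("copepod_id", "replicate", "line", "generation",
                   "infected", "day", "activity")

#' Write / read behaviour-record CSV
#'
#' Schema: `copepod_id, replicate, line, generation, infected, day,
#' activity`; `line` is `control`, `susceptible`, `resistant` or `stock`;
#' `infected` is 0/1. Ground-truth simulation columns are dropped on write.
#'
#' @param records A behaviour-record tibble (see [generate_cohort()]).
#' @param path File path.
#' @return `write_behavior_csv()` returns `path` invisibly;
#'   `read_behavior_csv()` returns a tibble with `infected` as logical.
#' @export
write_behavior_csv <- function(records, path) {
  records |>
    as_tibble() |>
    mutate(infected = as.integer(.data$infected)) |>
    select(dplyr::all_of(intersect(behavior_cols, names(records)))) |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(infected = as.logical(.data$infected))
}

#' Write / read manipulation-score CSV
#'
#' Schema: design labels plus `a_pre, a_post, n_pre, n_post, score`. The
#' scoring direction is recorded in a `# direction:` comment line.
#'
#' @param scores A score table (see [score_table()]).
#' @param path File path.
#' @export
write_scores_csv <- function(scores, path) {
  direction <- attr(scores, "direction") %||% "post_minus_pre"
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(sprintf("# direction: %s", direction), con)
  close(con)
  scores |>
    as_tibble() |>
    mutate(across(dplyr::any_of("infected"), as.integer)) |>
    select(dplyr::any_of(c("copepod_id", "replicate", "line", "generation",
                           "infected", "a_pre", "a_post", "n_pre", "n_post",
                           "score"))) |>
    readr::write_csv(path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  first <- readLines(path, n = 1L)
  direction <- if (grepl("^# direction:", first)) {
    trimws(sub("^# direction:", "", first))
  } else {
    "post_minus_pre"
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if ("infected" %in% names(out)) out$infected <- as.logical(out$infected)
  attr(out, "direction") <- direction
  out
}

#' Write a track result as CSV
#'
#' One row per frame (`copepod_id, frame, t_s, x, y, moved`) plus a summary
#' row (`frame = NA`) carrying `activity` and `n_intervals`.
#'
#' @param result A `track_result` (see [track_sequence()]), or a named list
#'   of them.
#' @param path File path.
#' @param copepod_id Identifier when a single result is given.
#' @export
write_track_csv <- function(result, path, copepod_id = "c01") {
  results <- if (inherits(result, "track_result")) {
    setNames(list(result), copepod_id)
  } else {
    result
  }
  rows <- imap(results, function(res, id) {
    per_frame <- res$positions |>
      mutate(copepod_id = id, moved = c(res$moved, NA),
             activity = NA_real_, n_intervals = NA_integer_)
    summary_row <- tibble(copepod_id = id, frame = NA_integer_,
                          t_s = NA_real_, x = NA_real_, y = NA_real_,
                          detected = NA, moved = NA,
                          activity = res$activity,
                          n_intervals = res$n_intervals)
    bind_rows(per_frame, summary_row)
  }) |> list_rbind()
  readr::write_csv(rows |> select("copepod_id", dplyr::everything()), path)
  invisible(path)
}
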