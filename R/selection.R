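#' Assign founding copepods to selection lines
#'
#' Implements the founding-generation line assignment: within each replicate,
#' one quarter of the pool (rounded down) is drawn at random as the control
#' line; the remaining `r` copepods are ranked by manipulation score and the
#' top `floor(r / 3)` become the susceptible line, the bottom `floor(r / 3)`
#' the resistant line, with the remainder joining the discarded middle band.
#' Ties at rank boundaries are broken by copepod id (stable), under the given
#' seed for the control draw.
#'
#' @param scores A score table (see [score_table()]) restricted to the
#'   selection pool — infected hosts that survived to day 15 — with columns
#'   `copepod_id`, `replicate`, `score`.
#' @param seed Integer seed for the random control draw.
#' @return The input tibble with a `line` column: `"control"`,
#'   `"susceptible"`, `"resistant"`, or `NA` for the discarded middle band.
#' @export
assign_lines_f0 <- function(scores, seed = 1L) {
  scores <- as_tibble(scores)
  stopifnot(all(c("copepod_id", "replicate", "score") %in% names(scores)))
  split(scores, scores$replicate) |>
    imap(function(pool, repl) {
      n <- nrow(pool)
      if (n < 4L) {
        abort(sprintf("Replicate %s pool has %d members; at least 4 are needed to form three lines.",
                      repl, n),
              class = "manipusel_error_selection")
      }
      n_ctrl <- floor(n / 4)
      ctrl_ids <- withr::with_seed(
        substream_seed(seed, 5L, as.integer(factor(repl, sort(unique(scores$replicate))))),
        sample(sort(pool$copepod_id), n_ctrl)
      )
      rest <- pool |>
        filter(!.data$copepod_id %in% ctrl_ids) |>
        arrange(dplyr::desc(.data$score), .data$copepod_id)
      r <- nrow(rest)
      third <- floor(r / 3)
      line <- rep(NA_character_, r)
      if (third > 0L) {
        line[seq_len(third)] <- "susceptible"
        line[seq(r - third + 1L, r)] <- "resistant"
      }
      rest$line <- line
      ctrl <- pool |>
        filter(.data$copepod_id %in% ctrl_ids) |>
        mutate(line = "control")
      bind_rows(ctrl, rest)
    }) |>
    list_rbind() |>
    arrange(.data$replicate, .data$copepod_id)
}

#' Truncation-select breeders from one line x replicate pool
#'
#' Applies the per-generation selection rule: if more than `cap` copepods are
#' available in a line x replicate pool, keep the `cap` most extreme — highest
#' manipulation scores for the susceptible regime, lowest for the resistant —
#' or `cap` drawn uniformly at random for the control regime. Pools of at most
#' `cap` members are kept whole. Ties at the truncation boundary are broken by
#' copepod id (stable).
#'
#' @param pool A tibble with columns `copepod_id` and `score` (one line x
#'   replicate selection pool: infected day-15 survivors).
#' @param regime `"susceptible"`, `"resistant"` or `"control"`.
#' @param cap Maximum number of breeders (default 10); `Inf` disables the
#'   cap, keeping the whole pool.
#' @param seed Integer seed (used by the control draw only).
#' @return The pool tibble with a logical `selected` column, ordered by
#'   copepod id, carrying attributes `differential`, `pool_mean`,
#'   `selected_mean` and `regime`. Class `selection_pool`.
#' @seealso [selection_differential()], [select_generation()]
#' @export
select_line <- function(pool, regime = c("susceptible", "resistant",
                                         "control"),
                        cap = 10, seed = 1L) {
  regime <- match.arg(regime)
  pool <- as_tibble(pool)
  stopifnot(all(c("copepod_id", "score") %in% names(pool)))
  if (nrow(pool) == 0L) {
    abort("Selection pool is empty.", class = "manipusel_error_selection")
  }
  k <- min(cap, nrow(pool))
  ranked <- switch(
    regime,
    susceptible = pool |> arrange(dplyr::desc(.data$score), .data$copepod_id),
    resistant = pool |> arrange(.data$score, .data$copepod_id),
    control = withr::with_seed(
      substream_seed(seed, 6L),
      pool |> slice(sample(dplyr::n()))
    )
  )
  sel_ids <- ranked$copepod_id[seq_len(k)]
  out <- pool |>
    mutate(selected = .data$copepod_id %in% sel_ids) |>
    arrange(.data$copepod_id)
  attr(out, "regime") <- regime
  attr(out, "pool_mean") <- mean(pool$score)
  attr(out, "selected_mean") <- mean(out$score[out$selected])
  attr(out, "differential") <- selection_differential(
    out$score[out$selected], pool$score
  )
  class(out) <- c("selection_pool", class(out))
  out
}

#' Selection differential
#'
#' Mean manipulation score of the selected breeders minus the mean of the
#' entire pool they were drawn from: the realized strength of selection.
#'
#' @param selected Scores of the selected individuals (must be a subset of the
#'   pool).
#' @param pool Scores of the full pool.
#' @return A single number, `mean(selected) - mean(pool)`.
#' @export
selection_differential <- function(selected, pool) {
  if (length(selected) == 0L) {
    abort("No selected individuals; the selection differential is undefined.",
          class = "manipusel_error_selection")
  }
  if (length(pool) == 0L || length(selected) > length(pool)) {
    abort("`selected` must be a nonempty subset of `pool`.",
          class = "manipusel_error_selection")
  }
  mean(selected) - mean(pool)
}

#' Select breeders for every line x replicate of a generation
#'
#' Splits a scored selection pool by line and replicate (replicates are never
#' mixed), truncation-selects each cell with [select_line()], and summarises
#' selection differentials per cell and pooled across replicates (all members
#' of a line pooled, the default aggregation; per-replicate values are also
#' reported).
#'
#' @param scores A score table restricted to the selection pool (infected
#'   day-15 survivors) with columns `copepod_id`, `replicate`, `line`,
#'   `score`; lines must be `control`, `susceptible` or `resistant`.
#' @param cap Maximum breeders per line x replicate (default 10).
#' @param seed Integer seed for the control-line draws.
#' @param reference Optional reference population for the differentials: a
#'   tibble with `replicate` and `score` covering the entire selection pool
#'   of each replicate. In the founding generation the three lines are carved
#'   out of one common pool, and the realized strength of selection is
#'   measured against that whole pool (selected mean minus whole-pool mean);
#'   from the next generation on each line's pool *is* its whole population
#'   and `reference` can stay `NULL`.
#' @return A list of class `selection_outcome`: `members` (one row per pool
#'   member with `selected` flag), `by_replicate` (per line x replicate
#'   differentials) and `by_line` (pooled-across-replicates differentials).
#' @export
select_generation <- function(scores, cap = 10, seed = 1L,
                              reference = NULL) {
  scores <- as_tibble(scores)
  stopifnot(all(c("copepod_id", "replicate", "line", "score") %in%
                  names(scores)))
  scores <- scores |> filter(!is.na(.data$line))
  bad <- setdiff(unique(scores$line),
                 c("control", "susceptible", "resistant"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown selection regime '%s'.", bad[1]),
          class = "manipusel_error_selection")
  }
  cells <- scores |> distinct(.data$line, .data$replicate)
  members <- purrr::pmap(cells, function(line, replicate) {
    pool <- scores[scores$line == line & scores$replicate == replicate, ]
    out <- select_line(pool, regime = line, cap = cap,
                       seed = substream_seed(seed, 7L, replicate,
                                             match(line, c("control",
                                                           "susceptible",
                                                           "resistant"))))
    as_tibble(out)
  }) |> list_rbind()
  ref_scores <- function(repls) {
    if (is.null(reference)) return(NULL)
    reference$score[reference$replicate %in% repls]
  }
  summarise_cells <- function(grouped) {
    grouped |>
      summarise(
        n_pool = if (is.null(reference)) dplyr::n() else
          length(ref_scores(unique(.data$replicate))),
        n_selected = sum(.data$selected),
        pool_mean = if (is.null(reference)) mean(.data$score) else
          mean(ref_scores(unique(.data$replicate))),
        selected_mean = mean(.data$score[.data$selected]),
        differential = selected_mean - pool_mean,
        .groups = "drop"
      )
  }
  by_replicate <- summarise_cells(
    members |> group_by(.data$line, .data$replicate)
  )
  by_line <- summarise_cells(members |> group_by(.data$line))
  structure(list(members = members, by_replicate = by_replicate,
                 by_line = by_line),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat("<selection_outcome> pooled differentials:\n")
  print(x$by_line)
  invisible(x)
}

#' @export
tidy.selection_outcome <- function(x, by = c("line", "replicate"), ...) {
  by <- match.arg(by)
  if (by == "line") x$by_line else x$by_replicate
}
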