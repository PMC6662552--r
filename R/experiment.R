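#' Simulate a multi-generation selection experiment
#'
#' Runs the full breeding loop on synthetic cohorts: a founding generation
#' (F0) is generated without line labels, scored, and partitioned into
#' control / susceptible / resistant lines with [assign_lines_f0()]; every
#' generation's infected day-15 survivors are truncation-selected per line x
#' replicate with [select_generation()] (cap 10), and the selected breeders'
#' latent traits seed the next generation through the parent-offspring
#' regression `offspring = pop_mean + h2 * (mid-parent - pop_mean) +
#' segregation noise`. Replicates never mix. Uninfected founding copepods are
#' randomly assigned to lines so every generation carries uninfected
#' controls.
#'
#' @param params A [cohort_params()] object; `h2`, `trait_sd` and
#'   `segregation_sd` govern the selection response.
#' @param n_generations Number of generations to simulate (>= 1; generation
#'   labels `F0`, `F1`, ...).
#' @param cap Maximum breeders per line x replicate (default 10).
#' @return A list of class `selection_experiment`:
#'   * `records` — all behaviour records, every generation;
#'   * `scores` — all manipulation-score rows;
#'   * `outcomes` — per-generation pooled selection differentials
#'     (`generation`, `line`, `n_pool`, `n_selected`, `pool_mean`,
#'     `selected_mean`, `differential`);
#'   * `outcomes_by_replicate` — the same per replicate;
#'   * `parents` — parent links: for each generation > F0, the selected
#'     breeder ids of each line x replicate that produced it.
#' @examples
#' \donttest{
#' ex <- generate_experiment(cohort_params(n_per_cell = 60, seed = 3),
#'                           n_generations = 2)
#' ex$outcomes
#' }
#' @export
generate_experiment <- function(params, n_generations = 1L, cap = 10) {
  stopifnot(inherits(params, "cohort_params"))
  n_generations <- assert_count(n_generations, "n_generations", min = 1L)

  all_records <- list()
  all_scores <- list()
  all_out_line <- list()
  all_out_rep <- list()
  parents <- list()
  parent_traits <- NULL
  pop_mean <- 0

  for (g in seq_len(n_generations) - 1L) {
    gen <- paste0("F", g)
    if (g == 0L) {
      rec <- generate_cohort(params, generation = gen, lines = NULL)
      sc <- suppressMessages(score_table(rec))
      pool <- sc |> filter(.data$infected)
      assigned <- assign_lines_f0(pool, seed = substream_seed(params$seed, 8L))
      line_map <- assigned |> select("copepod_id", "line")
      # uninfected founders: random line labels, as in a founding design where
      # every line needs uninfected controls
      uninf <- sc |> filter(!.data$infected) |> pull("copepod_id")
      uninf_lines <- withr::with_seed(
        substream_seed(params$seed, 9L),
        sample(c("control", "susceptible", "resistant"), length(uninf),
               replace = TRUE)
      )
      line_map <- bind_rows(line_map,
                            tibble(copepod_id = uninf, line = uninf_lines))
      rec <- rec |> select(-"line") |> left_join(line_map, by = "copepod_id")
      sc <- sc |> select(-"line") |> left_join(line_map, by = "copepod_id")
    } else {
      rec <- generate_cohort(params, generation = gen,
                             parent_traits = parent_traits,
                             pop_mean = pop_mean)
      sc <- suppressMessages(score_table(rec))
    }
    sel_pool <- sc |> filter(.data$infected, !is.na(.data$line))
    check_pools(sel_pool, gen)
    # in the founding generation the lines are carved out of one common pool
    # per replicate; differentials are measured against that whole pool
    reference <- if (g == 0L) {
      sc |> filter(.data$infected) |> select("replicate", "score")
    } else {
      NULL
    }
    outcome <- select_generation(sel_pool, cap = cap,
                                 seed = substream_seed(params$seed, 10L, g),
                                 reference = reference)
    all_records[[gen]] <- rec
    all_scores[[gen]] <- sc |> mutate(generation = gen)
    all_out_line[[gen]] <- outcome$by_line |> mutate(generation = gen)
    all_out_rep[[gen]] <- outcome$by_replicate |> mutate(generation = gen)

    sel_members <- outcome$members |> filter(.data$selected)
    parents[[gen]] <- sel_members |>
      select("line", "replicate", parent_id = "copepod_id") |>
      mutate(offspring_generation = paste0("F", g + 1L))
    parent_traits <- sel_members |> select("line", "replicate", "trait")
    # reference mean for the breeder's-equation regression: the population
    # the parents were selected from. At F0 the lines are carved out of one
    # common replicate pool; afterwards each line x replicate is a closed
    # population whose mean already carries the transmitted gains.
    indiv <- rec |> distinct(.data$copepod_id, .keep_all = TRUE)
    pop_mean <- if (g == 0L) {
      base <- indiv |>
        group_by(.data$replicate) |>
        summarise(pop_mean = mean(.data$trait), .groups = "drop")
      tidyr::expand_grid(line = c("control", "susceptible", "resistant"),
                         base)
    } else {
      indiv |>
        filter(!is.na(.data$line)) |>
        group_by(.data$line, .data$replicate) |>
        summarise(pop_mean = mean(.data$trait), .groups = "drop")
    }
  }

  structure(
    list(
      records = list_rbind(all_records),
      scores = list_rbind(all_scores),
      outcomes = list_rbind(all_out_line) |>
        select("generation", dplyr::everything()),
      outcomes_by_replicate = list_rbind(all_out_rep) |>
        select("generation", dplyr::everything()),
      parents = list_rbind(parents),
      params = params
    ),
    class = "selection_experiment"
  )
}

check_pools <- function(sel_pool, gen) {
  cells <- tidyr::expand_grid(
    line = c("control", "susceptible", "resistant"),
    replicate = sort(unique(sel_pool$replicate))
  )
  have <- sel_pool |> distinct(.data$line, .data$replicate)
  missing <- dplyr::anti_join(cells, have, by = c("line", "replicate"))
  if (nrow(sel_pool) > 0L && nrow(missing) > 0L) {
    abort(sprintf("Empty selection pool in %s for line '%s', replicate %s.",
                  gen, missing$line[1], missing$replicate[1]),
          class = "manipusel_error_selection")
  }
}

#' @export
print.selection_experiment <- function(x, ...) {
  cat("<selection_experiment> ", length(unique(x$records$generation)),
      " generation(s), ", nrow(x$records), " behaviour records\n", sep = "")
  print(x$outcomes)
  invisible(x)
}
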