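# Quarantined adapter for the published study deposit. The deposit's internal
# column layout is not bundled with this package, so the mapping lives here,
# in one file, and everything downstream consumes the standard schemas.

#' Load a locally downloaded study deposit
#'
#' Validation adapter for the deposited behaviour data of the original
#' selection experiment (Dryad, \doi{10.5061/dryad.cb2f70h}). The deposit is
#' not redistributed with this package and must be downloaded by the user;
#' this function maps its tables onto the package's behaviour-record and
#' manipulation-score schemas so every downstream stage (scoring, selection
#' differentials per generation, mixed models) runs unchanged.
#'
#' @param path Path to the downloaded deposit: a CSV file, or a directory
#'   containing one.
#' @param mapping Named character vector mapping the package's column names
#'   (`copepod_id`, `replicate`, `line`, `generation`, `infected`, `day`,
#'   `activity`) to the deposit's column names. Columns whose names already
#'   match are picked up automatically; any unmapped required column raises
#'   an explicit mapping-needed error rather than being guessed.
#' @return A list with `records` (behaviour records) and `scores`
#'   (manipulation scores computed with [score_table()]); either may be
#'   `NULL` for a partial deposit (e.g. a deposit of per-copepod scores
#'   only, in which case the upstream stages are skipped with a log line).
#' @export
load_dryad_adapter <- function(path, mapping = character()) {
  if (!file.exists(path)) {
    abort(paste0(
      "Study deposit not found at '", path, "'.\n",
      "Download it from Dryad (https://doi.org/10.5061/dryad.cb2f70h) and ",
      "pass the local path; the deposit is not redistributed with this package."
    ), class = "manipusel_error_dryad")
  }
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(csv|txt|tsv)$", full.names = TRUE,
               ignore.case = TRUE)
  } else {
    path
  }
  if (length(files) == 0L) {
    abort("No tabular files (.csv/.tsv/.txt) found in the deposit directory.",
          class = "manipusel_error_dryad")
  }
  raw <- readr::read_csv(files[[1]], show_col_types = FALSE)
  required <- c("copepod_id", "replicate", "line", "generation", "infected",
                "day", "activity")
  nm <- names(raw)
  resolved <- setNames(rep(NA_character_, length(required)), required)
  for (col in required) {
    if (col %in% names(mapping) && mapping[[col]] %in% nm) {
      resolved[[col]] <- mapping[[col]]
    } else if (col %in% nm) {
      resolved[[col]] <- col
    }
  }
  score_like <- c("score", "a_pre", "a_post")
  if (anyNA(resolved)) {
    if (all(score_like %in% nm) ||
        ("score" %in% nm && !"day" %in% nm)) {
      inform("[dryad] deposit holds per-copepod scores only; tracking and scoring stages skipped.")
      scores <- raw
      if ("infected" %in% names(scores)) {
        scores$infected <- as.logical(scores$infected)
      }
      return(list(records = NULL, scores = as_tibble(scores)))
    }
    abort(paste0(
      "Unknown deposit schema: no mapping for column(s) ",
      paste(names(resolved)[is.na(resolved)], collapse = ", "),
      ". Supply `mapping = c(<package column> = <deposit column>, ...)`; ",
      "columns are never guessed."
    ), class = "manipusel_error_dryad")
  }
  records <- raw |>
    rename(!!!setNames(resolved, names(resolved))) |>
    mutate(infected = as.logical(.data$infected))
  scores <- suppressMessages(score_table(records))
  list(records = as_tibble(records), scores = scores)
}

#' Selection differentials of a mapped deposit, per generation
#'
#' Convenience wrapper for validation against the study's printed values:
#' truncation-selects every line x replicate of every generation of a mapped
#' deposit and returns the pooled differentials.
#'
#' @param adapter The result of [load_dryad_adapter()].
#' @param cap Breeder cap (default 10).
#' @param seed Seed for control-line draws.
#' @param founding_generation Generation whose lines were carved out of one
#'   common pool per replicate (default `"F0"`); its differentials are
#'   referenced to that whole pool rather than to each line's own members.
#'   `NULL` disables the special case.
#' @return A tibble: `generation`, `line`, `differential` (pooled across
#'   replicates) plus pool sizes.
#' @export
dryad_selection_differentials <- function(adapter, cap = 10, seed = 1L,
                                          founding_generation = "F0") {
  scores <- adapter$scores
  if (is.null(scores)) {
    abort("Adapter holds no scores.", class = "manipusel_error_dryad")
  }
  pool <- scores |>
    filter(.data$infected, !is.na(.data$line),
           .data$line %in% c("control", "susceptible", "resistant"))
  all_infected <- scores |> filter(.data$infected)
  split(pool, pool$generation) |>
    imap(function(p, gen) {
      reference <- if (!is.null(founding_generation) &&
                         identical(gen, founding_generation)) {
        all_infected |>
          filter(.data$generation == gen) |>
          select("replicate", "score")
      } else {
        NULL
      }
      select_generation(p, cap = cap, seed = seed,
                        reference = reference)$by_line |>
        mutate(generation = gen)
    }) |>
    list_rbind() |>
    select("generation", "line", "n_pool", "n_selected", "differential")
}
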