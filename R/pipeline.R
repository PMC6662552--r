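#' Build a pipeline configuration
#'
#' Collects the knobs of every stage (defaults shown) into one validated
#' list. `read_pipeline_config()` builds the same object from a YAML file
#' whose blocks mirror the argument names; absent keys fall back to these
#' defaults (with a log line for the movement threshold, the
#' protocol-critical one).
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed; every stage derives its streams from it.
#' @param cohort A [cohort_params()] object (or list of its arguments) for
#'   the synthetic cohort stage.
#' @param n_generations Generations to simulate (default 1).
#' @param tracking List: `threshold_px` (5), `interval_s` (2), `window_s`
#'   (90), `offset_s` (10), `polarity` ("dark"), `n_sequences` (2; simulated
#'   demo sequences rendered and tracked, 0 to skip).
#' @param scoring List: `direction` ("post_minus_pre"), `require_complete`
#'   (TRUE).
#' @param selection List: `cap` (10).
#' @param stats List: `nboot_repeatability` (200), `nboot_ci` (2000).
#' @param paths List of direct stage inputs that short-circuit the upstream
#'   stages: `behavior_csv` (skip simulation), `frames_dir` (track real
#'   frames instead of rendering synthetic ones).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("manipusel_run_"),
                            seed = 1L,
                            cohort = cohort_params(n_per_cell = 40,
                                                   seed = seed),
                            n_generations = 1L,
                            tracking = list(),
                            scoring = list(),
                            selection = list(),
                            stats = list(),
                            paths = list()) {
  if (!inherits(cohort, "cohort_params")) {
    cohort$seed <- cohort$seed %||% seed
    cohort <- do.call(cohort_params, cohort)
  }
  defaults <- function(given, def, stage) {
    for (k in names(def)) {
      if (is.null(given[[k]])) {
        if (stage == "tracking" && k == "threshold_px") {
          inform("pipeline_config: tracking.threshold_px absent, defaulting to 5 px.")
        }
        given[[k]] <- def[[k]]
      }
    }
    given
  }
  tracking <- defaults(tracking,
                       list(threshold_px = 5, interval_s = 2, window_s = 90,
                            offset_s = 10, polarity = "dark",
                            n_sequences = 2L),
                       "tracking")
  scoring <- defaults(scoring,
                      list(direction = "post_minus_pre",
                           require_complete = TRUE), "scoring")
  selection <- defaults(selection, list(cap = 10), "selection")
  stats <- defaults(stats, list(nboot_repeatability = 200L,
                                nboot_ci = 2000L), "stats")
  structure(
    list(out_dir = out_dir, seed = assert_count(seed, "seed", min = 0L),
         cohort = cohort,
         n_generations = assert_count(n_generations, "n_generations"),
         tracking = tracking, scoring = scoring, selection = selection,
         stats = stats, paths = paths),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "manipusel_error_io")
  }
  y <- yaml::read_yaml(path)
  pipeline_config(
    out_dir = y$out_dir %||% tempfile("manipusel_run_"),
    seed = y$seed %||% 1L,
    cohort = y$cohort %||% list(),
    n_generations = y$n_generations %||% 1L,
    tracking = y$tracking %||% list(),
    scoring = y$scoring %||% list(),
    selection = y$selection %||% list(),
    stats = y$stats %||% list(),
    paths = y$paths %||% list()
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulation (or ingestion), tracking, scoring, selection and
#' statistics, writing each stage's artifact under `config$out_dir`:
#' `behavior.csv`, a frames directory plus `track.csv` (when tracking runs),
#' `scores.csv`, `outcome.csv`, `stats.json` and `manifest.json`. Stages are
#' skipped when their input is supplied directly through `config$paths`.
#' Reruns with the same config and seed produce byte-identical CSVs. Any
#' stage error aborts with the stage name attached.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_manifest`: `artifacts` (tibble with
#'   `artifact`, `path`, `rows`), `seed`, `exclusions`, and the computed
#'   `outcomes`, `repeatability` and `response` objects.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_params(n_per_cell = 24, seed = 1))
#' man <- run_pipeline(cfg)
#' man$artifacts
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  add <- function(name, path, rows) {
    artifacts[[name]] <<- tibble(artifact = name, path = path,
                                 rows = as.integer(rows))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "manipusel_error_pipeline", stage = name, parent = e)
    })
  }

  # -- simulate / ingest ------------------------------------------------
  records <- stage("simulate", {
    if (!is.null(config$paths$behavior_csv)) {
      inform(sprintf("[simulate] skipped; reading %s",
                     config$paths$behavior_csv))
      read_behavior_csv(config$paths$behavior_csv)
    } else {
      ex <- generate_experiment(config$cohort,
                                n_generations = config$n_generations,
                                cap = config$selection$cap)
      ex$records
    }
  })
  behavior_path <- file.path(config$out_dir, "behavior.csv")
  write_behavior_csv(records, behavior_path)
  add("behavior", behavior_path, nrow(records))
  inform(sprintf("[simulate] seed %d: %d records on %d copepods",
                 config$seed, nrow(records),
                 dplyr::n_distinct(records$copepod_id)))

  # -- tracking (demo sequences or supplied frames) ---------------------
  tk <- config$tracking
  track_results <- stage("track", {
    if (!is.null(config$paths$frames_dir)) {
      frames <- read_frames_png(config$paths$frames_dir,
                                interval_s = tk$interval_s,
                                offset_s = tk$offset_s)
      list(seq01 = track_sequence(frames, polarity = tk$polarity,
                                  threshold_px = tk$threshold_px,
                                  interval_s = tk$interval_s,
                                  window_s = tk$window_s,
                                  offset_s = tk$offset_s))
    } else if (tk$n_sequences > 0L) {
      frames_dir <- file.path(config$out_dir, "frames")
      res <- list()
      for (i in seq_len(tk$n_sequences)) {
        tr <- generate_trajectory(trajectory_params(
          threshold_px = tk$threshold_px, frame_interval = tk$interval_s,
          seed = substream_seed(config$seed, 13L, i)
        ))
        fr <- render_frames(tr, seed = substream_seed(config$seed, 14L, i))
        write_frames_png(fr, frames_dir, plate_id = sprintf("p%02d", i))
        res[[sprintf("p%02d", i)]] <-
          track_sequence(fr, polarity = tk$polarity,
                         threshold_px = tk$threshold_px,
                         interval_s = tk$interval_s,
                         window_s = tk$window_s, offset_s = tk$offset_s)
      }
      add("frames", frames_dir,
          tk$n_sequences * length(res[[1]]$positions$frame))
      res
    } else {
      NULL
    }
  })
  if (!is.null(track_results)) {
    track_path <- file.path(config$out_dir, "track.csv")
    write_track_csv(track_results, track_path)
    add("track", track_path,
        sum(map_dbl(track_results, ~ nrow(.x$positions) + 1)))
    inform(sprintf("[track] %d sequence(s), threshold %g px",
                   length(track_results), tk$threshold_px))
  }

  # -- scoring ----------------------------------------------------------
  scores <- stage("score", {
    suppressMessages(score_table(
      records,
      require_complete = config$scoring$require_complete,
      direction = config$scoring$direction
    ))
  })
  excl <- attr(scores, "exclusions")
  scores_path <- file.path(config$out_dir, "scores.csv")
  write_scores_csv(scores, scores_path)
  add("scores", scores_path, nrow(scores))
  inform(sprintf("[score] %d copepods scored, %d excluded (incomplete schedule)",
                 nrow(scores), nrow(excl)))

  # -- selection --------------------------------------------------------
  outcome_rows <- stage("select", {
    pool <- scores |>
      filter(.data$infected, !is.na(.data$line),
             .data$line %in% c("control", "susceptible", "resistant"))
    split(pool, pool$generation) |>
      imap(function(p, gen) {
        # founding generations (recognisable by discarded middle-band members
        # with no line label) are measured against the whole replicate pool
        full_gen <- scores |> filter(.data$infected,
                                     .data$generation == gen)
        reference <- if (any(is.na(full_gen$line))) {
          full_gen |> select("replicate", "score")
        } else {
          NULL
        }
        out <- select_generation(p, cap = config$selection$cap,
                                 seed = substream_seed(config$seed, 10L,
                                                       generation_index(gen)),
                                 reference = reference)
        out$members |>
          left_join(out$by_replicate |>
                      select("line", "replicate", "pool_mean",
                             "selected_mean", "differential"),
                    by = c("line", "replicate")) |>
          mutate(generation = gen, selected = as.integer(.data$selected)) |>
          select("generation", "replicate", "line", "copepod_id",
                 "selected", "pool_mean", "selected_mean", "differential")
      }) |>
      list_rbind()
  })
  outcome_path <- file.path(config$out_dir, "outcome.csv")
  readr::write_csv(outcome_rows, outcome_path)
  add("outcome", outcome_path, nrow(outcome_rows))
  inform(sprintf("[select] %d pool members, cap %d",
                 nrow(outcome_rows), config$selection$cap))

  # -- statistics -------------------------------------------------------
  stats_out <- stage("stats", {
    rep_pre <- repeatability(records |> filter(.data$day <= 8),
                             nboot = config$stats$nboot_repeatability,
                             seed = substream_seed(config$seed, 15L))
    rep_post <- repeatability(records |> filter(.data$day >= 13),
                              nboot = config$stats$nboot_repeatability,
                              seed = substream_seed(config$seed, 16L))
    resp <- suppressMessages(selection_response_summary(
      scores |> filter(.data$infected),
      nboot = config$stats$nboot_ci,
      seed = substream_seed(config$seed, 17L)
    ))
    list(rep_pre = rep_pre, rep_post = rep_post, response = resp)
  })
  stats_path <- file.path(config$out_dir, "stats.json")
  jsonlite::write_json(
    list(
      seed = config$seed,
      repeatability = list(
        pre = list(R = stats_out$rep_pre$R, se = stats_out$rep_pre$se,
                   p = stats_out$rep_pre$p),
        post = list(R = stats_out$rep_post$R, se = stats_out$rep_post$se,
                    p = stats_out$rep_post$p)
      ),
      differentials = outcome_rows |>
        distinct(.data$generation, .data$replicate, .data$line,
                 .keep_all = TRUE) |>
        select("generation", "replicate", "line", "differential"),
      response = as.data.frame(stats_out$response)
    ),
    stats_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  add("stats", stats_path, 1L)

  manifest <- structure(
    list(artifacts = list_rbind(artifacts), seed = config$seed,
         exclusions = excl,
         outcomes = outcome_rows,
         repeatability = list(pre = stats_out$rep_pre,
                              post = stats_out$rep_post),
         response = stats_out$response),
    class = "pipeline_manifest"
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = config$seed,
         package_version = as.character(utils::packageVersion("manipusel")),
         artifacts = as.data.frame(manifest$artifacts),
         n_exclusions = nrow(excl)),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest> seed ", x$seed, "\n", sep = "")
  print(x$artifacts)
  invisible(x)
}
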