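#' Generate one generation of synthetic behaviour records
#'
#' Simulates a cohort of copepods observed on days 6, 7, 8 (pre-infectivity)
#' and 13, 14, 15 (post-infectivity) under the variance structure of
#' [cohort_params()]. Each line x infection-status cell holds `n_per_cell`
#' copepods spread as evenly as possible over the replicates. Per-record
#' activity is
#' `clamp01(baseline + replicate + individual intercept + stage x infection
#' effect + drift_per_day * day + residual)`, where infected hosts express
#' their latent manipulation trait `m` as `-m/2` during suppression and
#' `+m/2` during enhancement. Uninfected hosts receive no stage or trait
#' terms. All draws use counter-derived substreams of the master seed, one per
#' copepod, so subsetting never shifts other copepods' values.
#'
#' @param params A [cohort_params()] object.
#' @param generation Generation label, e.g. `"F0"`.
#' @param lines Character vector of line labels (default control /
#'   susceptible / resistant). Use `NULL` for a pre-assignment founding cohort
#'   (line is `NA`; the population size stays at 3 cells per status so
#'   founding and selected generations are comparable).
#' @param parent_traits Optional tibble with columns `line`, `replicate`,
#'   `trait`: the latent traits of the selected parents of this generation.
#'   When supplied, each offspring's trait is
#'   `pop_mean + h2 * (mid-parent - pop_mean) + segregation noise`, with
#'   mid-parent the mean trait of two parents sampled from the matching
#'   line x replicate pool.
#' @param pop_mean Mean trait of the population the parents were selected
#'   from: a single number, or a tibble with columns `line`, `replicate`,
#'   `pop_mean` (one row per cell). Only the deviation of the selected
#'   mid-parents from this mean is transmitted (at slope `h2`), so gains
#'   already fixed in a line's population mean are kept while the current
#'   round of selection regresses as the breeder's equation prescribes.
#'   Default 0 (a founding base population).
#' @return A tibble of behaviour records: `copepod_id`, `replicate`, `line`,
#'   `generation`, `infected`, `exposed`, `day`, `activity`, plus the
#'   ground-truth columns `id_effect` and `trait` (dropped by
#'   [write_behavior_csv()]).
#' @examples
#' records <- generate_cohort(cohort_params(n_per_cell = 20, seed = 1))
#' dplyr::count(records, line, infected)
#' @export
generate_cohort <- function(params, generation = "F0",
                            lines = c("control", "susceptible", "resistant"),
                            parent_traits = NULL, pop_mean = 0) {
  stopifnot(inherits(params, "cohort_params"))
  founding <- is.null(lines)
  if (founding) lines <- rep(NA_character_, 3L)
  gen_idx <- generation_index(generation)
  days <- c(6L, 7L, 8L, 13L, 14L, 15L)

  repl_eff <- withr::with_seed(
    substream_seed(params$seed, 4L, gen_idx),
    rnorm(params$n_replicates, 0, sqrt(params$var_replicate))
  )

  cells <- tidyr::expand_grid(
    cell_line = lines, infected = c(TRUE, FALSE)
  )
  cells$cell <- seq_len(nrow(cells))

  nd <- length(days)
  out <- purrr::pmap(cells, function(cell_line, infected, cell) {
    n <- params$n_per_cell
    k <- seq_len(n)
    replicate <- ((k - 1L) %% params$n_replicates) + 1L
    line_tag <- if (is.na(cell_line)) paste0("pool", cell) else cell_line
    id <- sprintf("%s_%s_%s_%04d", generation, line_tag,
                  ifelse(infected, "inf", "uni"), k)
    id_eff <- numeric(n)
    trait <- numeric(n)
    resid <- matrix(0, nrow = nd, ncol = n)
    with_preserved_rng({
      for (j in k) {
        set.seed(substream_seed(params$seed, 3L, gen_idx, cell, j))
        id_eff[j] <- rnorm(1, 0, sqrt(params$var_id))
        trait[j] <- draw_trait(params, cell_line, replicate[j],
                               parent_traits, pop_mean)
        resid[, j] <- rnorm(nd, 0, sqrt(params$var_resid))
      }
    })
    stage_eff <- matrix(0, nrow = nd, ncol = n)
    if (infected) {
      pre <- days <= 8
      stage_eff[pre, ] <- matrix(rep(params$effect_suppression - trait / 2,
                                     each = sum(pre)), nrow = sum(pre))
      stage_eff[!pre, ] <- matrix(rep(params$effect_enhancement + trait / 2,
                                      each = sum(!pre)), nrow = sum(!pre))
    }
    act <- clamp01(
      params$baseline +
        rep(repl_eff[replicate], each = nd) +
        rep(id_eff, each = nd) +
        as.vector(stage_eff) +
        params$drift_per_day * rep(days, times = n) +
        as.vector(resid)
    )
    tibble(
      copepod_id = rep(id, each = nd),
      replicate = rep(replicate, each = nd),
      line = cell_line, generation = generation,
      infected = infected, exposed = TRUE,
      day = rep(days, times = n),
      activity = act,
      id_effect = rep(id_eff, each = nd),
      trait = rep(trait, each = nd)
    )
  }) |> purrr::list_rbind()
  out
}

draw_trait <- function(params, line, replicate, parent_traits, pop_mean) {
  if (is.null(parent_traits) || is.na(line)) {
    return(rnorm(1, 0, params$trait_sd))
  }
  pool <- parent_traits$trait[parent_traits$line == line &
                                parent_traits$replicate == replicate]
  if (length(pool) == 0L) {
    abort(sprintf("Empty selected parent pool for line '%s', replicate %d.",
                  line, replicate),
          class = "manipusel_error_breeding")
  }
  mu <- if (is.data.frame(pop_mean)) {
    hit <- pop_mean$pop_mean[pop_mean$line == line &
                               pop_mean$replicate == replicate]
    if (length(hit) != 1L) {
      abort(sprintf("No population mean for line '%s', replicate %d.",
                    line, replicate),
            class = "manipusel_error_breeding")
    }
    hit
  } else {
    pop_mean
  }
  midparent <- mean(sample(pool, 2L, replace = TRUE))
  mu + params$h2 * (midparent - mu) + rnorm(1, 0, params$segregation_sd)
}

generation_index <- function(generation) {
  g <- suppressWarnings(as.integer(sub("^F", "", generation)))
  if (is.na(g)) 0L else g
}
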