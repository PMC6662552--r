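#' Behavioural repeatability from variance components
#'
#' Repeatability (intraclass correlation) of repeated activity measurements:
#' `R = var_id / (var_id + var_resid)` from an intercept-only Gaussian mixed
#' model `value ~ 1 + (1 | group)` fitted by maximum likelihood. The
#' standard error comes from a seeded parametric bootstrap (simulate from the
#' fitted model, refit, recompute `R`), and the p value from a
#' likelihood-ratio test of `var_id = 0` against the boundary-corrected
#' `0.5 chi2_0 + 0.5 chi2_1` mixture null.
#'
#' @param records A data frame with one row per observation.
#' @param value Name of the response column (default `"activity"`).
#' @param group Name of the grouping column (default `"copepod_id"`).
#' @param nboot Number of parametric-bootstrap refits for the SE (default
#'   1000; 0 skips the bootstrap and returns `se = NA`).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `repeatability_estimate`: `R`, `se`, `p`,
#'   `var_id`, `var_resid`, `chi2`, `n_obs`, `n_groups`, `nboot`, and the
#'   bootstrap replicates (`boot`).
#' @examples
#' rec <- generate_cohort(cohort_params(n_per_cell = 40, var_id = 0.01,
#'                                      var_resid = 0.01, seed = 5))
#' repeatability(dplyr::filter(rec, day <= 8), nboot = 0)
#' @export
repeatability <- function(records, value = "activity", group = "copepod_id",
                          nboot = 1000L, seed = 1L) {
  records <- as.data.frame(records)
  stopifnot(all(c(value, group) %in% names(records)))
  sizes <- table(records[[group]])
  if (length(sizes) < 2L) {
    abort("At least two groups are needed to estimate repeatability.",
          class = "manipusel_error_stats")
  }
  if (all(sizes < 2L)) {
    abort("All groups are singletons; within-group variance is not estimable.",
          class = "manipusel_error_stats")
  }
  fml <- as.formula(sprintf("%s ~ 1 + (1 | %s)", value, group))
  fit <- lme4::lmer(fml, data = records, REML = FALSE)
  null_fit <- stats::lm(as.formula(sprintf("%s ~ 1", value)),
                        data = records)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_id <- vc$vcov[vc$grp == group]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  R <- ratio_R(var_id, var_resid)
  chi2 <- max(0, 2 * (as.numeric(logLik(fit)) -
                        as.numeric(logLik(null_fit))))
  p <- 0.5 * (chi2 <= 1e-12) + 0.5 * pchisq(chi2, df = 1,
                                            lower.tail = FALSE)
  boot <- numeric(0)
  se <- NA_real_
  if (nboot > 0L) {
    sims <- withr::with_seed(substream_seed(seed, 11L),
                             simulate(fit, nsim = nboot))
    boot <- map_dbl(sims, function(y) {
      bf <- suppressMessages(suppressWarnings(lme4::refit(fit, y)))
      bvc <- as.data.frame(lme4::VarCorr(bf))
      ratio_R(bvc$vcov[bvc$grp == group],
              bvc$vcov[bvc$grp == "Residual"])
    })
    se <- sd(boot)
  }
  structure(
    list(R = R, se = se, p = p, var_id = var_id, var_resid = var_resid,
         chi2 = chi2, n_obs = stats::nobs(fit), n_groups = length(sizes),
         nboot = as.integer(nboot), boot = boot, fit = fit),
    class = "repeatability_estimate"
  )
}

ratio_R <- function(var_id, var_resid) {
  if (var_id + var_resid <= 0) return(0)
  var_id / (var_id + var_resid)
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("<repeatability_estimate> R = %.3f%s, p = %.3g (n = %d obs, %d individuals)\n",
              x$R,
              if (is.na(x$se)) "" else sprintf(" +/- %.3f", x$se),
              x$p, x$n_obs, x$n_groups))
  invisible(x)
}

#' @export
tidy.repeatability_estimate <- function(x, ...) {
  tibble(term = c("R", "var_id", "var_resid"),
         estimate = c(x$R, x$var_id, x$var_resid),
         std.error = c(x$se, NA, NA),
         p.value = c(x$p, NA, NA))
}

#' @export
glance.repeatability_estimate <- function(x, ...) {
  tibble(R = x$R, se = x$se, p = x$p, chi2 = x$chi2, n_obs = x$n_obs,
         n_groups = x$n_groups, nboot = x$nboot)
}

#' Group means of manipulation scores with bootstrap confidence intervals
#'
#' Summarises a score table per selection line and generation: group mean
#' and a seeded nonparametric bootstrap percentile confidence interval
#' (default 2000 resamples, 95%). Single-copepod groups are flagged as
#' degenerate (their interval collapses to the mean).
#'
#' @param scores A score table (see [score_table()]) or the `scores` element
#'   of a [generate_experiment()] result.
#' @param nboot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param groups Grouping columns (default `c("generation", "line")`).
#' @return A tibble of class `response_summary`: grouping columns, `n`,
#'   `mean`, `lo`, `hi`, `degenerate`.
#' @export
selection_response_summary <- function(scores, nboot = 2000L, conf = 0.95,
                                       seed = 1L,
                                       groups = c("generation", "line")) {
  scores <- as_tibble(scores)
  groups <- intersect(groups, names(scores))
  alpha <- (1 - conf) / 2
  out <- scores |>
    filter(!is.na(.data$score)) |>
    group_by(across(dplyr::all_of(groups))) |>
    summarise(n = dplyr::n(),
              mean = mean(.data$score),
              boot = list(boot_means(.data$score, nboot,
                                     substream_seed(seed, 12L,
                                                    dplyr::cur_group_id()))),
              .groups = "drop") |>
    mutate(lo = map_dbl(.data$boot, ~ quantile(.x, alpha, names = FALSE)),
           hi = map_dbl(.data$boot, ~ quantile(.x, 1 - alpha,
                                               names = FALSE)),
           degenerate = .data$n < 2L) |>
    select(-"boot")
  if (any(out$degenerate)) {
    inform("selection_response_summary: single-copepod group(s); their intervals are degenerate.")
  }
  class(out) <- c("response_summary", class(out))
  out
}

boot_means <- function(x, nboot, seed) {
  if (length(x) < 2L) return(rep(mean(x), 2L))
  withr::with_seed(seed, {
    replicate(nboot, mean(sample(x, replace = TRUE)))
  })
}
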