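#' Fit a linear mixed model by maximum likelihood
#'
#' Thin wrapper around [lme4::lmer()] (Gaussian response, `REML = FALSE`)
#' that returns the variance components in a tidy form. ML rather than REML
#' is used throughout so that likelihood-ratio tests across fixed-effect
#' structures are coherent. Formulas use the usual mixed-model notation,
#' e.g. `activity ~ stage * infected + (1 | copepod_id) + (1 | replicate)`;
#' a formula without random terms falls back to [stats::lm()].
#'
#' @param records A data frame of behaviour records or scores.
#' @param formula A model formula (lme4 syntax).
#' @param logit If `TRUE`, model the empirical logit of the response instead
#'   of the raw proportion (off by default: activities are analysed on the
#'   proportion scale).
#' @return An object of class `mixed_vc`: the fitted model (`fit`), a tibble
#'   of variance components (`var_components`: `group`, `variance`, `sd`),
#'   fixed-effect estimates, `loglik`, `df`, `aic`, `n_obs`, `n_groups`, and
#'   `boundary` (`TRUE` when a variance estimate sits on the zero boundary).
#' @examples
#' rec <- generate_cohort(cohort_params(n_per_cell = 30, seed = 2))
#' fit_mixed(rec, activity ~ infected + (1 | copepod_id))
#' @export
fit_mixed <- function(records, formula, logit = FALSE) {
  records <- as.data.frame(records)
  response <- all.vars(formula)[1]
  if (logit) {
    eps <- 1 / (2 * nrow(records))
    records[[response]] <- log((records[[response]] + eps) /
                                 (1 - records[[response]] + eps))
  }
  has_ranef <- length(lme4::findbars(formula)) > 0L
  mm <- stats::model.matrix(lme4::nobars(formula), data = records)
  if (qr(mm)$rank < ncol(mm)) {
    abort("Singular fixed-effect design (rank-deficient).",
          class = "manipusel_error_fit")
  }
  if (has_ranef) {
    fit <- tryCatch(
      lme4::lmer(formula, data = records, REML = FALSE),
      error = function(e) abort(paste0("Mixed-model fit failed: ",
                                       conditionMessage(e)),
                                class = "manipusel_error_fit")
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_components <- tibble(group = vc$grp, variance = vc$vcov,
                             sd = vc$sdcor)
    n_groups <- lme4::ngrps(fit)
    fixed <- lme4::fixef(fit)
    boundary <- any(vc$vcov[vc$grp != "Residual"] < 1e-8)
    if (boundary) {
      inform("fit_mixed: a variance estimate is on the zero boundary.")
    }
  } else {
    fit <- stats::lm(formula, data = records)
    var_components <- tibble(group = "Residual",
                             variance = summary(fit)$sigma^2,
                             sd = summary(fit)$sigma)
    n_groups <- integer()
    fixed <- coef(fit)
    boundary <- FALSE
  }
  if (any(is.na(fixed))) {
    abort("Singular fixed-effect design (rank-deficient).",
          class = "manipusel_error_fit")
  }
  ll <- logLik(fit)
  structure(
    list(fit = fit, formula = formula, var_components = var_components,
         fixed_effects = fixed, loglik = as.numeric(ll),
         df = attr(ll, "df"), aic = AIC(fit),
         n_obs = stats::nobs(fit), n_groups = n_groups,
         boundary = boundary),
    class = "mixed_vc"
  )
}

#' @export
print.mixed_vc <- function(x, ...) {
  cat("<mixed_vc> ML fit, logLik ", format(x$loglik, digits = 6),
      ", AIC ", format(x$aic, digits = 6), ", n = ", x$n_obs, "\n", sep = "")
  print(x$var_components)
  invisible(x)
}

#' @export
tidy.mixed_vc <- function(x, ...) {
  bind_rows(
    tibble(term = names(x$fixed_effects),
           estimate = unname(x$fixed_effects),
           type = "fixed"),
    x$var_components |>
      mutate(term = paste0("var_", tolower(.data$group))) |>
      select(term = "term", estimate = "variance") |>
      mutate(type = "variance")
  )
}

#' @export
glance.mixed_vc <- function(x, ...) {
  tibble(loglik = x$loglik, df = x$df, aic = x$aic, n_obs = x$n_obs,
         boundary = x$boundary)
}

#' Likelihood-ratio comparison of nested model fits
#'
#' Computes the likelihood-ratio statistic `chi2 = 2 (l_full - l_reduced)`,
#' its degrees of freedom (difference in parameter counts), the upper-tail
#' chi-square p value, and the AIC difference `AIC(reduced) - AIC(full)`
#' (positive when the fuller model is preferred). Both fits must be ML fits
#' of nested models on the same data.
#'
#' @param fit_full,fit_reduced `mixed_vc` objects (or any fits supporting
#'   [stats::logLik()], [stats::AIC()] and [stats::nobs()]).
#' @return An object of class `model_comparison` with elements `chi2`, `df`,
#'   `p`, `delta_aic`.
#' @export
lrt_compare <- function(fit_full, fit_reduced) {
  get_ll <- function(f) if (inherits(f, "mixed_vc")) {
    list(ll = f$loglik, df = f$df, aic = f$aic, n = f$n_obs)
  } else {
    ll <- logLik(f)
    list(ll = as.numeric(ll), df = attr(ll, "df"), aic = AIC(f),
         n = stats::nobs(f))
  }
  a <- get_ll(fit_full); b <- get_ll(fit_reduced)
  if (a$n != b$n) {
    abort("Fits use different numbers of observations; models are not comparable.",
          class = "manipusel_error_lrt")
  }
  df <- a$df - b$df
  if (df < 1L) {
    abort("`fit_full` must have more parameters than `fit_reduced` (nested models).",
          class = "manipusel_error_lrt")
  }
  chi2 <- 2 * (a$ll - b$ll)
  if (chi2 < -1e-6) {
    abort("The fuller model has a lower likelihood; the models are not nested ML fits on the same data.",
          class = "manipusel_error_lrt")
  }
  chi2 <- max(0, chi2)
  structure(
    list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
         delta_aic = b$aic - a$aic),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> chi2 = %.4g (df = %d), p = %.4g, delta AIC = %.4g\n",
              x$chi2, x$df, x$p, x$delta_aic))
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p = x$p, delta_aic = x$delta_aic)
}
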