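#' Log-transform a cohort table
#'
#' Applies the natural logarithm to gut volume, body weight and every canal
#' measurement column present (linear dimensions, shape indices and
#' angles), the transformation applied before all regression analyses.
#' Using the natural base affects coefficients by a constant factor only,
#' never p-values or R-squared. The returned tibble carries a `log_scale`
#' attribute that downstream fitting checks.
#'
#' @param cohort Cohort tibble with columns `specimen_id`, `sex`,
#'   `body_weight_kg`, `gut_volume_cc` and canal measurement columns.
#' @return The cohort on the log scale (same column names), with
#'   `attr(, "log_scale") = TRUE`.
#' @export
log_transform_cohort <- function(cohort) {
  log_cols <- intersect(
    c("body_weight_kg", "stature_m", "gut_volume_cc", canal_responses()),
    names(cohort)
  )
  for (col in log_cols) {
    v <- cohort[[col]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      abort_pelvi(
        sprintf("Cannot log-transform field '%s': nonpositive value for specimen %s.",
                col, cohort$specimen_id[bad[1]]),
        "domain_error"
      )
    }
    cohort[[col]] <- log(v)
  }
  attr(cohort, "log_scale") <- TRUE
  attr(cohort, "log_columns") <- log_cols
  cohort
}

.check_log_scale <- function(cohort) {
  if (!isTRUE(attr(cohort, "log_scale"))) {
    abort_pelvi("Cohort must be log-transformed first; see log_transform_cohort().",
                "schema_error")
  }
}

.sex_formula <- function(response, sex) {
  if (sex == "male") {
    stats::reformulate("gut_volume_cc * body_weight_kg", response = response)
  } else {
    stats::reformulate("gut_volume_cc + body_weight_kg", response = response)
  }
}

#' Fit the sex-specific canal regression
#'
#' Ordinary least squares of one log canal measurement on log gut volume
#' and log body weight. Body weight enters as an interacting predictor in
#' males (`response ~ GV * weight`, reflecting the negative allometry of
#' gut volume on weight in males) and as a non-interacting covariate in
#' females (`response ~ GV + weight`, where gut volume and weight are
#' independent). Coefficient p-values are two-sided marginal t-tests from
#' the fitted model.
#'
#' @param cohort A log-scale cohort (see [log_transform_cohort()]).
#' @param response One of [canal_responses()] (or any numeric column).
#' @param sex `"male"` or `"female"`.
#' @return An object of class `canal_fit`; see [tidy.canal_fit()],
#'   [glance.canal_fit()] and [fit_report()].
#' @export
fit_sex_model <- function(cohort, response, sex = c("male", "female")) {
  sex <- match.arg(sex)
  .check_log_scale(cohort)
  if (!response %in% names(cohort)) {
    abort_pelvi(sprintf("Unknown response '%s'.", response), "schema_error")
  }
  dat <- cohort %>% filter(.data$sex == !!sex)
  p <- if (sex == "male") 3L else 2L
  if (nrow(dat) < p + 2L) {
    abort_pelvi(sprintf("Too few %s specimens (%d) to fit %d predictors.",
                        sex, nrow(dat), p), "schema_error")
  }
  fit <- stats::lm(.sex_formula(response, sex), data = dat)
  if (any(is.na(coef(fit)))) {
    abort_pelvi("Rank-deficient design: predictors are collinear.",
                "collinearity_error")
  }
  rw <- relative_weights(
    as.matrix(dat[, c("gut_volume_cc", "body_weight_kg")]),
    dat[[response]]
  )
  structure(
    list(
      fit = fit, response = response, sex = sex,
      model_form = if (sex == "male") "interaction" else "additive",
      n = nrow(dat), relative_weights = rw, data = dat
    ),
    class = "canal_fit"
  )
}

#' @export
print.canal_fit <- function(x, ...) {
  cat(sprintf("<canal_fit: %s ~ GV %s weight, %s (n = %d)>\n",
              x$response, if (x$model_form == "interaction") "*" else "+",
              x$sex, x$n))
  print(glance(x))
  invisible(x)
}

#' Tidy a canal fit
#'
#' Coefficient-level summary of a [fit_sex_model()] object with
#' significance flags.
#'
#' @param x A `canal_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `flag`.
#' @exportS3Method generics::tidy
#' @export
tidy.canal_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4],
    flag = significance_flags(s[, 4])
  )
}

#' Glance at a canal fit
#'
#' Model-level summary: adjusted R-squared is the headline `r.squared`
#' figure reported alongside the raw value (adjusted R-squared may
#' legitimately be negative for uninformative models), plus the overall
#' F-test p-value.
#'
#' @param x A `canal_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared.adjusted`, `r.squared.raw`,
#'   `statistic`, `p.value`, `df`, `nobs`.
#' @exportS3Method generics::glance
#' @export
glance.canal_fit <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble(
    r.squared.adjusted = s$adj.r.squared,
    r.squared.raw = s$r.squared,
    statistic = unname(f[1]),
    p.value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
    df = unname(f[2]), nobs = x$n
  )
}

#' One-row regression report for a canal fit
#'
#' Shapes a fitted model into the reporting convention of the analysis:
#' per-predictor betas with p-values and flags, adjusted R-squared as the
#' headline R-squared (raw alongside), the overall model p-value, and the
#' relative-weight percentages of the two main predictors.
#'
#' @param x A `canal_fit`.
#' @return A one-row tibble.
#' @export
fit_report <- function(x) {
  td <- tidy(x)
  gl <- glance(x)
  beta <- function(term) unname(td$estimate[td$term == term])
  pval <- function(term) unname(td$p.value[td$term == term])
  out <- tibble(
    response = x$response, sex = x$sex, model_form = x$model_form,
    beta_gv = beta("gut_volume_cc"), p_gv = pval("gut_volume_cc"),
    flag_gv = significance_flags(pval("gut_volume_cc")),
    beta_weight = beta("body_weight_kg"), p_weight = pval("body_weight_kg"),
    flag_weight = significance_flags(pval("body_weight_kg")),
    beta_interaction = NA_real_, p_interaction = NA_real_,
    r2_adjusted = gl$r.squared.adjusted, r2_raw = gl$r.squared.raw,
    model_p = gl$p.value, flag_model = significance_flags(gl$p.value),
    rw_gv_pct = x$relative_weights$pct[1],
    rw_weight_pct = x$relative_weights$pct[2],
    n = x$n
  )
  if (x$model_form == "interaction") {
    it <- "gut_volume_cc:body_weight_kg"
    out$beta_interaction <- beta(it)
    out$p_interaction <- pval(it)
  }
  out
}

#' Test whether the female model needs an interaction term
#'
#' Nested-model F-test (ANOVA) comparing the additive model
#' `response ~ GV + weight` against the interaction model
#' `response ~ GV * weight` on the same specimens.
#'
#' @param cohort A log-scale cohort.
#' @param response A canal response name.
#' @param sex Which sex's specimens to use (default `"female"`).
#' @return The F-test p-value (scalar).
#' @export
compare_interaction <- function(cohort, response, sex = "female") {
  .check_log_scale(cohort)
  dat <- cohort %>% filter(.data$sex == !!sex)
  f_add <- stats::lm(stats::reformulate("gut_volume_cc + body_weight_kg",
                                        response = response), data = dat)
  f_int <- stats::lm(stats::reformulate("gut_volume_cc * body_weight_kg",
                                        response = response), data = dat)
  if (any(is.na(coef(f_int))) ||
      f_int$df.residual >= f_add$df.residual) {
    abort_pelvi("Interaction term is degenerate (collinear or constant); the comparison is undefined.",
                "degenerate_comparison_error")
  }
  an <- stats::anova(f_add, f_int)
  an[["Pr(>F)"]][2]
}

#' Johnson relative weights
#'
#' Decomposes the raw R-squared of an OLS regression into approximate
#' per-predictor contributions. Predictors are transformed to their
#' closest orthogonal counterparts through the symmetric square root of
#' the predictor correlation matrix \eqn{R_{xx} = V \Lambda V'}: with
#' \eqn{\Delta = V \Lambda^{1/2} V'}, the raw weights are
#' \eqn{\epsilon = (\Delta \circ \Delta)(\beta^* \circ \beta^*)} where
#' \eqn{\beta^* = \Delta^{-1} r_{xy}}. The raw weights are non-negative
#' and sum exactly to the raw R-squared; percentages sum to 100.
#'
#' @param x Numeric matrix of predictors (n x p, p >= 2).
#' @param y Numeric response vector.
#' @return A tibble with columns `predictor`, `raw_weight`, `pct`.
#' @export
relative_weights <- function(x, y) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    abort_pelvi("Relative weights need at least 2 predictors.", "schema_error")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  rxx <- stats::cor(x)
  eig <- eigen(rxx, symmetric = TRUE)
  if (min(eig$values) < 1e-10) {
    abort_pelvi("Predictor correlation matrix is singular; relative weights are undefined.",
                "collinearity_error")
  }
  delta <- eig$vectors %*% diag(sqrt(eig$values)) %*% t(eig$vectors)
  rxy <- stats::cor(x, y)
  beta <- solve(delta, rxy)
  eps <- as.vector((delta * delta) %*% (beta * beta))
  tibble(
    predictor = colnames(x),
    raw_weight = eps,
    pct = 100 * eps / sum(eps)
  )
}

#' Significance flags
#'
#' The reporting convention: `"**"` for p at or below the conservative
#' alpha of 0.01, `"*"` for p at or below 0.05, empty otherwise
#' (thresholds inclusive).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector in `{"", "*", "**"}`.
#' @export
significance_flags <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort_pelvi("p-values must lie in [0, 1].", "schema_error")
  }
  dplyr::case_when(p <= 0.01 ~ "**", p <= 0.05 ~ "*", .default = "")
}

#' Body-mass groups at one standard deviation
#'
#' Splits specimens of each sex into three body-mass groups around the
#' per-sex mean: `low` strictly below mean - 1 SD, `high` strictly above
#' mean + 1 SD, `mid` otherwise (sample SD). Used for grouped display of
#' regressions.
#'
#' @param cohort Cohort tibble with `sex` and `body_weight_kg` (any scale;
#'   grouping is monotone-invariant only under per-sex monotone
#'   transforms, so use one scale consistently).
#' @return The cohort with a `weight_group` factor column
#'   (levels low/mid/high).
#' @export
bodymass_groups <- function(cohort) {
  grouped <- cohort %>%
    group_by(sex) %>%
    mutate(
      .mean = mean(body_weight_kg),
      .sd = stats::sd(body_weight_kg)
    ) %>%
    ungroup()
  if (any(grouped$.sd == 0)) {
    rlang::warn("Zero body-weight variance in at least one sex; all specimens fall in one group.")
  }
  grouped %>%
    mutate(
      weight_group = factor(
        case_when(
          .sd > 0 & body_weight_kg < .mean - .sd ~ "low",
          .sd > 0 & body_weight_kg > .mean + .sd ~ "high",
          .default = "mid"
        ),
        levels = c("low", "mid", "high")
      )
    ) %>%
    select(-".mean", -".sd")
}

#' Full per-sex regression report
#'
#' Fits the sex-specific model for every canal response present in the
#' cohort and binds the one-row reports: eleven responses per sex (six
#' linear dimensions, three shape indices, two angles) with betas,
#' p-values, flags, adjusted and raw R-squared, model p-value, and the
#' two relative-weight percentages (which sum to 100 within each row).
#' No multiple-testing correction is applied across responses; instead the
#' `"**"` flag marks the conservative alpha of 0.01 (the number of tests
#' is returned as an attribute).
#'
#' @param cohort A cohort tibble on the raw scale (it is log-transformed
#'   internally) or already log-scale.
#' @param responses Response columns to fit (default all of
#'   [canal_responses()] present in the cohort).
#' @return A tibble with one row per (sex, response); attribute `n_tests`
#'   records how many models were fitted.
#' @export
regression_report <- function(cohort, responses = NULL) {
  if (!isTRUE(attr(cohort, "log_scale"))) {
    cohort <- log_transform_cohort(cohort)
  }
  if (is.null(responses)) {
    responses <- intersect(canal_responses(), names(cohort))
  }
  sexes <- intersect(c("male", "female"), unique(cohort$sex))
  report <- purrr::map(sexes, function(sx) {
    purrr::map(responses, function(resp) {
      fit_report(fit_sex_model(cohort, resp, sx))
    }) %>% list_rbind()
  }) %>% list_rbind()
  attr(report, "n_tests") <- nrow(report)
  report
}
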