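#' Two-way absolute-agreement intraclass correlation, single rater
#'
#' ICC from the two-way crossed ANOVA decomposition (subjects x raters),
#' absolute-agreement definition, single-rater form:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares. Absolute agreement penalises systematic rater
#' offsets as well as inconsistency, so adding a constant to one rater
#' lowers the estimate. The 95% confidence interval uses the standard
#' F-based method with Satterthwaite degrees of freedom.
#'
#' Subjects with any missing rating are dropped listwise (a message reports
#' how many).
#'
#' @param ratings An n-subjects x k-raters numeric matrix or data frame of
#'   one measurement (n >= 2, k >= 2).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param measurement_name Label carried into the result.
#' @return A one-row tibble: `measurement`, `estimate`, `ci_low`,
#'   `ci_high`, `model` (fixed text "two-way, absolute agreement, single
#'   rater"), `n`, `k`.
#' @export
#' @examples
#' m <- cbind(r1 = c(1, 3, 5, 7), r2 = c(2, 4, 6, 8))
#' icc_absolute_agreement(m) # estimate 40/43
icc_absolute_agreement <- function(ratings, conf_level = 0.95,
                                   measurement_name = "measurement") {
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  keep <- stats::complete.cases(x)
  if (any(!keep)) {
    rlang::inform(sprintf("Dropped %d subject(s) with missing ratings.", sum(!keep)))
    x <- x[keep, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) {
    abort_pelvi("ICC needs at least 2 subjects and 2 raters after dropping missing rows.",
                "schema_error")
  }

  ms <- .twoway_mean_squares(x)
  scale2 <- mean(x^2) + 1
  if (ms$msr <= 1e-12 * scale2) {
    abort_pelvi("Between-subject variance is zero; the ICC is undefined for these ratings.",
                "undefined_icc_error")
  }
  est <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))

  alpha <- 1 - conf_level
  if (est < 1) {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v_num <- (a * ms$msc + b * ms$mse)^2
    v_den <- (a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1))
    v <- if (v_den > 0) v_num / v_den else Inf
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    ci_high <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  } else {
    ci_low <- 1; ci_high <- 1   # perfect agreement: degenerate interval
  }

  tibble(
    measurement = measurement_name,
    estimate = est,
    ci_low = min(ci_low, est),
    ci_high = max(ci_high, est),
    model = "two-way, absolute agreement, single rater",
    n = n, k = k
  )
}

# two-way crossed ANOVA mean squares, computed directly from the matrix
.twoway_mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(
    msr = ss_rows / (n - 1),
    msc = ss_cols / (k - 1),
    mse = max(0, ss_err) / ((n - 1) * (k - 1))
  )
}

#' Classify an ICC estimate
#'
#' Conventional agreement bands with closed-left thresholds: excellent for
#' estimates of at least 0.90, good for at least 0.75, moderate for at
#' least 0.50, poor below.
#'
#' @param estimate Numeric vector of ICC estimates.
#' @return Character vector in `{"poor","moderate","good","excellent"}`.
#' @export
classify_agreement <- function(estimate) {
  if (any(!is.finite(estimate))) {
    abort_pelvi("ICC estimates must be finite to classify.", "schema_error")
  }
  dplyr::case_when(
    estimate >= 0.90 ~ "excellent",
    estimate >= 0.75 ~ "good",
    estimate >= 0.50 ~ "moderate",
    .default = "poor"
  )
}

#' ICC report from a long ratings table
#'
#' Computes the absolute-agreement ICC for each measurement in a long
#' table, treating observers as raters. When replicates are present they
#' are averaged within observer first (replicate averaging belongs to the
#' fuzzy-landmark rule, not the inter-observer comparison).
#'
#' @param ratings_long Tibble with columns `specimen_id`, `observer_id`,
#'   `replicate_id`, `measurement`, `value`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of ICC rows, one per measurement, with an `agreement`
#'   classification column.
#' @export
icc_report <- function(ratings_long, conf_level = 0.95) {
  needed <- c("specimen_id", "observer_id", "measurement", "value")
  missing_cols <- setdiff(needed, names(ratings_long))
  if (length(missing_cols) > 0) {
    abort_pelvi(sprintf("Ratings table is missing column(s): %s.",
                        paste(missing_cols, collapse = ", ")), "schema_error")
  }
  ratings_long %>%
    group_by(specimen_id, observer_id, measurement) %>%
    summarise(value = mean(value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = observer_id, values_from = value) %>%
    dplyr::group_split(measurement) %>%
    map(function(df) {
      icc_absolute_agreement(
        df %>% select(-specimen_id, -measurement),
        conf_level = conf_level,
        measurement_name = df$measurement[1]
      )
    }) %>%
    list_rbind() %>%
    mutate(agreement = classify_agreement(estimate))
}

#' Average fuzzy-landmark replicates
#'
#' Canal measurements built on "fuzzy" landmarks (points without a sharply
#' defined anatomical location — by default the ischial tuberosities, hence
#' the outlet ML diameter) are measured in replicate and averaged; all
#' other fields are required to agree across replicates. Shape indices
#' whose AP or ML parent is fuzzy (the outlet shape, by default) are
#' recomputed from the averaged parents rather than averaged as ratios.
#'
#' @param measurements Canal-measurement tibble with one row per
#'   (specimen_id, observer_id, replicate_id), as from
#'   [canal_measurements()].
#' @param fuzzy Character vector of fuzzy measurement columns
#'   (default `"OML"`).
#' @param tol Relative tolerance within which non-fuzzy fields must agree
#'   across replicates.
#' @return A tibble with one row per (specimen_id, observer_id),
#'   `replicate_id` set to 1.
#' @export
average_fuzzy_replicates <- function(measurements, fuzzy = "OML", tol = 1e-6) {
  shape_parents <- list(
    inlet_shape = c("IAP", "IML"),
    midplane_shape = c("MAP", "MML"),
    outlet_shape = c("OAP", "OML")
  )
  num_cols <- setdiff(
    names(measurements)[vapply(measurements, is.numeric, logical(1))],
    c("replicate_id")
  )
  affected_shapes <- names(shape_parents)[
    vapply(shape_parents, function(p) any(p %in% fuzzy), logical(1))
  ]
  affected_shapes <- intersect(affected_shapes, num_cols)
  strict_cols <- setdiff(num_cols, c(fuzzy, affected_shapes))

  collapse <- function(df, key) {
    if (nrow(df) > 1L) {
      for (col in strict_cols) {
        v <- df[[col]]
        if (diff(range(v)) > tol * max(1, abs(mean(v)))) {
          abort_pelvi(
            sprintf("Non-fuzzy field '%s' differs across replicates for specimen %s.",
                    col, key$specimen_id[1]),
            "inconsistent_replicates_error"
          )
        }
      }
    }
    out <- df[1, , drop = FALSE]
    for (col in intersect(fuzzy, num_cols)) out[[col]] <- mean(df[[col]])
    for (col in affected_shapes) {
      p <- shape_parents[[col]]
      if (all(p %in% names(out))) {
        out[[col]] <- shape_index(out[[p[1]]], out[[p[2]]])
      } else {
        out[[col]] <- mean(df[[col]])
      }
    }
    out$replicate_id <- 1L
    out
  }

  measurements %>%
    group_by(specimen_id, observer_id) %>%
    dplyr::group_modify(~ collapse(.x, .y)) %>%
    ungroup()
}
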