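#' Grouped gut-volume regression plot
#'
#' Scatter of a log canal response against log gut volume with specimens
#' split into body-mass groups (below mean - 1 SD, within 1 SD, above
#' mean + 1 SD, per sex) and a least-squares line per group, facetted by
#' sex — the standard display for how the gut-canal relationship is
#' modulated by body size.
#'
#' @param cohort Cohort tibble on the raw scale.
#' @param response One of [canal_responses()].
#' @return A ggplot object.
#' @export
plot_canal_regression <- function(cohort, response) {
  dat <- bodymass_groups(cohort) %>%
    mutate(log_gv = log(gut_volume_cc), log_resp = log(.data[[response]]))
  ggplot2::ggplot(dat, ggplot2::aes(x = log_gv, y = .data$log_resp,
                                    colour = weight_group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.7) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::scale_colour_manual(
      values = c(low = "#c7e9c0", mid = "#74c476", high = "#00441b"),
      name = "body mass"
    ) +
    ggplot2::labs(x = "log gut volume (cc)", y = paste0("log ", response)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_sex_model Plot a fitted sex-specific model: observed
#'   points by body-mass group (grouped on the fit's log-weight scale)
#'   with per-group least-squares lines against log gut volume.
#' @param object A `canal_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.canal_fit <- function(object, ...) {
  dat <- bodymass_groups(object$data)
  ggplot2::ggplot(dat, ggplot2::aes(x = gut_volume_cc,
                                    y = .data[[object$response]],
                                    colour = weight_group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(low = "#fdd0a2", mid = "#fd8d3c", high = "#7f2704"),
      name = "body mass"
    ) +
    ggplot2::labs(
      x = "log gut volume (cc)", y = paste0("log ", object$response),
      title = sprintf("%s ~ GV %s weight (%s)", object$response,
                      if (object$model_form == "interaction") "*" else "+",
                      object$sex)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ICC report
#'
#' Dot-and-interval display of per-measurement absolute-agreement ICC
#' estimates with their 95% confidence intervals and the good (0.75) and
#' excellent (0.90) agreement thresholds.
#'
#' @param icc A tibble from [icc_report()].
#' @return A ggplot object.
#' @export
plot_icc <- function(icc) {
  ggplot2::ggplot(icc, ggplot2::aes(x = estimate,
                                    y = stats::reorder(measurement, estimate))) +
    ggplot2::geom_vline(xintercept = c(0.75, 0.90), linetype = "dashed",
                        colour = "grey55") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "ICC (two-way, absolute agreement, single rater)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
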