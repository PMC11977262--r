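#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Differences against pair means with the bias line (solid) and 95% limits
#' of agreement (dashed); outliers beyond the limits are drawn in red.
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$mean, y = .data$diff,
                               colour = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "Mean of manual and automated CSA (cm²)",
                  y = "Automated - manual (cm²)") +
    ggplot2::theme_minimal()
}

#' Fixed-effect plot of the vertebral level model
#'
#' Level CSA estimates relative to L3 (percent) with Wald 95% intervals
#' propagated on the percentage scale.
#'
#' @param object a [fit_level_model()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.level_model_fit <- function(object, ...) {
  f <- object$fixed
  ref <- f$estimate_cm2[f$level == "L3"]
  d <- dplyr::mutate(f,
                     pct_low = ifelse(.data$level == "L3", 100,
                                      100 * (ref + .data$estimate_cm2 -
                                               1.96 * .data$se) / ref),
                     pct_high = ifelse(.data$level == "L3", 100,
                                       100 * (ref + .data$estimate_cm2 +
                                                1.96 * .data$se) / ref))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$relative_pct)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$pct_low,
                                          ymax = .data$pct_high)) +
    ggplot2::labs(x = "Vertebral level", y = "CSA relative to L3 (%)",
                  title = object$tissue) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of the SMI median split
#'
#' @param object a [survival_analysis()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.survival_result <- function(object, ...) {
  km2 <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = object$data)
  d <- tibble::tibble(
    time = km2$time,
    surv = km2$surv,
    group = rep(sub("group=", "", names(km2$strata)), km2$strata)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (months)", y = "Overall survival",
                  colour = "SMI group") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot per-slice CSA relative to the vertebra center
#'
#' Reproduces the signed-offset view of slice-selection sensitivity: percent
#' CSA against the slice offset from the vertebra's center (negative =
#' inferior), one line per tissue.
#'
#' @param relative_profiles tibble from [relative_profile()], possibly
#'   stacked over tissues/subjects.
#' @return A ggplot object.
#' @export
plot_relative_profile <- function(relative_profiles) {
  ggplot2::ggplot(relative_profiles,
                  ggplot2::aes(x = .data$offset, y = .data$pct,
                               colour = .data$tissue)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Slice offset from vertebra center (inferior < 0)",
                  y = "CSA relative to center slice (%)") +
    ggplot2::theme_minimal()
}
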