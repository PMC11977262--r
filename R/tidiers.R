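#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-pair Bland-Altman table
#'
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @return Tibble with one row per pair: `manual`, `auto`, `mean`, `diff`,
#'   `outlier`.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' One-row Bland-Altman summary
#'
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @return One-row tibble: `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pearson_r`, `r_ci_low`, `r_ci_high`, `n_outliers`.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 pearson_r = x$pearson_r, r_ci_low = x$r_ci_low,
                 r_ci_high = x$r_ci_high,
                 n_outliers = sum(x$pairs$outlier))
}

#' Fixed-effect table of a level model fit
#'
#' @param x a [fit_level_model()] object.
#' @param ... unused.
#' @return Tibble: `level`, `estimate_cm2`, `se`, `p`, `relative_pct`.
#' @export
tidy.level_model_fit <- function(x, ...) x$fixed

#' One-row level-model summary
#'
#' @param x a [fit_level_model()] object.
#' @param ... unused.
#' @return One-row tibble with variance components and sizes.
#' @export
glance.level_model_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_patients = x$n_patients,
                 var_patient = x$var_patient,
                 var_residual = x$var_residual,
                 sd_patient = sqrt(x$var_patient),
                 sd_residual = sqrt(x$var_residual))
}

#' Tidy survival-result coefficients
#'
#' @param x a [survival_analysis()] object.
#' @param ... unused.
#' @return Tibble with one row per reported statistic (`median_os`,
#'   `hazard_ratio`, `c_index`, `auc`) with estimate and CI bounds where
#'   defined.
#' @export
tidy.survival_result <- function(x, ...) {
  tibble::tibble(
    statistic = c("median_os", "hazard_ratio", "c_index", "auc"),
    estimate = c(x$median_os, x$hazard_ratio, x$c_index, x$auc),
    ci_low = c(x$median_os_ci[1], x$hr_ci[1], NA, NA),
    ci_high = c(x$median_os_ci[2], x$hr_ci[2], NA, NA),
    p = c(NA, x$hr_p, NA, NA)
  )
}

#' One-row survival summary
#'
#' @param x a [survival_analysis()] object.
#' @param ... unused.
#' @return One-row tibble of the headline prognosis numbers.
#' @export
glance.survival_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 median_os = x$median_os,
                 median_os_low = x$median_os_ci[1],
                 median_os_high = x$median_os_ci[2],
                 smi_split = x$smi_split,
                 hazard_ratio = x$hazard_ratio,
                 hr_low = x$hr_ci[1], hr_high = x$hr_ci[2], hr_p = x$hr_p,
                 c_index = x$c_index, auc = x$auc)
}
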