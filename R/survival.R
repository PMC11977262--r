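#' Harrell's concordance index for a risk score
#'
#' Probability that, of two comparable subjects, the one with the higher
#' risk score has the shorter survival. Comparable pairs are those where the
#' ordering of the event times is determinate under censoring; tied risk
#' scores in comparable pairs contribute 1/2. Computed with the
#' `survival` package's concordance machinery in risk-score orientation.
#'
#' @param time follow-up times.
#' @param event event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param risk risk scores: higher risk should mean shorter survival.
#' @return Concordance index in [0, 1].
#' @export
concordance_index <- function(time, event, risk) {
  d <- data.frame(time = time, event = as.integer(event), risk = risk)
  cf <- survival::concordance(survival::Surv(time, event) ~ risk, data = d,
                              reverse = TRUE)
  unname(cf$concordance)
}

#' SMI-based survival analysis
#'
#' The prognosis battery for a skeletal-muscle-index measurement:
#' Kaplan-Meier median overall survival with 95% CI; a Cox
#' proportional-hazards model on the cohort-internal median split of SMI
#' (Efron ties); Harrell's C-index treating low SMI as high risk (risk score
#' = -SMI, so C > 0.5 means higher SMI predicts longer survival); and the
#' ROC AUC of SMI for classifying above-median OS. For the AUC labels,
#' subjects with an event before the median OS are the below-median class,
#' subjects observed (event or censored) beyond it are the above-median
#' class, and subjects censored before the median OS are excluded as
#' indeterminate.
#'
#' The hazard ratio is for the low-SMI group relative to the high-SMI group
#' (reference = high SMI), so HR > 1 means low muscle mass is adverse.
#'
#' @param data data frame of survival records.
#' @param time,event,smi unquoted column names: follow-up time (months),
#'   event indicator, skeletal muscle index.
#' @param split split point for the Cox groups; `"median"` (default) or a
#'   number.
#' @return An object of class `survival_result`.
#' @export
survival_analysis <- function(data, time = time_months, event = event,
                              smi = smi, split = "median") {
  d <- tibble::tibble(
    time = dplyr::pull(data, {{ time }}),
    event = as.integer(dplyr::pull(data, {{ event }})),
    smi = dplyr::pull(data, {{ smi }})
  )
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n < 10) {
    stop("sample-size error: at least 10 subjects required", call. = FALSE)
  }
  if (sum(d$event) == 0) {
    stop("estimation error: no events observed", call. = FALSE)
  }
  cut <- if (identical(split, "median")) stats::median(d$smi) else split
  if (all(d$smi == d$smi[1])) {
    stop("degenerate split error: all SMI values are tied", call. = FALSE)
  }
  d$group <- factor(ifelse(d$smi <= cut, "low", "high"),
                    levels = c("high", "low"))
  if (any(tapply(d$event, d$group, sum) == 0)) {
    stop("estimation error: a split group has no events", call. = FALSE)
  }

  km <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  kt <- summary(km)$table
  cox <- survival::coxph(survival::Surv(time, event) ~ group, data = d,
                         ties = "efron")
  sc <- summary(cox)
  hr <- unname(sc$conf.int[1, "exp(coef)"])
  hr_ci <- unname(sc$conf.int[1, c("lower .95", "upper .95")])
  hr_p <- unname(sc$coefficients[1, "Pr(>|z|)"])

  cidx <- concordance_index(d$time, d$event, -d$smi)

  med_os <- unname(kt["median"])
  roc_lab <- rep(NA, n)
  if (!is.na(med_os)) {
    roc_lab[d$event == 1 & d$time < med_os] <- FALSE
    roc_lab[d$time >= med_os] <- TRUE
  }
  keep <- !is.na(roc_lab)
  auc <- if (length(unique(roc_lab[keep])) == 2) {
    as.numeric(pROC::auc(pROC::roc(
      response = roc_lab[keep], predictor = d$smi[keep],
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )))
  } else NA_real_

  structure(list(
    n = n, n_events = sum(d$event),
    median_os = med_os,
    median_os_ci = unname(kt[c("0.95LCL", "0.95UCL")]),
    smi_split = cut,
    hazard_ratio = hr, hr_ci = hr_ci, hr_p = hr_p,
    c_index = cidx, auc = auc,
    km = km, cox = cox, data = d
  ), class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("<survival_result> n = ", x$n, " (", x$n_events, " events)\n",
      "  median OS ", signif(x$median_os, 4), " [",
      signif(x$median_os_ci[1], 4), ", ", signif(x$median_os_ci[2], 4),
      "] months\n",
      "  HR (low vs high SMI) ", signif(x$hazard_ratio, 4), " [",
      signif(x$hr_ci[1], 4), ", ", signif(x$hr_ci[2], 4), "], p = ",
      signif(x$hr_p, 3), "\n",
      "  C-index ", signif(x$c_index, 4), ", AUC ", signif(x$auc, 4), "\n",
      sep = "")
  invisible(x)
}
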