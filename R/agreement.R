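#' Bland-Altman agreement between manual and automated measurements
#'
#' Computes the mean difference (bias = mean(auto - manual)), the sample SD
#' of the differences, and the 95% limits of agreement bias +/- 1.96 x SD,
#' together with the Pearson correlation of the paired measurements and its
#' Fisher-z 95% confidence interval. Pairs whose difference lies outside the
#' limits of agreement are flagged as outliers.
#'
#' @param data data frame of paired measurements.
#' @param manual,auto unquoted column names of the manual and automated
#'   values.
#' @return An object of class `bland_altman`; see [tidy.bland_altman()] and
#'   [glance.bland_altman()].
#' @examples
#' d <- data.frame(manual = c(10, 20, 30, 40, 50),
#'                 auto   = c(11, 22, 33, 44, 55))
#' glance(bland_altman(d, manual, auto))
#' @export
bland_altman <- function(data, manual, auto) {
  m <- dplyr::pull(data, {{ manual }})
  a <- dplyr::pull(data, {{ auto }})
  keep <- stats::complete.cases(m, a)
  m <- m[keep]; a <- a[keep]
  n <- length(m)
  if (n < 3) {
    stop("sample-size error: at least 3 complete pairs required",
         call. = FALSE)
  }
  diffs <- a - m
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  # correlation is reported when defined; degenerate pairs (n < 4 or zero
  # variance) leave the r fields NA rather than failing the agreement stats
  r <- tryCatch(pearson_ci(tibble::tibble(x = m, y = a), x, y),
                error = function(e) {
                  tibble::tibble(r = NA_real_, ci_low = NA_real_,
                                 ci_high = NA_real_, p = NA_real_, n = n)
                })
  pairs <- tibble::tibble(
    manual = m, auto = a,
    mean = (m + a) / 2, diff = diffs,
    outlier = diffs < loa_low - 1e-12 | diffs > loa_high + 1e-12
  )
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high,
                 pearson_r = r$r, r_ci_low = r$ci_low, r_ci_high = r$ci_high,
                 r_p = r$p, pairs = pairs),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n = ", x$n,
      ", bias = ", signif(x$bias, 4),
      ", limits of agreement [", signif(x$loa_low, 4), ", ",
      signif(x$loa_high, 4), "]",
      ", r = ", signif(x$pearson_r, 4),
      ", outliers = ", sum(x$pairs$outlier), "\n", sep = "")
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param data data frame.
#' @param x,y unquoted column names.
#' @param level confidence level (default 0.95).
#' @return One-row tibble with `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_ci <- function(data, x, y, level = 0.95) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 4) {
    stop("sample-size error: at least 4 complete pairs required",
         call. = FALSE)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("degenerate-input error: zero variance in one of the variables",
         call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv, conf.level = level)
  tibble::tibble(r = unname(ct$estimate),
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 p = ct$p.value, n = length(xv))
}
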