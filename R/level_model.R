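#' Linear mixed model for CSA across vertebral levels
#'
#' Fits `csa ~ level + (1 | patient)` by restricted maximum likelihood, with
#' L3 as the reference level, quantifying how much a measurement taken at L2
#' or L4 differs systematically from the L3 reference while a per-patient
#' random intercept absorbs between-subject size differences. Fixed-effect
#' p-values are large-sample Wald tests. The relative value of each level is
#' derived from the fixed effects only:
#' `100 * (beta_ref + beta_level) / beta_ref`, so L3 is 100% by definition.
#'
#' @param data long-format data frame with one row per patient x level.
#' @param csa,level,patient unquoted column names: CSA in cm^2, vertebral
#'   level (`"L2"`, `"L3"`, `"L4"`), patient identifier.
#' @param tissue optional tissue name recorded in the fit.
#' @return An object of class `level_model_fit` with elements `tissue`,
#'   `fixed` (tibble: `level`, `estimate_cm2`, `se`, `p`, `relative_pct`),
#'   `var_patient`, `var_residual`, `n_patients`, `n_obs`, and the
#'   underlying `lme4` `model`.
#' @export
fit_level_model <- function(data, csa = csa, level = level,
                            patient = patient, tissue = NULL) {
  d <- tibble::tibble(
    csa = dplyr::pull(data, {{ csa }}),
    level = as.character(dplyr::pull(data, {{ level }})),
    patient = as.character(dplyr::pull(data, {{ patient }}))
  )
  d <- d[stats::complete.cases(d), ]
  levels_present <- unique(d$level)
  if (!"L3" %in% levels_present) {
    stop("design error: reference level L3 is absent", call. = FALSE)
  }
  if (length(levels_present) < 2) {
    stop("design error: at least two vertebral levels are required",
         call. = FALSE)
  }
  per_patient <- table(d$patient)
  if (sum(per_patient >= 2) < 2) {
    stop("design error: need >= 2 patients with >= 2 levels each",
         call. = FALSE)
  }
  d$level <- factor(d$level, levels = intersect(c("L3", "L1", "L2", "L4", "L5"),
                                                levels_present))
  fit <- suppressMessages(lme4::lmer(
    csa ~ level + (1 | patient), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.grad = "ignore",
                                check.conv.hess = "ignore",
                                check.conv.singular = "ignore")
  ))
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_patient <- vc$vcov[vc$grp == "patient"]
  var_residual <- vc$vcov[vc$grp == "Residual"]
  # an exactly noiseless fit has a degenerate information matrix; its
  # fixed-effect covariance is the zero matrix
  V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                error = function(e) NULL)
  se <- if (!is.null(V) && !anyNA(V)) {
    sqrt(diag(V))
  } else if (var_patient + var_residual < 1e-8) {
    rep(0, length(beta))
  } else {
    rep(NA_real_, length(beta))
  }
  lv <- c("(Intercept)" = "L3",
          stats::setNames(sub("^level", "", names(beta)[-1]),
                          names(beta)[-1]))
  est <- unname(beta)
  beta_ref <- est[1]
  offsets <- unname(ifelse(lv == "L3", 0, est))
  p <- ifelse(is.finite(se) & se > 0,
              2 * stats::pnorm(-abs(est / se)), NA_real_)
  fixed <- tibble::tibble(
    level = unname(lv),
    estimate_cm2 = est,
    se = unname(se),
    p = unname(p),
    relative_pct = relative_level_pct(beta_ref, offsets)
  )
  structure(list(
    tissue = tissue,
    fixed = fixed,
    var_patient = var_patient,
    var_residual = var_residual,
    n_patients = length(unique(d$patient)),
    n_obs = nrow(d),
    model = fit
  ), class = "level_model_fit")
}

#' @export
print.level_model_fit <- function(x, ...) {
  cat("<level_model_fit>",
      if (!is.null(x$tissue)) paste0(" ", x$tissue), " ",
      x$n_obs, " observations, ", x$n_patients, " patients\n", sep = "")
  print(x$fixed)
  cat("random intercept variance ", signif(x$var_patient, 4),
      ", residual variance ", signif(x$var_residual, 4), "\n", sep = "")
  invisible(x)
}

#' Level CSA relative to the L3 reference, in percent
#'
#' `100 * (beta_ref + beta_level) / beta_ref`, where `beta_ref` is the L3
#' reference estimate and `beta_level` the fixed-effect offset of the level
#' (0 for L3 itself).
#'
#' @param beta_ref L3 reference CSA estimate (cm^2), > 0.
#' @param beta_level fixed-effect offset (cm^2); vectorized.
#' @return Percentages (100 for L3).
#' @export
relative_level_pct <- function(beta_ref, beta_level) {
  if (any(!is.finite(beta_ref)) || any(beta_ref <= 0)) {
    stop("undefined-reference error: reference estimate must be positive",
         call. = FALSE)
  }
  100 * (beta_ref + beta_level) / beta_ref
}

#' Relative value of a fitted level
#'
#' @param fit a [fit_level_model()] result.
#' @param level level name, e.g. `"L2"`.
#' @return Percent CSA relative to L3.
#' @export
relative_level_value <- function(fit, level) {
  stopifnot(inherits(fit, "level_model_fit"))
  i <- match(level, fit$fixed$level)
  if (is.na(i)) {
    stop("level '", level, "' was not fitted", call. = FALSE)
  }
  fit$fixed$relative_pct[i]
}
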