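#' Configuration for a measurement run
#'
#' Bundles everything one subject's measurement needs: the CT (path or
#' [ct_volume()]), the label maps (named list of paths or [ct_labelmap()]s;
#' names `spine`, `vertebral_bodies`, `trunk`, `psoas`,
#' `compartment_muscle`, `compartment_visceral`,
#' `compartment_subcutaneous`), the target vertebra, the tissue definitions
#' (HU windows may be overridden), the reference mode, and where to write
#' results.
#'
#' @param ct CT volume or NIfTI path.
#' @param labels named list of label maps or NIfTI paths.
#' @param subject subject identifier.
#' @param target_vertebra vertebra defining the reference level (default
#'   `"vertebra_L3"`).
#' @param tissues tissue definition tibble (default [tissue_definitions()]).
#' @param reference_mode `"center_slice"` (single-slice reference at the
#'   vertebra's center of mass) or `"vertebra_mean"` (mean over the
#'   vertebra's slice span).
#' @param height_m body height in m, or `NA` to skip SMI.
#' @param output_dir directory for CSV/JSON outputs, or `NULL` to keep
#'   results in memory only.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ct, labels, subject = "subject",
                       target_vertebra = "vertebra_L3",
                       tissues = tissue_definitions(),
                       reference_mode = c("center_slice", "vertebra_mean"),
                       height_m = NA_real_, output_dir = NULL) {
  reference_mode <- match.arg(reference_mode)
  if (any(tissues$hu_low > tissues$hu_high)) {
    stop("invalid tissue override: hu_low > hu_high", call. = FALSE)
  }
  if (!target_vertebra %in% names(default_vocabulary())) {
    stop("target vertebra '", target_vertebra,
         "' is not in the label vocabulary", call. = FALSE)
  }
  structure(list(ct = ct, labels = labels, subject = subject,
                 target_vertebra = target_vertebra, tissues = tissues,
                 reference_mode = reference_mode, height_m = height_m,
                 output_dir = output_dir),
            class = "run_config")
}

resolve_ct <- function(x) {
  if (inherits(x, "ct_volume")) x else load_ct(x)
}

resolve_labels <- function(labels, reference) {
  needed <- c("spine", "vertebral_bodies", "trunk", "psoas",
              "compartment_muscle", "compartment_visceral",
              "compartment_subcutaneous")
  missing <- setdiff(needed, names(labels))
  if (length(missing) > 0) {
    stop("missing label map(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  purrr::imap(labels[needed], function(x, nm) {
    if (inherits(x, "ct_labelmap")) {
      check_alignment(x$geometry, reference, nm)
      x
    } else {
      load_labels(x, reference = reference)
    }
  })
}

#' Measure body composition for one subject
#'
#' The full measurement pipeline: ingest CT and label maps, reduce the spine
#' labels to the vertebral bodies, run spine QC, locate the target vertebra
#' by center of mass, confine the compartments to the trunk, threshold each
#' tissue by its HU window, and compute per-slice CSAs plus the
#' subject-level summary (single-slice reference CSA, vertebra-mean CSA, and
#' SMI when height is available). If the target vertebra is absent the run
#' returns with status `"qc_skip"` and writes nothing.
#'
#' @param config a [run_config()].
#' @return A list of class `measure_run` with `status` (`"ok"` or
#'   `"qc_skip"`), `subject`, `location`, `measurements` (tibble),
#'   `profiles` (long tibble), `qc` (list), and `files` when written.
#' @export
run_measure <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ct <- resolve_ct(config$ct)
  labels <- resolve_labels(config$labels, ct$geometry)

  qc <- list(hu = qc_hu(ct))
  dz <- ct$geometry$spacing[3]
  qc$slice_thickness_mm <- dz
  qc$slice_thickness_warning <- dz > 8

  bodies_map <- restrict_spine_to_bodies(labels$spine,
                                         labels$vertebral_bodies)
  qc$spine <- qc_spine(bodies_map)

  muscle <- confine_to_trunk(labels$compartment_muscle, labels$trunk)
  visceral <- confine_to_trunk(labels$compartment_visceral, labels$trunk)
  subq <- confine_to_trunk(labels$compartment_subcutaneous, labels$trunk)
  psoas <- confine_to_trunk(labels$psoas, labels$trunk)
  qc$psoas_outside_muscle <- sum(mask_array(psoas) & !mask_array(muscle))
  comp_masks <- list(compartment_muscle = muscle,
                     compartment_visceral = visceral,
                     compartment_subcutaneous = subq,
                     psoas = psoas)

  loc <- tryCatch(locate_vertebra(bodies_map, config$target_vertebra),
                  error = function(e) NULL)
  if (is.null(loc)) {
    return(structure(list(status = "qc_skip", subject = config$subject,
                          location = NULL, measurements = NULL,
                          profiles = NULL, qc = qc),
                     class = "measure_run"))
  }

  profiles <- purrr::pmap_dfr(config$tissues,
    function(name, compartment, hu_low, hu_high) {
      def <- tibble::tibble(name = name, compartment = compartment,
                            hu_low = hu_low, hu_high = hu_high)
      mask <- assign_tissue(ct, comp_masks[[compartment]], def)
      csa_per_slice(mask, subject = config$subject, tissue_name = name)
    })

  measurements <- profiles |>
    dplyr::group_by(.data$subject, .data$tissue) |>
    dplyr::group_modify(function(p, key) {
      p$subject <- key$subject; p$tissue <- key$tissue
      tibble::tibble(
        csa_reference_cm2 = csa_at_reference(p, loc),
        csa_vertebra_mean_cm2 = mean_csa_over_vertebra(p, loc)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      reference_vertebra = loc$vertebra,
      reference_slice = loc$center_slice,
      csa_cm2 = if (config$reference_mode == "center_slice") {
        .data$csa_reference_cm2
      } else {
        .data$csa_vertebra_mean_cm2
      },
      height_m = config$height_m,
      smi_cm2_m2 = ifelse(
        .data$tissue %in% c("SM_total", "SM_psoas") &
          is.finite(config$height_m),
        .data$csa_cm2 / config$height_m^2, NA_real_)
    )

  run <- structure(list(status = "ok", subject = config$subject,
                        location = loc, measurements = measurements,
                        profiles = profiles, qc = qc),
                   class = "measure_run")
  if (!is.null(config$output_dir)) {
    run$files <- write_results(profiles, measurements, config$output_dir)
    qc_path <- file.path(config$output_dir, "qc.json")
    jsonlite::write_json(qc_report_list(qc), qc_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    run$files[["qc"]] <- qc_path
  }
  run
}

qc_report_list <- function(qc) {
  list(
    hu_flagged = qc$hu$flagged,
    hu_below = qc$hu$n_below, hu_above = qc$hu$n_above,
    slice_thickness_mm = qc$slice_thickness_mm,
    slice_thickness_warning = qc$slice_thickness_warning,
    psoas_voxels_outside_muscle = qc$psoas_outside_muscle,
    spine_missing = as.list(qc$spine$missing_vertebrae),
    spine_order_violations = qc$spine$order_violations,
    spine_fragments = as.list(qc$spine$fragment_warnings)
  )
}

#' @export
print.measure_run <- function(x, ...) {
  cat("<measure_run> subject ", x$subject, ", status ", x$status, "\n",
      sep = "")
  if (x$status == "ok") print(x$measurements)
  invisible(x)
}

#' Validate measurements against manual readings, levels, and survival
#'
#' Dispatches to the statistics layer: per-tissue Bland-Altman agreement
#' when a manual table is given (columns `subject`, `tissue`, `csa_cm2`),
#' the vertebral-level mixed model when a long level table is given
#' (columns `patient`, `tissue`, `level`, `csa_cm2`), and the SMI prognosis
#' battery when survival records are given (columns `time_months`, `event`,
#' `smi`). Results are returned as a named list and, when `output_dir` is
#' set, written as JSON/CSV.
#'
#' @param measurements automated measurement tibble (as from [run_measure()],
#'   stacked over subjects) with columns `subject`, `tissue`, `csa_cm2`.
#' @param manual optional manual measurement table.
#' @param levels optional long per-level table.
#' @param survival optional survival table.
#' @param output_dir optional output directory.
#' @return A list of class `validate_run` with any of `agreement` (named by
#'   tissue), `level_models` (named by tissue), `survival`.
#' @export
run_validate <- function(measurements = NULL, manual = NULL, levels = NULL,
                         survival = NULL, output_dir = NULL) {
  out <- list()
  if (!is.null(manual)) {
    if (is.null(measurements)) {
      stop("schema violation: 'measurements' required with 'manual'",
           call. = FALSE)
    }
    check_columns(measurements, c("subject", "tissue", "csa_cm2"),
                  "measurements")
    check_columns(manual, c("subject", "tissue", "csa_cm2"), "manual")
    paired <- dplyr::inner_join(
      dplyr::select(manual, "subject", "tissue", manual_csa = "csa_cm2"),
      dplyr::select(measurements, "subject", "tissue", auto_csa = "csa_cm2"),
      by = c("subject", "tissue"))
    out$agreement <- paired |>
      split(paired$tissue) |>
      purrr::map(function(p) bland_altman(p, manual_csa, auto_csa))
  }
  if (!is.null(levels)) {
    check_columns(levels, c("patient", "level", "csa_cm2"), "levels")
    if (!"tissue" %in% names(levels)) levels$tissue <- "tissue"
    out$level_models <- levels |>
      split(levels$tissue) |>
      purrr::imap(function(d, nm) {
        fit_level_model(d, csa = csa_cm2, level = level, patient = patient,
                        tissue = nm)
      })
  }
  if (!is.null(survival)) {
    check_columns(survival, c("time_months", "event", "smi"), "survival")
    out$survival <- survival_analysis(survival)
  }
  out <- structure(out, class = "validate_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    summary <- validate_summary(out)
    jsonlite::write_json(summary, file.path(output_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(out$level_models)) {
      tab <- purrr::imap_dfr(out$level_models, function(f, nm) {
        dplyr::mutate(tidy(f), tissue = nm, .before = 1)
      })
      readr::write_csv(tab, file.path(output_dir, "level_model.csv"))
    }
  }
  out
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema violation in '", what, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

validate_summary <- function(x) {
  out <- list()
  if (!is.null(x$agreement)) {
    out$agreement <- purrr::map(x$agreement, function(b) {
      as.list(glance(b))
    })
  }
  if (!is.null(x$level_models)) {
    out$level_models <- purrr::map(x$level_models, function(f) {
      list(fixed = f$fixed, var_patient = f$var_patient,
           var_residual = f$var_residual)
    })
  }
  if (!is.null(x$survival)) out$survival <- as.list(glance(x$survival))
  out
}
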