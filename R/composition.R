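#' Tissue definitions: compartment plus HU window
#'
#' The pipeline distinguishes anatomical *compartments* (muscle, visceral,
#' subcutaneous; delimited by skin, fascia, bone and organs and produced by a
#' segmentation backend) from *tissue*, the HU-defined subset of a
#' compartment. The default windows are the established body-composition
#' thresholds: skeletal muscle [-29, 150] HU, adipose tissue [-190, -30] HU,
#' both closed intervals. IMAT (intermuscular adipose tissue) is the adipose
#' window applied inside the muscle compartment; it is reported but plays no
#' role in the skeletal muscle index.
#'
#' @param name optional character vector restricting the returned rows.
#' @return Tibble with columns `name`, `compartment`, `hu_low`, `hu_high`.
#' @export
tissue_definitions <- function(name = NULL) {
  defs <- tibble::tribble(
    ~name,       ~compartment,               ~hu_low, ~hu_high,
    "SM_total",  "compartment_muscle",          -29,     150,
    "SM_psoas",  "psoas",                       -29,     150,
    "VAT",       "compartment_visceral",       -190,     -30,
    "SAT",       "compartment_subcutaneous",   -190,     -30,
    "IMAT",      "compartment_muscle",         -190,     -30
  )
  if (!is.null(name)) {
    bad <- setdiff(name, defs$name)
    if (length(bad) > 0) {
      stop("unknown tissue definition(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    defs <- defs[match(name, defs$name), ]
  }
  defs
}

check_tissue_definition <- function(definition) {
  definition <- tibble::as_tibble(definition)
  stopifnot(nrow(definition) == 1,
            all(c("name", "compartment", "hu_low", "hu_high") %in%
                  names(definition)))
  if (definition$hu_low > definition$hu_high) {
    stop("invalid tissue definition: hu_low > hu_high", call. = FALSE)
  }
  definition
}

#' Assign tissue voxels by HU thresholding within a compartment
#'
#' A voxel belongs to the tissue iff it lies in the compartment mask and its
#' HU value is inside the closed interval `[hu_low, hu_high]`. Thresholding
#' is purely voxelwise: no connected-component filtering or island removal is
#' applied, so e.g. bowel content inside the visceral compartment that falls
#' in the adipose window is counted as VAT.
#'
#' @param ct a [ct_volume()].
#' @param compartment binary compartment mask aligned to `ct`.
#' @param definition one row of [tissue_definitions()] (or an equivalent
#'   list with `name`, `hu_low`, `hu_high`).
#' @return Binary [ct_labelmap()] named after the tissue.
#' @export
assign_tissue <- function(ct, compartment, definition) {
  stopifnot(inherits(ct, "ct_volume"))
  definition <- check_tissue_definition(definition)
  if (inherits(compartment, "ct_labelmap")) {
    check_alignment(compartment$geometry, ct$geometry, "compartment mask")
  }
  inside <- mask_array(compartment) &
    ct$data >= definition$hu_low & ct$data <= definition$hu_high
  as_mask(inside, ct$geometry, definition$name)
}

#' Cross-sectional area per axial slice
#'
#' For each axial slice, the tissue cross-sectional area is the voxel count
#' times the in-plane pixel area, converted from mm^2 to cm^2:
#' `csa_cm2 = n * dx * dy / 100`.
#'
#' @param tissue binary tissue mask ([ct_labelmap()]).
#' @param subject subject identifier stored in the profile (default `NA`).
#' @param tissue_name tissue name stored in the profile; defaults to the
#'   mask's vocabulary name.
#' @param slice_range optional inclusive 0-based `c(first, last)` slice
#'   range; default is the full volume.
#' @return Tibble (one row per slice, no duplicates) with columns `subject`,
#'   `tissue`, `slice_index` (0-based), `z_mm`, `csa_cm2`.
#' @export
csa_per_slice <- function(tissue, subject = NA_character_,
                          tissue_name = NULL, slice_range = NULL) {
  stopifnot(inherits(tissue, "ct_labelmap"))
  geom <- tissue$geometry
  nz <- geom$shape[3]
  if (is.null(slice_range)) slice_range <- c(0L, nz - 1L)
  stopifnot(length(slice_range) == 2, slice_range[1] >= 0,
            slice_range[2] < nz, slice_range[1] <= slice_range[2])
  if (is.null(tissue_name)) tissue_name <- names(tissue$vocabulary)[1]
  ks <- seq(slice_range[1], slice_range[2])
  counts <- apply(tissue$data[, , ks + 1, drop = FALSE] != 0L, 3, sum)
  pixel_cm2 <- geom$spacing[1] * geom$spacing[2] / 100
  tibble::tibble(
    subject = subject,
    tissue = tissue_name,
    slice_index = as.integer(ks),
    z_mm = slice_z(geom)[ks + 1],
    csa_cm2 = counts * pixel_cm2
  )
}

check_coverage <- function(profile, slices) {
  missing <- setdiff(slices, profile$slice_index)
  if (length(missing) > 0) {
    stop("coverage error: profile lacks slice(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(profile$slice_index) > 0) {
    stop("profile has duplicated slice indices", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean CSA over a vertebra's slice span
#'
#' Unweighted mean of the per-slice CSA over every slice intersected by the
#' vertebral body. Averaging across the whole vertebra damps the strong
#' slice-to-slice variability seen at a single level and is the basis of the
#' vertebra-mean skeletal muscle index.
#'
#' @param profile a per-slice CSA tibble from [csa_per_slice()].
#' @param location one-row tibble from [locate_vertebra()].
#' @return Mean CSA in cm^2.
#' @export
mean_csa_over_vertebra <- function(profile, location) {
  slices <- seq(location$slice_start, location$slice_end)
  check_coverage(profile, slices)
  mean(profile$csa_cm2[match(slices, profile$slice_index)])
}

#' CSA at the vertebra's center slice
#'
#' The single-slice reference measurement: the CSA on the axial slice at the
#' vertebra's center of mass, mirroring manual single-slice reading at L3.
#'
#' @inheritParams mean_csa_over_vertebra
#' @return CSA in cm^2 at `location$center_slice`.
#' @export
csa_at_reference <- function(profile, location) {
  check_coverage(profile, location$center_slice)
  profile$csa_cm2[match(location$center_slice, profile$slice_index)]
}

#' Skeletal muscle index
#'
#' SMI = muscle CSA divided by body height squared, in cm^2/m^2.
#'
#' @param csa muscle cross-sectional area in cm^2.
#' @param height_m body height in meters (> 0). Heights outside (0.5, 2.5) m
#'   are accepted with a QC warning.
#' @return SMI in cm^2/m^2 (vectorized).
#' @export
smi <- function(csa, height_m) {
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    stop("domain error: height must be positive", call. = FALSE)
  }
  if (any(height_m <= 0.5 | height_m >= 2.5)) {
    warning("QC: height outside the plausible (0.5, 2.5) m range")
  }
  csa / height_m^2
}

#' Per-slice CSA relative to the vertebra center
#'
#' Expresses each slice's CSA as a percentage of the CSA at the vertebra's
#' center slice, indexed by the signed slice offset from that center:
#' negative offsets are inferior (below the center), positive offsets
#' superior. The center itself is 100% by construction.
#'
#' @inheritParams mean_csa_over_vertebra
#' @return Tibble with columns `subject`, `tissue`, `offset` (signed
#'   slices), `slice_index`, `z_mm`, `csa_cm2`, `pct`.
#' @export
relative_profile <- function(profile, location) {
  ref <- csa_at_reference(profile, location)
  if (!is.finite(ref) || ref <= 0) {
    stop("undefined-reference error: CSA at the center slice is zero",
         call. = FALSE)
  }
  dplyr::mutate(profile,
                offset = .data$slice_index - location$center_slice,
                pct = 100 * .data$csa_cm2 / ref,
                .after = "tissue")
}
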