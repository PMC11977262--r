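#' Load a CT volume from NIfTI or a DICOM series
#'
#' Reads a NIfTI file (or a directory holding exactly one DICOM series,
#' converted on ingest) and returns the volume in canonical RAS orientation:
#' axes ordered right-anterior-superior, so slice index increases toward the
#' head. Reorientation permutes and flips the voxel grid only; the world
#' coordinates of every voxel are unchanged. For DICOM input the rescale
#' slope/intercept are applied so voxel values are HU.
#'
#' @param path a NIfTI file (`.nii` / `.nii.gz`) or a directory containing a
#'   single DICOM series.
#' @return A [ct_volume()]; the orientation string of the file as stored is
#'   kept in attribute `original_orientation` for round-tripping.
#' @export
load_ct <- function(path) {
  if (dir.exists(path)) {
    path <- dicom_to_nifti(path)
    on.exit(unlink(path), add = TRUE)
  }
  if (!file.exists(path)) {
    stop("format error: cannot read '", path, "'", call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("format error: ", conditionMessage(e), call. = FALSE)
                  })
  orig <- canonical_nifti_check(img)
  RNifti::orientation(img) <- "RAS"
  geom <- geometry_from_nifti(img)
  ct <- ct_volume(array(as.numeric(img), dim = dim(img)), geom)
  attr(ct, "original_orientation") <- orig
  ct
}

# reject images whose header carries no usable spatial transform
canonical_nifti_check <- function(img) {
  xf <- RNifti::xform(img)
  code <- attr(xf, "code")
  if (is.null(code) || code == 0L) {
    stop("metadata error: image carries no qform/sform, ",
         "preventing accurate image orientation", call. = FALSE)
  }
  det_a <- det(unclass(xf)[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop("metadata error: affine is not invertible", call. = FALSE)
  }
  RNifti::orientation(img)
}

geometry_from_nifti <- function(img) {
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  sp <- abs(RNifti::pixdim(img))[1:3]
  ct_geometry(dim(img)[1:3], sp, aff, axial_axis = 3L)
}

# Convert a directory holding one DICOM series to a temporary NIfTI file via
# SimpleITK (python); applies rescale slope/intercept, refuses ambiguous
# multi-series directories listing the series UIDs found.
dicom_to_nifti <- function(dir) {
  out <- tempfile(fileext = ".nii.gz")
  script <- paste(
    "import sys, SimpleITK as sitk",
    "d, out = sys.argv[1], sys.argv[2]",
    "r = sitk.ImageSeriesReader()",
    "ids = r.GetGDCMSeriesIDs(d)",
    "if len(ids) == 0: sys.exit('no DICOM series found')",
    "if len(ids) > 1: sys.exit('AMBIGUOUS:' + ','.join(ids))",
    "r.SetFileNames(r.GetGDCMSeriesFileNames(d, ids[0]))",
    "sitk.WriteImage(r.Execute(), out)",
    sep = "\n")
  res <- suppressWarnings(system2("python", c("-c", shQuote(script),
                                              shQuote(dir), shQuote(out)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    msg <- paste(res, collapse = " ")
    if (grepl("AMBIGUOUS:", msg)) {
      stop("ambiguity error: directory contains multiple DICOM series: ",
           sub(".*AMBIGUOUS:", "", msg), call. = FALSE)
    }
    stop("format error: DICOM ingest failed: ", msg, call. = FALSE)
  }
  out
}

#' Load a label map aligned to a reference geometry
#'
#' Reads an integer NIfTI label volume, canonicalizes it to RAS, and checks
#' that its geometry matches `reference` within tolerance. A geometry
#' mismatch is an error: the loader never resamples, because voxel-grid
#' alignment between CT and labels is the segmentation backend's contract.
#'
#' @param path NIfTI file of integer labels.
#' @param vocabulary named integer vector mapping label name to code
#'   (default [default_vocabulary()]).
#' @param reference a [ct_geometry()] the labels must align to, or `NULL` to
#'   accept the file's own geometry.
#' @param tol alignment tolerance in mm (default 1e-4).
#' @return A [ct_labelmap()].
#' @export
load_labels <- function(path, vocabulary = default_vocabulary(),
                        reference = NULL, tol = 1e-4) {
  if (!file.exists(path)) {
    stop("format error: cannot read '", path, "'", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  canonical_nifti_check(img)
  RNifti::orientation(img) <- "RAS"
  geom <- geometry_from_nifti(img)
  dat <- array(as.numeric(img), dim = dim(img))
  if (any(dat != round(dat))) {
    stop("format error: label volume is not integer-valued", call. = FALSE)
  }
  if (!is.null(reference)) check_alignment(geom, reference)
  ct_labelmap(dat, if (is.null(reference)) geom else reference, vocabulary)
}

#' Write a CT volume or label map to NIfTI
#'
#' Volumes are written in the canonical RAS orientation with the geometry's
#' affine stored in both qform and sform; labels are written as integers.
#'
#' @param x a [ct_volume()] or [ct_labelmap()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, c("ct_volume", "ct_labelmap")))
  dat <- x$data
  if (inherits(x, "ct_labelmap")) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$geometry$spacing
  RNifti::qform(img) <- structure(x$geometry$affine, code = 2L)
  RNifti::sform(img) <- structure(x$geometry$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write slice profiles and subject summaries to disk
#'
#' Serializes the pipeline's quantitative products: a long-format CSV of
#' per-slice cross-sectional areas (columns `subject`, `tissue`,
#' `slice_index`, `z_mm`, `csa_cm2`), a per-subject measurement CSV, and a
#' JSON summary. The schema is stable; an empty profile collection yields a
#' header-only CSV.
#'
#' @param profiles tibble of per-slice CSAs (may have zero rows).
#' @param summaries tibble of per-subject measurements, or `NULL`.
#' @param dir output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(profiles, summaries = NULL, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create '", dir, "'", call. = FALSE)
  }
  cols <- c("subject", "tissue", "slice_index", "z_mm", "csa_cm2")
  if (is.null(profiles) || nrow(profiles) == 0) {
    profiles <- tibble::as_tibble(stats::setNames(
      list(character(), character(), integer(), double(), double()), cols))
  }
  profiles <- dplyr::select(profiles, dplyr::all_of(cols))
  files <- c(profiles = file.path(dir, "profiles.csv"))
  readr::write_csv(profiles, files[["profiles"]])
  if (!is.null(summaries)) {
    files[["measurements"]] <- file.path(dir, "measurements.csv")
    readr::write_csv(summaries, files[["measurements"]])
    files[["summary"]] <- file.path(dir, "summary.json")
    jsonlite::write_json(split(summaries, summaries$subject),
                         files[["summary"]], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(files)
}
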