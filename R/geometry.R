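#' Image geometry for CT volumes and label maps
#'
#' A `ct_geometry` ties a voxel grid to world (scanner) coordinates: the grid
#' shape, the voxel spacing in mm, and a 4x4 voxel-index-to-world-mm affine
#' (NIfTI convention, 0-based voxel indices). After canonicalization the axes
#' are ordered right-anterior-superior (RAS), so the third axis is the
#' axial (superior-inferior) axis and slice index increases toward superior.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, mm per voxel along each axis;
#'   all components must be strictly positive.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#' @param axial_axis index of the superior-inferior axis; always 3 after
#'   canonicalization.
#' @return An object of class `ct_geometry`.
#' @export
ct_geometry <- function(shape, spacing, affine, axial_axis = 3L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) {
    stop("all spacing components must be strictly positive", call. = FALSE)
  }
  affine <- unclass(affine)[1:4, 1:4]
  attributes(affine) <- list(dim = c(4L, 4L))
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop("metadata error: affine is missing or not invertible", call. = FALSE)
  }
  structure(
    list(shape = shape, spacing = spacing, affine = affine,
         axial_axis = as.integer(axial_axis)),
    class = "ct_geometry"
  )
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat("<ct_geometry> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Compare two geometries within tolerance
#'
#' Shapes must match exactly; spacing and affine entries must agree within
#' `tol` mm. Used by the loaders to refuse label maps that are not aligned to
#' their CT (no silent resampling).
#'
#' @param a,b `ct_geometry` objects.
#' @param tol absolute tolerance in mm (default 1e-4).
#' @return `TRUE` or `FALSE`.
#' @export
geometry_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Map voxel indices to world coordinates
#'
#' @param geometry a `ct_geometry`.
#' @param ijk matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(geometry, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk, 1)
  out <- h %*% t(geometry$affine)
  out[, 1:3, drop = FALSE]
}

# world z (mm) of each axial slice plane, slice index 0-based
slice_z <- function(geometry) {
  k <- seq_len(geometry$shape[3]) - 1
  geometry$affine[3, 3] * k + geometry$affine[3, 4]
}

stop_alignment <- function(what = "label map") {
  stop("alignment error: ", what,
       " geometry does not match the reference CT grid ",
       "(this pipeline never resamples; alignment is the backend's contract)",
       call. = FALSE)
}

check_alignment <- function(a, b, what = "label map", tol = 1e-4) {
  if (!geometry_equal(a, b, tol = tol)) stop_alignment(what)
  invisible(TRUE)
}
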