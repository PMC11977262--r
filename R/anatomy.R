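#' Reduce spine labels to the vertebral bodies
#'
#' Vertebra labels from a whole-spine segmentation include the vertebral arch
#' and spinous/transverse processes, whose voxels would drag the center of
#' mass posteriorly and smear the axial extent. Intersecting with a
#' vertebral-bodies mask keeps a voxel's vertebra label iff it also lies in
#' the bodies mask; everything else becomes background. The vocabulary is
#' preserved.
#'
#' @param spine a [ct_labelmap()] carrying vertebra labels.
#' @param bodies a binary mask ([ct_labelmap()] or logical array) on the same
#'   geometry.
#' @return A [ct_labelmap()] restricted to the vertebral bodies.
#' @export
restrict_spine_to_bodies <- function(spine, bodies) {
  stopifnot(inherits(spine, "ct_labelmap"))
  if (inherits(bodies, "ct_labelmap")) {
    check_alignment(bodies$geometry, spine$geometry, "vertebral-bodies mask")
  }
  keep <- mask_array(bodies)
  out <- spine$data
  out[!keep] <- 0L
  ct_labelmap(out, spine$geometry, spine$vocabulary)
}

#' Confine a compartment mask to the body trunk
#'
#' Voxelwise intersection of a compartment mask with the trunk mask, removing
#' extremities (e.g. arms resting on the abdomen), head and neck that a
#' segmentation backend may have included in the compartment.
#'
#' @param compartment binary mask ([ct_labelmap()]).
#' @param trunk binary trunk mask on the same geometry.
#' @return A binary [ct_labelmap()] with the compartment's vocabulary.
#' @export
confine_to_trunk <- function(compartment, trunk) {
  stopifnot(inherits(compartment, "ct_labelmap"))
  if (inherits(trunk, "ct_labelmap")) {
    check_alignment(trunk$geometry, compartment$geometry, "trunk mask")
  }
  keep <- mask_array(trunk)
  out <- compartment$data
  out[!keep] <- 0L
  ct_labelmap(out, compartment$geometry, compartment$vocabulary)
}

#' Locate a vertebra along the axial axis
#'
#' The vertebra's center is the unweighted center of mass of its body voxels,
#' computed in world mm: `center_z_mm` is the mean world z of the voxels, and
#' `center_slice` is the axial slice whose plane lies nearest that z. When
#' the center falls exactly between two slice planes the inferior slice is
#' chosen. The slice span is the inclusive 0-based index range of slices
#' containing at least one body voxel of the vertebra.
#'
#' @param bodies_labelmap a [ct_labelmap()] of vertebra labels restricted to
#'   the vertebral bodies (see [restrict_spine_to_bodies()]).
#' @param vertebra label name, e.g. `"vertebra_L3"`.
#' @return One-row tibble with columns `vertebra`, `center_slice`,
#'   `center_z_mm`, `slice_start`, `slice_end`, `n_voxels`.
#' @export
locate_vertebra <- function(bodies_labelmap, vertebra) {
  stopifnot(inherits(bodies_labelmap, "ct_labelmap"))
  voc <- bodies_labelmap$vocabulary
  if (!vertebra %in% names(voc)) {
    stop("not-found error: '", vertebra, "' is not in the vocabulary",
         call. = FALSE)
  }
  idx <- which(bodies_labelmap$data == voc[[vertebra]], arr.ind = TRUE)
  if (nrow(idx) == 0) {
    qc <- qc_spine(bodies_labelmap)
    stop("not-found error: no voxels labelled '", vertebra, "'",
         if (length(qc$missing_vertebrae) > 0) {
           paste0(" (spine QC missing: ",
                  paste(qc$missing_vertebrae, collapse = ", "), ")")
         } else "",
         call. = FALSE)
  }
  geom <- bodies_labelmap$geometry
  zw <- voxel_to_world(geom, idx - 1)[, 3]
  center_z <- mean(zw)
  zs <- slice_z(geom)
  d <- abs(zs - center_z)
  # ties resolve to the inferior slice: z increases with slice index in RAS
  center_slice <- min(which(d <= min(d) + 1e-9)) - 1L
  span <- range(idx[, 3] - 1L)
  center_slice <- min(max(center_slice, span[1]), span[2])
  tibble::tibble(
    vertebra = vertebra,
    center_slice = as.integer(center_slice),
    center_z_mm = center_z,
    slice_start = as.integer(span[1]),
    slice_end = as.integer(span[2]),
    n_voxels = nrow(idx)
  )
}

#' Locate every vertebra present in a bodies label map
#'
#' @param bodies_labelmap a [ct_labelmap()] of vertebral bodies.
#' @return Tibble with one row per vertebra present (cranial to caudal),
#'   columns as in [locate_vertebra()].
#' @export
locate_vertebrae <- function(bodies_labelmap) {
  voc <- bodies_labelmap$vocabulary
  present <- names(voc)[voc %in% setdiff(unique(as.integer(bodies_labelmap$data)), 0L)]
  present <- intersect(vertebra_order(), present)
  purrr::map_dfr(present, function(v) locate_vertebra(bodies_labelmap, v))
}

#' Spine quality-control report
#'
#' Surfaces (does not fix) the failure modes automated vertebra labelling is
#' known for: vertebrae missing between the most cranial and most caudal
#' label present, centers of mass that are not monotonically ordered along z
#' (e.g. swapped labels after lumbarization/sacralization), and bodies whose
#' axial extent exceeds `fragment_factor` times the median extent (label
#' fragments merged across levels).
#'
#' @param bodies_labelmap a [ct_labelmap()] of vertebral bodies.
#' @param fragment_factor extent multiple beyond which a vertebra is flagged
#'   as fragmented (default 2.5).
#' @return A list of class `spine_qc` with `missing_vertebrae`,
#'   `order_violations` (tibble of label pairs), `fragment_warnings`, and
#'   `locations` (tibble from [locate_vertebrae()]).
#' @export
qc_spine <- function(bodies_labelmap, fragment_factor = 2.5) {
  loc <- locate_vertebrae(bodies_labelmap)
  ord <- vertebra_order()
  missing <- character()
  violations <- tibble::tibble(cranial = character(), caudal = character())
  fragments <- character()
  if (nrow(loc) > 0) {
    pos <- match(loc$vertebra, ord)
    expected <- ord[seq(min(pos), max(pos))]
    missing <- setdiff(expected, loc$vertebra)
    if (nrow(loc) > 1) {
      # cranial-to-caudal ordering must be strictly decreasing in world z
      dz <- diff(loc$center_z_mm)
      bad <- which(dz >= 0)
      violations <- tibble::tibble(cranial = loc$vertebra[bad],
                                   caudal = loc$vertebra[bad + 1])
      dzmm <- abs(bodies_labelmap$geometry$affine[3, 3])
      extent <- (loc$slice_end - loc$slice_start + 1) * dzmm
      fragments <- loc$vertebra[extent > fragment_factor * stats::median(extent)]
    }
  }
  structure(list(missing_vertebrae = missing,
                 order_violations = violations,
                 fragment_warnings = fragments,
                 locations = loc),
            class = "spine_qc")
}

#' @export
print.spine_qc <- function(x, ...) {
  cat("<spine_qc> ", nrow(x$locations), " vertebrae located\n", sep = "")
  if (qc_clean(x)) {
    cat("  clean: no missing labels, order violations or fragments\n")
  } else {
    if (length(x$missing_vertebrae) > 0) {
      cat("  missing:", paste(x$missing_vertebrae, collapse = ", "), "\n")
    }
    if (nrow(x$order_violations) > 0) {
      cat("  order violations:",
          paste(x$order_violations$cranial, x$order_violations$caudal,
                sep = "/", collapse = ", "), "\n")
    }
    if (length(x$fragment_warnings) > 0) {
      cat("  fragments:", paste(x$fragment_warnings, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Is a spine QC report clean?
#'
#' @param report a `spine_qc` report.
#' @return `TRUE` iff no missing vertebrae, order violations or fragments.
#' @export
qc_clean <- function(report) {
  length(report$missing_vertebrae) == 0 &&
    nrow(report$order_violations) == 0 &&
    length(report$fragment_warnings) == 0
}
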