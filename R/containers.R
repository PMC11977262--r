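#' CT volume container
#'
#' A calibrated CT volume: a 3-D grid of Hounsfield Units (HU) plus its
#' geometry. Data are held as doubles regardless of the on-disk integer type.
#' Values outside the usual 12-bit CT range [-1024, 3071] are allowed but are
#' flagged by [qc_hu()].
#'
#' @param data 3-D numeric array of HU values.
#' @param geometry a [ct_geometry()] whose shape equals `dim(data)`.
#' @return An object of class `ct_volume` with elements `data` and `geometry`.
#' @export
ct_volume <- function(data, geometry) {
  stopifnot(inherits(geometry, "ct_geometry"))
  if (!identical(dim(data), NULL) && length(dim(data)) != 3L) {
    stop("CT data must be a 3-D array", call. = FALSE)
  }
  if (!identical(as.integer(dim(data)), geometry$shape)) {
    stop("data shape does not equal geometry shape", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("HU values must be finite", call. = FALSE)
  }
  storage.mode(data) <- "double"
  structure(list(data = data, geometry = geometry), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(x$geometry$shape, collapse = " x "),
      " voxels, HU range [", round(min(x$data)), ", ", round(max(x$data)),
      "]\n", sep = "")
  invisible(x)
}

#' Label map container
#'
#' An integer label grid aligned to a CT volume, with a named vocabulary
#' mapping label names to integer codes. Every nonzero code present in the
#' data must appear in the vocabulary. Binary masks are label maps with a
#' single-entry vocabulary.
#'
#' @param data 3-D array of non-negative integer labels.
#' @param geometry a [ct_geometry()].
#' @param vocabulary named integer vector mapping label name to code.
#' @return An object of class `ct_labelmap`.
#' @export
ct_labelmap <- function(data, geometry, vocabulary) {
  stopifnot(inherits(geometry, "ct_geometry"))
  if (!identical(as.integer(dim(data)), geometry$shape)) {
    stop("data shape does not equal geometry shape", call. = FALSE)
  }
  if (any(data < 0) || any(data != round(data))) {
    stop("format error: label data must be non-negative integers",
         call. = FALSE)
  }
  vocabulary <- vapply(vocabulary, as.integer, integer(1))
  present <- setdiff(unique(as.integer(data)), 0L)
  unknown <- setdiff(present, vocabulary)
  if (length(unknown) > 0) {
    stop("vocabulary error: codes present in data but absent from vocabulary: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  storage.mode(data) <- "integer"
  structure(list(data = data, geometry = geometry, vocabulary = vocabulary),
            class = "ct_labelmap")
}

#' @export
print.ct_labelmap <- function(x, ...) {
  nfg <- sum(x$data != 0L)
  cat("<ct_labelmap> ", paste(x$geometry$shape, collapse = " x "),
      " voxels, ", nfg, " foreground, ", length(x$vocabulary),
      " vocabulary entries\n", sep = "")
  invisible(x)
}

#' Default anatomical label vocabulary
#'
#' Names and codes for the structures the pipeline consumes: vertebrae T1-L5,
#' S1 and sacrum, the three tissue compartments (muscle, visceral,
#' subcutaneous), the body trunk, the psoas muscle, and the vertebral-bodies
#' mask.
#'
#' @return Named integer vector.
#' @export
default_vocabulary <- function() {
  v <- c(
    stats::setNames(1:12, paste0("vertebra_T", 1:12)),
    stats::setNames(13:17, paste0("vertebra_L", 1:5)),
    vertebra_S1 = 18L, sacrum = 19L,
    compartment_muscle = 20L, compartment_visceral = 21L,
    compartment_subcutaneous = 22L,
    trunk = 23L, psoas = 24L, vertebral_bodies = 25L
  )
  vapply(v, as.integer, integer(1))
}

# canonical caudal ordering of vertebra labels (cranial first)
vertebra_order <- function() {
  c(paste0("vertebra_T", 1:12), paste0("vertebra_L", 1:5),
    "vertebra_S1", "sacrum")
}

# coerce a ct_labelmap (or logical/numeric array) to a logical mask array
mask_array <- function(x) {
  if (inherits(x, "ct_labelmap")) return(x$data != 0L)
  if (is.array(x)) return(x != 0)
  stop("expected a ct_labelmap or array mask", call. = FALSE)
}

# wrap a logical array as a single-label mask on a geometry
as_mask <- function(data, geometry, name = "mask") {
  ct_labelmap(array(as.integer(data != 0), dim = geometry$shape), geometry,
              stats::setNames(1L, name))
}

#' Flag out-of-range HU values
#'
#' CT attenuation is calibrated so that water is 0 HU and air about -1000 HU;
#' standard 12-bit reconstructions span [-1024, 3071]. Values outside that
#' interval are legal in the container but usually indicate ingest problems,
#' so they are surfaced as a QC flag rather than an error.
#'
#' @param ct a [ct_volume()].
#' @return A list with `n_below`, `n_above` and logical `flagged`.
#' @export
qc_hu <- function(ct) {
  stopifnot(inherits(ct, "ct_volume"))
  n_below <- sum(ct$data < -1024)
  n_above <- sum(ct$data > 3071)
  list(n_below = n_below, n_above = n_above,
       flagged = (n_below + n_above) > 0)
}
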