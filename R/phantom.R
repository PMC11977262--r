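#' Specification of a synthetic abdominal CT phantom
#'
#' The phantom emulates the structures the measurement pipeline consumes: an
#' elliptical body trunk with a subcutaneous fat ring, an annular
#' abdominal-wall muscle band, two psoas muscles, a stack of vertebral bodies
#' with optional posterior spinous processes, a visceral interior, a small
#' intramuscular fat inclusion (IMAT), an adipose-range "bowel content" blob
#' inside the visceral compartment, and optional out-of-trunk "arm" blobs
#' reproducing the included-extremities failure mode. All primitives are
#' ellipses/annuli/cylinders rasterized by voxel-center membership, so
#' analytic areas are available for auditing.
#'
#' Default HU means sit strictly inside the tissue HU windows (muscle 50,
#' fat -100), so with `noise_sd = 0` thresholding recovers every compartment
#' voxel exactly. The default bowel mean of -50 HU lies inside the adipose
#' window, deliberately reproducing the bowel-content misclassification of
#' purely HU-based VAT measurement.
#'
#' @param shape,spacing voxel grid (default 96 x 96 x 56 voxels at
#'   2 x 2 x 2.5 mm).
#' @param trunk_semiaxes in-plane trunk ellipse semi-axes in mm.
#' @param sat_thickness,muscle_thickness thickness in mm of the subcutaneous
#'   ring and of the muscle band inside it.
#' @param psoas_radius,psoas_offset psoas circle radius (mm) and center
#'   offset `c(|x|, y)` from the trunk center; two mirror-image circles.
#' @param psoas_taper radius decrease in mm per slice moving superiorly
#'   (0 = uniform cylinders).
#' @param vertebrae character vector of vertebra labels, cranial to caudal.
#' @param vertebra_height,vertebra_gap,vertebra_radius vertebral body height,
#'   inter-body gap and body radius, mm.
#' @param spinous_process if `TRUE`, a posterior process is attached to each
#'   vertebra (part of the spine label, outside the bodies mask).
#' @param imat_radius radius of the intramuscular fat inclusion (0 disables).
#' @param bowel_radius radius of the bowel-content blob (0 disables).
#' @param arms if `TRUE`, add muscle-HU blobs outside the trunk that the
#'   "backend" wrongly includes in the muscle compartment.
#' @param arm_offset,arm_radius arm blob center |x| offset and radius, mm.
#' @param anomalies list with optional elements `missing` (labels to delete),
#'   `swap` (two labels whose voxels are exchanged), `fragment` (label that
#'   additionally receives a detached fragment on the most superior
#'   unlabelled slices, inflating its apparent axial extent).
#' @param hu_means named HU means for `muscle`, `fat`, `bone`, `air`,
#'   `bowel`.
#' @param noise_sd Gaussian HU noise standard deviation.
#' @param seed integer seed making generation deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 56L),
                         spacing = c(2, 2, 2.5),
                         trunk_semiaxes = c(75, 65),
                         sat_thickness = 14,
                         muscle_thickness = 11,
                         psoas_radius = 12,
                         psoas_offset = c(22, -4),
                         psoas_taper = 0,
                         vertebrae = paste0("vertebra_L", 1:5),
                         vertebra_height = 20,
                         vertebra_gap = 4,
                         vertebra_radius = 14,
                         spine_center_y = -24,
                         spinous_process = TRUE,
                         imat_radius = 4,
                         bowel_radius = 8,
                         arms = FALSE,
                         arm_offset = 85,
                         arm_radius = 6,
                         anomalies = list(),
                         hu_means = c(muscle = 50, fat = -100, bone = 400,
                                      air = -1000, bowel = -50),
                         noise_sd = 0,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               trunk_semiaxes = trunk_semiaxes, sat_thickness = sat_thickness,
               muscle_thickness = muscle_thickness,
               psoas_radius = psoas_radius, psoas_offset = psoas_offset,
               psoas_taper = psoas_taper, vertebrae = vertebrae,
               vertebra_height = vertebra_height, vertebra_gap = vertebra_gap,
               vertebra_radius = vertebra_radius,
               spine_center_y = spine_center_y,
               spinous_process = spinous_process, imat_radius = imat_radius,
               bowel_radius = bowel_radius, arms = arms,
               arm_offset = arm_offset, arm_radius = arm_radius,
               anomalies = anomalies, hu_means = hu_means,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  half_x <- spec$shape[1] * spec$spacing[1] / 2
  half_y <- spec$shape[2] * spec$spacing[2] / 2
  if (spec$trunk_semiaxes[1] >= half_x || spec$trunk_semiaxes[2] >= half_y) {
    stop("spec error: trunk ellipse does not fit the grid", call. = FALSE)
  }
  if (spec$sat_thickness + spec$muscle_thickness >=
      min(spec$trunk_semiaxes)) {
    stop("spec error: SAT ring plus muscle band exceed the trunk",
         call. = FALSE)
  }
  n <- length(spec$vertebrae)
  z_extent <- spec$shape[3] * spec$spacing[3]
  z_need <- spine_z_bottom(spec) +
    n * spec$vertebra_height + (n - 1) * spec$vertebra_gap
  if (z_need > z_extent) {
    stop("spec error: vertebra stack exceeds the axial extent", call. = FALSE)
  }
  if (spec$arms && spec$arm_offset + spec$arm_radius >= half_x) {
    stop("spec error: arm blobs do not fit the grid", call. = FALSE)
  }
  bad <- setdiff(unlist(spec$anomalies[c("missing", "swap", "fragment")]),
                 spec$vertebrae)
  if (length(bad) > 0) {
    stop("spec error: anomaly refers to absent vertebra ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

# z (mm) of the bottom of the most caudal vertebral body
spine_z_bottom <- function(spec) 4 * spec$spacing[3]

phantom_geometry <- function(spec) {
  sp <- spec$spacing
  aff <- diag(4)
  aff[1, 1] <- sp[1]; aff[2, 2] <- sp[2]; aff[3, 3] <- sp[3]
  aff[1, 4] <- -(spec$shape[1] - 1) / 2 * sp[1]
  aff[2, 4] <- -(spec$shape[2] - 1) / 2 * sp[2]
  aff[3, 4] <- 0
  ct_geometry(spec$shape, sp, aff)
}

# inclusive 0-based slice range whose voxel centers fall in [z_lo, z_hi)
slab_slices <- function(geometry, z_lo, z_hi) {
  zs <- slice_z(geometry)
  which(zs >= z_lo - 1e-9 & zs < z_hi - 1e-9) - 1L
}

# per-vertebra z slab, cranial-to-caudal input order, caudal-most at bottom
vertebra_slabs <- function(spec) {
  n <- length(spec$vertebrae)
  z0 <- spine_z_bottom(spec)
  pitch <- spec$vertebra_height + spec$vertebra_gap
  tibble::tibble(
    vertebra = spec$vertebrae,
    z_lo = z0 + (n - seq_len(n)) * pitch,
    z_hi = z0 + (n - seq_len(n)) * pitch + spec$vertebra_height
  )
}

in_ellipse <- function(X, Y, cx, cy, a, b) {
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
}

#' Generate a synthetic CT phantom with labels and ground truth
#'
#' Rasterizes the [phantom_spec()] into an HU volume, the full set of label
#' maps the pipeline consumes (spine, vertebral bodies, trunk, psoas, and the
#' three compartments), and a ground-truth table of per-slice per-tissue
#' voxel counts and CSAs plus per-vertebra center/span. Generation is
#' deterministic given the spec's seed. By construction the label maps obey
#' the pipeline's containment assumptions (psoas inside the muscle
#' compartment, bodies inside spine labels, everything inside the trunk)
#' unless a failure mode (`arms`, `anomalies`) is explicitly requested.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `ct_phantom` with elements `ct` ([ct_volume()]),
#'   `labels` (named list of [ct_labelmap()]), `truth` (list of tibbles
#'   `csa`, `vertebrae`, `analytic`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  xs <- (seq_len(nx) - 1) * spec$spacing[1] + geom$affine[1, 4]
  ys <- (seq_len(ny) - 1) * spec$spacing[2] + geom$affine[2, 4]
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)

  a_t <- spec$trunk_semiaxes[1]; b_t <- spec$trunk_semiaxes[2]
  a_i <- a_t - spec$sat_thickness; b_i <- b_t - spec$sat_thickness
  a_m <- a_i - spec$muscle_thickness; b_m <- b_i - spec$muscle_thickness

  trunk2d <- in_ellipse(X, Y, 0, 0, a_t, b_t)
  inner2d <- in_ellipse(X, Y, 0, 0, a_i, b_i)
  core2d <- in_ellipse(X, Y, 0, 0, a_m, b_m)
  sat2d <- trunk2d & !inner2d
  band2d <- inner2d & !core2d

  sy <- spec$spine_center_y
  spine2d <- in_ellipse(X, Y, 0, sy, spec$vertebra_radius,
                        spec$vertebra_radius)
  proc2d <- if (spec$spinous_process) {
    abs(X) <= 3 & Y >= sy - spec$vertebra_radius - 12 &
      Y <= sy - spec$vertebra_radius + 2
  } else {
    matrix(FALSE, nx, ny)
  }
  imat2d <- if (spec$imat_radius > 0) {
    in_ellipse(X, Y, 0, (b_i + b_m) / 2, spec$imat_radius, spec$imat_radius)
  } else matrix(FALSE, nx, ny)
  bowel2d <- if (spec$bowel_radius > 0) {
    in_ellipse(X, Y, 0, 18, spec$bowel_radius, spec$bowel_radius)
  } else matrix(FALSE, nx, ny)
  arms2d <- if (spec$arms) {
    in_ellipse(X, Y, -spec$arm_offset, 0, spec$arm_radius, spec$arm_radius) |
      in_ellipse(X, Y, spec$arm_offset, 0, spec$arm_radius, spec$arm_radius)
  } else matrix(FALSE, nx, ny)

  voc <- default_vocabulary()
  slabs <- vertebra_slabs(spec)
  vert_slices <- lapply(seq_len(nrow(slabs)), function(i) {
    slab_slices(geom, slabs$z_lo[i], slabs$z_hi[i])
  })

  spine3d <- array(0L, spec$shape)
  bodies3d <- array(FALSE, spec$shape)
  psoas3d <- array(FALSE, spec$shape)
  mat3d <- array("air", spec$shape)

  for (k in seq_len(nz) - 1L) {
    m <- matrix("air", nx, ny)
    m[sat2d] <- "fat"
    m[core2d] <- "fat"                         # visceral interior
    m[band2d] <- "muscle"
    m[imat2d] <- "fat"
    rk <- spec$psoas_radius - spec$psoas_taper * k
    ps2d <- matrix(FALSE, nx, ny)
    if (rk > 0) {
      ps2d <- in_ellipse(X, Y, -spec$psoas_offset[1], spec$psoas_offset[2],
                         rk, rk) |
        in_ellipse(X, Y, spec$psoas_offset[1], spec$psoas_offset[2], rk, rk)
    }
    m[ps2d] <- "muscle"
    m[bowel2d] <- "bowel"
    if (spec$arms) m[arms2d] <- "muscle"
    iv <- which(vapply(vert_slices, function(s) k %in% s, logical(1)))
    spinevox2d <- matrix(FALSE, nx, ny)
    if (length(iv) == 1) {
      spinevox2d <- spine2d | proc2d
      m[spinevox2d] <- "bone"
      spine3d[, , k + 1][spinevox2d] <- voc[[slabs$vertebra[iv]]]
      bodies3d[, , k + 1] <- spine2d
    }
    psoas3d[, , k + 1] <- ps2d & !spinevox2d
    mat3d[, , k + 1] <- m
  }

  # anomalies act on the spine / bodies labels only (the CT is unchanged)
  an <- spec$anomalies
  if (!is.null(an$missing)) {
    for (v in an$missing) {
      drop <- spine3d == voc[[v]]
      spine3d[drop] <- 0L
      bodies3d[drop] <- FALSE
    }
  }
  if (!is.null(an$swap)) {
    c1 <- voc[[an$swap[1]]]; c2 <- voc[[an$swap[2]]]
    i1 <- spine3d == c1; i2 <- spine3d == c2
    spine3d[i1] <- c2; spine3d[i2] <- c1
  }
  if (!is.null(an$fragment)) {
    # detached far-away fragment: the label reappears on the most superior
    # unlabelled slices, inflating its apparent axial extent
    labelled <- apply(spine3d > 0L, 3, any)
    frag_k <- utils::tail(which(!labelled), 3) - 1L
    for (k in frag_k) {
      spine3d[, , k + 1][spine2d] <- voc[[an$fragment]]
      bodies3d[, , k + 1] <- bodies3d[, , k + 1] | spine2d
    }
  }

  spinevox3d <- spine3d > 0L
  muscle3d <- array(band2d | imat2d, spec$shape) | psoas3d
  if (spec$arms) muscle3d <- muscle3d | array(arms2d, spec$shape)
  muscle3d <- muscle3d & !spinevox3d
  visc3d <- array(core2d, spec$shape) & !muscle3d & !spinevox3d
  subq3d <- array(sat2d, spec$shape) & !spinevox3d
  trunk3d <- array(trunk2d, spec$shape)

  set.seed(spec$seed)
  hu <- spec$hu_means[mat3d]
  if (spec$noise_sd > 0) {
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd)
  }
  ct <- ct_volume(array(hu, spec$shape), geom)

  labels <- list(
    spine = ct_labelmap(spine3d, geom, voc),
    vertebral_bodies = as_mask(bodies3d, geom, "vertebral_bodies"),
    trunk = as_mask(trunk3d, geom, "trunk"),
    psoas = as_mask(psoas3d, geom, "psoas"),
    compartment_muscle = as_mask(muscle3d, geom, "compartment_muscle"),
    compartment_visceral = as_mask(visc3d, geom, "compartment_visceral"),
    compartment_subcutaneous = as_mask(subq3d, geom, "compartment_subcutaneous")
  )

  truth <- phantom_truth(spec, geom, mat3d,
                         list(compartment_muscle = muscle3d,
                              psoas = psoas3d,
                              compartment_visceral = visc3d,
                              compartment_subcutaneous = subq3d),
                         bodies_labels = spine3d * bodies3d)

  structure(list(ct = ct, labels = labels, truth = truth, spec = spec),
            class = "ct_phantom")
}

# Ground truth by per-voxel membership over the generated material grid and
# compartment masks: a voxel truly belongs to a tissue iff it is in the
# tissue's compartment and its *noise-free* material mean lies in the HU
# window. Under noise_sd > 0 this remains the generative ground truth.
phantom_truth <- function(spec, geom, mat3d, comps, bodies_labels) {
  defs <- tissue_definitions()
  pixel_cm2 <- geom$spacing[1] * geom$spacing[2] / 100
  zs <- slice_z(geom)
  nz <- geom$shape[3]
  hu_of <- spec$hu_means[mat3d]
  csa <- purrr::pmap_dfr(defs, function(name, compartment, hu_low, hu_high) {
    member <- comps[[compartment]] & hu_of >= hu_low & hu_of <= hu_high
    counts <- apply(member, 3, sum)
    tibble::tibble(tissue = name, slice_index = 0:(nz - 1), z_mm = zs,
                   n_voxels = as.integer(counts),
                   csa_cm2 = counts * pixel_cm2)
  })
  voc <- default_vocabulary()
  present <- intersect(vertebra_order(),
                       names(voc)[voc %in% unique(as.integer(bodies_labels))])
  verts <- purrr::map_dfr(present, function(v) {
    counts <- apply(bodies_labels == voc[[v]], 3, sum)
    ks <- which(counts > 0) - 1L
    cz <- sum(zs[ks + 1] * counts[ks + 1]) / sum(counts)
    d <- abs(zs - cz)
    tibble::tibble(vertebra = v,
                   center_slice = min(which(d <= min(d) + 1e-9)) - 1L,
                   center_z_mm = cz,
                   slice_start = min(ks), slice_end = max(ks),
                   n_voxels = as.integer(sum(counts)))
  })
  a_i <- spec$trunk_semiaxes[1] - spec$sat_thickness
  b_i <- spec$trunk_semiaxes[2] - spec$sat_thickness
  analytic <- tibble::tribble(
    ~structure, ~area_cm2,
    "trunk", pi * prod(spec$trunk_semiaxes) / 100,
    "psoas_disc", pi * spec$psoas_radius^2 / 100,
    "vertebral_body", pi * spec$vertebra_radius^2 / 100,
    "muscle_band",
      pi * (a_i * b_i -
              (a_i - spec$muscle_thickness) * (b_i - spec$muscle_thickness)) / 100,
    "imat_disc", pi * spec$imat_radius^2 / 100,
    "arm_blob", if (spec$arms) pi * spec$arm_radius^2 / 100 else 0
  )
  list(csa = csa, vertebrae = verts, analytic = analytic)
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat("<ct_phantom> ", paste(x$spec$shape, collapse = " x "),
      " voxels, ", length(x$spec$vertebrae), " vertebrae, noise_sd ",
      x$spec$noise_sd, " HU\n", sep = "")
  invisible(x)
}

#' Write a phantom to disk as NIfTI plus truth tables
#'
#' @param phantom a `ct_phantom` from [generate_phantom()].
#' @param dir output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ct_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(ct = file.path(dir, "ct.nii.gz"))
  write_nifti(phantom$ct, files[["ct"]])
  for (nm in names(phantom$labels)) {
    files[[nm]] <- file.path(dir, paste0(nm, ".nii.gz"))
    write_nifti(phantom$labels[[nm]], files[[nm]])
  }
  files[["truth_csa"]] <- file.path(dir, "truth_csa.csv")
  readr::write_csv(phantom$truth$csa, files[["truth_csa"]])
  files[["truth_vertebrae"]] <- file.path(dir, "truth_vertebrae.csv")
  readr::write_csv(phantom$truth$vertebrae, files[["truth_vertebrae"]])
  invisible(files)
}
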