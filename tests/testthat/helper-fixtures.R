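# Shared fixtures: small in-memory geometries, label maps and oracles.

# simple axis-aligned geometry: unit-ish spacing, z translation 0
toy_geometry <- function(shape = c(4L, 4L, 40L), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  aff <- diag(4)
  aff[1, 1] <- spacing[1]; aff[2, 2] <- spacing[2]; aff[3, 3] <- spacing[3]
  aff[1:3, 4] <- origin
  ct_geometry(shape, spacing, aff)
}

# label map with a single vertebra occupying given 0-based slices
cylinder_labelmap <- function(slices, shape = c(4L, 4L, 40L),
                              spacing = c(1, 1, 1),
                              vertebra = "vertebra_L3",
                              counts = NULL) {
  geom <- toy_geometry(shape, spacing)
  data <- array(0L, shape)
  voc <- default_vocabulary()
  if (is.null(counts)) counts <- rep(shape[1] * shape[2], length(slices))
  for (i in seq_along(slices)) {
    k <- slices[i]
    flat <- rep(0L, shape[1] * shape[2])
    flat[seq_len(counts[i])] <- voc[[vertebra]]
    data[, , k + 1] <- matrix(flat, shape[1], shape[2])
  }
  ct_labelmap(data, geom, voc)
}

# brute-force center-of-mass oracle: explicit voxel enumeration in world mm
oracle_locate <- function(labelmap, vertebra) {
  voc <- labelmap$vocabulary
  idx <- which(labelmap$data == voc[[vertebra]], arr.ind = TRUE)
  aff <- labelmap$geometry$affine
  z <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    w <- aff %*% c(idx[r, 1] - 1, idx[r, 2] - 1, idx[r, 3] - 1, 1)
    z[r] <- w[3]
  }
  cz <- mean(z)
  ks <- seq_len(labelmap$geometry$shape[3]) - 1
  zk <- aff[3, 3] * ks + aff[3, 4]
  d <- abs(zk - cz)
  list(center_z = cz,
       center_slice = ks[min(which(d <= min(d) + 1e-9))],
       span = range(idx[, 3] - 1))
}

# brute-force comparable-pair concordance oracle (Harrell convention:
# higher risk should accompany shorter survival; tied risks count 1/2)
oracle_c_index <- function(time, event, risk) {
  n <- length(time); num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    shorter <- NA
    if (time[i] < time[j] && event[i]) shorter <- i
    else if (time[j] < time[i] && event[j]) shorter <- j
    else if (time[i] == time[j] && event[i] && !event[j]) shorter <- i
    else if (time[i] == time[j] && event[j] && !event[i]) shorter <- j
    if (is.na(shorter)) next
    den <- den + 1
    longer <- if (shorter == i) j else i
    if (risk[shorter] > risk[longer]) num <- num + 1
    else if (risk[shorter] == risk[longer]) num <- num + 0.5
  }
  num / den
}

# independent per-voxel recount of phantom ground truth: compartment
# membership AND the noise-free CT value inside the HU window
oracle_recount <- function(phantom, tissue_name) {
  def <- tissue_definitions(tissue_name)
  comp <- phantom$labels[[def$compartment]]$data != 0L
  hu <- phantom$ct$data
  member <- comp & hu >= def$hu_low & hu <= def$hu_high
  apply(member, 3, sum)
}

# quick default phantom reused across tests (noiseless)
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec())
    cache
  }
})
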