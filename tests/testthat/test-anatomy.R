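test_that("spine restriction keeps exactly the voxels inside the bodies mask", {
  ph <- default_phantom()
  spine <- ph$labels$spine
  bodies <- ph$labels$vertebral_bodies
  geom <- spine$geometry

  all_ones <- as_ones <- ct_labelmap(array(1L, geom$shape), geom,
                                     c(mask = 1L))
  expect_identical(restrict_spine_to_bodies(spine, all_ones)$data, spine$data)
  all_zero <- ct_labelmap(array(0L, geom$shape), geom, c(mask = 1L))
  expect_equal(sum(restrict_spine_to_bodies(spine, all_zero)$data), 0)

  # the spinous process lies outside the bodies mask: restriction removes it
  # and the surviving voxel count equals the per-voxel set intersection
  restricted <- restrict_spine_to_bodies(spine, bodies)
  expect_lt(sum(restricted$data > 0), sum(spine$data > 0))
  expect_equal(sum(restricted$data > 0),
               sum(spine$data > 0 & bodies$data > 0))
  expect_identical(restricted$vocabulary, spine$vocabulary)
})

test_that("trunk confinement is a voxelwise intersection", {
  ph <- generate_phantom(phantom_spec(arms = TRUE))
  muscle <- ph$labels$compartment_muscle
  trunk <- ph$labels$trunk

  confined <- confine_to_trunk(muscle, trunk)
  # arm voxels (outside the trunk) removed, trunk-interior voxels untouched
  expect_equal(confined$data != 0L,
               muscle$data != 0L & trunk$data != 0L)
  expect_lt(sum(confined$data), sum(muscle$data))

  # trunk superset -> unchanged; disjoint -> empty
  geom <- muscle$geometry
  everything <- ct_labelmap(array(1L, geom$shape), geom, c(mask = 1L))
  expect_identical(confine_to_trunk(muscle, everything)$data, muscle$data)
  outside <- ct_labelmap(array(as.integer(trunk$data == 0L), geom$shape),
                         geom, c(mask = 1L))
  expect_equal(sum(confine_to_trunk(confined, outside)$data), 0)
})

test_that("mask intersections are idempotent, commutative and non-increasing", {
  set.seed(11)
  geom <- toy_geometry(c(8L, 8L, 8L))
  for (i in 1:5) {
    a <- ct_labelmap(array(rbinom(512, 1, 0.4), c(8, 8, 8)), geom,
                     c(mask = 1L))
    b <- ct_labelmap(array(rbinom(512, 1, 0.4), c(8, 8, 8)), geom,
                     c(mask = 1L))
    ab <- confine_to_trunk(a, b)
    expect_identical(confine_to_trunk(ab, b)$data, ab$data)        # idempotent
    expect_identical(ab$data != 0L, confine_to_trunk(b, a)$data != 0L)
    expect_lte(sum(ab$data != 0L), min(sum(a$data != 0L), sum(b$data != 0L)))
  }
})

test_that("operations refuse misaligned geometries", {
  ph <- default_phantom()
  other <- ct_labelmap(array(1L, c(4, 4, 4)), toy_geometry(c(4L, 4L, 4L)),
                       c(mask = 1L))
  expect_error(restrict_spine_to_bodies(ph$labels$spine, other),
               "alignment error")
  expect_error(confine_to_trunk(ph$labels$compartment_muscle, other),
               "alignment error")
})

test_that("vertebra localization matches the voxel-enumeration oracle", {
  # single voxel at slice k
  lm <- cylinder_labelmap(slices = 17, counts = 1)
  loc <- locate_vertebra(lm, "vertebra_L3")
  expect_equal(loc$center_slice, 17L)
  expect_equal(loc$slice_start, 17L)
  expect_equal(loc$slice_end, 17L)
  expect_equal(loc$n_voxels, 1)

  # 10-slice symmetric cylinder over slices 20..29: the center of mass is
  # equidistant between slices 24 and 25; the tie resolves inferior -> 24
  lm <- cylinder_labelmap(slices = 20:29)
  loc <- locate_vertebra(lm, "vertebra_L3")
  expect_equal(loc$center_z_mm, 24.5)
  expect_equal(loc$center_slice, 24L)
  expect_equal(c(loc$slice_start, loc$slice_end), c(20L, 29L))

  # asymmetric wedge (more voxels inferiorly) against the explicit oracle
  lm <- cylinder_labelmap(slices = 10:15, counts = c(16, 16, 12, 6, 3, 1))
  loc <- locate_vertebra(lm, "vertebra_L3")
  orc <- oracle_locate(lm, "vertebra_L3")
  expect_equal(loc$center_z_mm, orc$center_z)
  expect_equal(loc$center_slice, orc$center_slice)
  expect_equal(c(loc$slice_start, loc$slice_end), orc$span)

  # anisotropic spacing: center of mass is computed in world mm
  lm <- cylinder_labelmap(slices = 5:9, spacing = c(0.7, 0.7, 3.2),
                          counts = c(10, 8, 4, 2, 1))
  loc <- locate_vertebra(lm, "vertebra_L3")
  orc <- oracle_locate(lm, "vertebra_L3")
  expect_equal(loc$center_z_mm, orc$center_z)
  expect_equal(loc$center_slice, orc$center_slice)
})

test_that("vertebra localization is equivariant under axial shifts", {
  base <- cylinder_labelmap(slices = 8:13, counts = c(16, 14, 10, 8, 2, 1))
  loc0 <- locate_vertebra(base, "vertebra_L3")
  for (s in c(1, 4, 10)) {
    shifted <- cylinder_labelmap(slices = 8:13 + s,
                                 counts = c(16, 14, 10, 8, 2, 1))
    locs <- locate_vertebra(shifted, "vertebra_L3")
    expect_equal(locs$center_slice, loc0$center_slice + s)
    expect_equal(locs$slice_start, loc0$slice_start + s)
  }
  # the center slice always lies inside the slice span
  expect_true(loc0$center_slice >= loc0$slice_start &&
                loc0$center_slice <= loc0$slice_end)
})

test_that("missing vertebrae raise a not-found error with QC context", {
  lm <- cylinder_labelmap(slices = 5:8, vertebra = "vertebra_L2")
  expect_error(locate_vertebra(lm, "vertebra_L3"), "not-found")
  expect_error(locate_vertebra(lm, "nonsense"), "not-found")
})

test_that("spine QC reports missing labels, order violations and fragments", {
  ph <- default_phantom()
  bodies <- restrict_spine_to_bodies(ph$labels$spine,
                                     ph$labels$vertebral_bodies)
  expect_true(qc_clean(qc_spine(bodies)))

  ph_miss <- generate_phantom(phantom_spec(
    anomalies = list(missing = "vertebra_L3")))
  b <- restrict_spine_to_bodies(ph_miss$labels$spine,
                                ph_miss$labels$vertebral_bodies)
  qc <- qc_spine(b)
  expect_equal(qc$missing_vertebrae, "vertebra_L3")

  ph_swap <- generate_phantom(phantom_spec(
    anomalies = list(swap = c("vertebra_L2", "vertebra_L3"))))
  b <- restrict_spine_to_bodies(ph_swap$labels$spine,
                                ph_swap$labels$vertebral_bodies)
  qc <- qc_spine(b)
  expect_equal(nrow(qc$order_violations), 1)
  expect_false(qc_clean(qc))

  ph_frag <- generate_phantom(phantom_spec(
    anomalies = list(fragment = "vertebra_L5")))
  b <- restrict_spine_to_bodies(ph_frag$labels$spine,
                                ph_frag$labels$vertebral_bodies)
  qc <- qc_spine(b)
  expect_true("vertebra_L5" %in% qc$fragment_warnings)
})
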