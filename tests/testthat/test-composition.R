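test_that("HU thresholds are closed intervals with the printed boundaries", {
  g <- toy_geometry(c(2L, 2L, 1L))
  hu <- array(c(-30, -29, 150, 151), c(2, 2, 1))
  ct <- ct_volume(hu, g)
  comp <- ct_labelmap(array(1L, c(2, 2, 1)), g, c(compartment_muscle = 1L))

  sm <- assign_tissue(ct, comp, tissue_definitions("SM_total"))
  imat <- assign_tissue(ct, comp, tissue_definitions("IMAT"))
  # muscle window [-29, 150]: -29 and 150 in, -30 and 151 out
  expect_equal(as.vector(sm$data), c(0L, 1L, 1L, 0L))
  # adipose window [-190, -30]: only -30 in
  expect_equal(as.vector(imat$data), c(1L, 0L, 0L, 0L))
  # the two windows are disjoint: no voxel is both muscle and IMAT
  expect_equal(sum(sm$data & imat$data), 0)
})

test_that("tissue assignment degenerates correctly", {
  g <- toy_geometry(c(4L, 4L, 2L))
  ct <- ct_volume(array(60, c(4, 4, 2)), g)
  empty <- ct_labelmap(array(0L, c(4, 4, 2)), g, c(compartment_muscle = 1L))
  expect_equal(sum(assign_tissue(ct, empty,
                                 tissue_definitions("SM_total"))$data), 0)
  # uniform HU strictly inside the window: mask equals the compartment
  full <- ct_labelmap(array(1L, c(4, 4, 2)), g, c(compartment_muscle = 1L))
  out <- assign_tissue(ct, full, tissue_definitions("SM_total"))
  expect_equal(out$data != 0L, full$data != 0L)
})

test_that("per-slice CSA applies the pixel-area unit conversion", {
  g <- toy_geometry(c(40L, 25L, 2L))
  dat <- array(0L, c(40, 25, 2))
  dat[, , 1] <- 1L          # 1000 voxels at 1 x 1 mm -> 10 cm^2
  m <- ct_labelmap(dat, g, c(SM_total = 1L))
  prof <- csa_per_slice(m, subject = "s")
  expect_equal(prof$csa_cm2, c(10, 0))
  expect_equal(prof$slice_index, c(0L, 1L))

  # CSA is linear in pixel area
  g2 <- toy_geometry(c(40L, 25L, 2L), spacing = c(2, 0.5, 1))
  m2 <- ct_labelmap(dat, g2, c(SM_total = 1L))
  expect_equal(csa_per_slice(m2)$csa_cm2[1], 10)
})

test_that("a rasterized disc matches voxel counting and the analytic area", {
  r_vox <- 30
  n <- 2L * r_vox + 5L
  g <- toy_geometry(c(n, n, 1L), spacing = c(0.8, 0.8, 1))
  cx <- (n - 1) / 2
  xs <- (seq_len(n) - 1) - cx
  inside <- outer(xs, xs, function(a, b) a^2 + b^2 <= r_vox^2)
  m <- ct_labelmap(array(as.integer(inside), c(n, n, 1)), g, c(SM_total = 1L))
  prof <- csa_per_slice(m)
  expect_equal(prof$csa_cm2, sum(inside) * 0.8 * 0.8 / 100)
  analytic <- pi * r_vox^2 * 0.8 * 0.8 / 100
  expect_lt(abs(prof$csa_cm2 - analytic) / analytic, 0.015)
})

test_that("vertebra mean, reference CSA and coverage errors behave", {
  prof <- tibble::tibble(subject = "s", tissue = "SM_total",
                         slice_index = 8:14, z_mm = 8:14,
                         csa_cm2 = c(5, 5, 8, 10, 12, 5, 5))
  loc <- tibble::tibble(vertebra = "vertebra_L3", center_slice = 11L,
                        center_z_mm = 11, slice_start = 10L, slice_end = 12L,
                        n_voxels = 10L)
  expect_equal(mean_csa_over_vertebra(prof, loc), 10)
  expect_equal(csa_at_reference(prof, loc), 10)

  const <- dplyr::mutate(prof, csa_cm2 = 7)
  expect_equal(mean_csa_over_vertebra(const, loc), 7)
  expect_equal(csa_at_reference(const, loc), 7)

  short <- dplyr::filter(prof, slice_index >= 11)
  expect_error(mean_csa_over_vertebra(short, loc), "coverage error")
  off <- dplyr::mutate(loc, center_slice = 3L)
  expect_error(csa_at_reference(prof, off), "coverage error")
})

test_that("SMI is CSA over height squared with domain checks", {
  expect_equal(smi(100, 2), 25)
  expect_equal(smi(0, 1.7), 0)
  set.seed(3)
  csa <- runif(20, 20, 200)
  h <- runif(20, 1.5, 2)
  expect_equal(smi(csa, h) * h^2, csa)
  expect_error(smi(100, 0), "domain error")
  expect_error(smi(100, -1), "domain error")
  expect_warning(smi(100, 3), "QC")
})

test_that("relative profiles use signed offsets with 100% at the center", {
  prof <- tibble::tibble(subject = "s", tissue = "SM_psoas",
                         slice_index = 0:6, z_mm = 0:6,
                         csa_cm2 = c(14, 13, 12, 10, 8, 6, 4))
  loc <- tibble::tibble(vertebra = "vertebra_L3", center_slice = 3L,
                        center_z_mm = 3, slice_start = 2L, slice_end = 4L,
                        n_voxels = 10L)
  rel <- relative_profile(prof, loc)
  expect_equal(rel$offset, -3:3)
  expect_equal(rel$pct[rel$offset == 0], 100)
  # negative offsets are inferior slices (here: larger CSA below the center)
  expect_equal(rel$pct, 100 * prof$csa_cm2 / 10)

  uniform <- dplyr::mutate(prof, csa_cm2 = 9)
  expect_true(all(relative_profile(uniform, loc)$pct == 100))
  zero <- dplyr::mutate(prof, csa_cm2 = 0)
  expect_error(relative_profile(zero, loc), "undefined-reference")
})

test_that("tapering psoas relative profile matches the truth ratio", {
  ph <- generate_phantom(phantom_spec(psoas_taper = 0.25, bowel_radius = 0))
  bodies <- restrict_spine_to_bodies(ph$labels$spine,
                                     ph$labels$vertebral_bodies)
  loc <- locate_vertebra(bodies, "vertebra_L3")
  mask <- assign_tissue(ph$ct, ph$labels$psoas,
                        tissue_definitions("SM_psoas"))
  prof <- csa_per_slice(mask, tissue_name = "SM_psoas")
  rel <- relative_profile(prof, loc)
  truth <- dplyr::filter(ph$truth$csa, tissue == "SM_psoas")
  ref_truth <- truth$csa_cm2[truth$slice_index == loc$center_slice]
  expect_equal(rel$pct, 100 * truth$csa_cm2 / ref_truth)
  # taper makes inferior slices larger in CSA
  span <- dplyr::filter(rel, offset >= -3, offset <= 3)
  expect_true(all(diff(span$csa_cm2) <= 0))
  expect_gt(span$csa_cm2[1], span$csa_cm2[nrow(span)])
})

test_that("muscle and IMAT partition the in-window muscle compartment", {
  ph <- default_phantom()
  muscle_comp <- ph$labels$compartment_muscle
  sm <- assign_tissue(ph$ct, muscle_comp, tissue_definitions("SM_total"))
  imat <- assign_tissue(ph$ct, muscle_comp, tissue_definitions("IMAT"))
  expect_equal(sum(sm$data & imat$data), 0)
  in_either <- ph$ct$data >= -190 & ph$ct$data <= 150 &
    !(ph$ct$data > -30 & ph$ct$data < -29)
  expect_equal(sum(sm$data | imat$data),
               sum((muscle_comp$data != 0L) & in_either))
  # psoas tissue is a subset of total muscle tissue (psoas inside compartment)
  ps <- assign_tissue(ph$ct, ph$labels$psoas, tissue_definitions("SM_psoas"))
  expect_equal(sum(ps$data & !sm$data), 0)
})
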