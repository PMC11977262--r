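test_that("canonical NIfTI round-trips and canonicalization is idempotent", {
  ph <- default_phantom()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(ph$ct, f)
  ct <- load_ct(f)
  expect_equal(ct$data, ph$ct$data)
  expect_equal(ct$geometry$affine, ph$ct$geometry$affine, tolerance = 1e-6)
  # loading what was already canonical changes nothing (idempotence)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(ct, f2)
  ct2 <- load_ct(f2)
  expect_equal(ct2$data, ct$data)
  expect_equal(ct2$geometry$affine, ct$geometry$affine, tolerance = 1e-6)
})

test_that("a flipped superior-inferior axis is reordered without moving voxels", {
  ph <- default_phantom()
  geom <- ph$ct$geometry
  nz <- geom$shape[3]
  # same volume stored inferior-last: flip the grid and negate the z axis
  flipped <- ph$ct$data[, , nz:1]
  aff <- geom$affine
  aff_f <- aff
  aff_f[3, 3] <- -aff[3, 3]
  aff_f[3, 4] <- aff[3, 4] + aff[3, 3] * (nz - 1)
  img <- RNifti::asNifti(flipped)
  RNifti::pixdim(img) <- geom$spacing
  RNifti::qform(img) <- structure(aff_f, code = 2L)
  RNifti::sform(img) <- structure(aff_f, code = 2L)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)

  ct <- load_ct(f)
  expect_equal(ct$data, ph$ct$data)
  # world coordinates of random voxels are invariant under canonicalization
  set.seed(7)
  ijk_canon <- cbind(sample(0:(geom$shape[1] - 1), 25, TRUE),
                     sample(0:(geom$shape[2] - 1), 25, TRUE),
                     sample(0:(nz - 1), 25, TRUE))
  ijk_flip <- ijk_canon
  ijk_flip[, 3] <- nz - 1 - ijk_canon[, 3]
  w_canon <- voxel_to_world(ct$geometry, ijk_canon)
  w_flip <- cbind(ijk_flip, 1) %*% t(aff_f)
  expect_equal(w_canon, w_flip[, 1:3], tolerance = 1e-6)
})

test_that("images without a usable transform are rejected as metadata errors", {
  a <- array(0, dim = c(4, 4, 4))
  img <- RNifti::asNifti(a)  # qform/sform codes are 0
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(load_ct(f), "metadata error")
  expect_error(load_ct(file.path(tempdir(), "does-not-exist.nii")),
               "format error")
})

test_that("label maps round-trip bit-exactly and enforce alignment/vocabulary", {
  ph <- default_phantom()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(ph$labels$spine, f)
  lm <- load_labels(f, reference = ph$ct$geometry)
  expect_identical(lm$data, ph$labels$spine$data)

  # all-zero volume is a valid empty label map
  z <- ct_labelmap(array(0L, ph$ct$geometry$shape), ph$ct$geometry,
                   default_vocabulary())
  expect_equal(sum(z$data), 0)

  # geometry mismatch -> alignment error, never silent resampling
  other <- toy_geometry(shape = ph$ct$geometry$shape,
                        spacing = c(1, 1, 1))
  expect_error(load_labels(f, reference = other), "alignment error")

  # unknown code -> vocabulary error naming the code
  bad <- array(0L, c(4, 4, 4))
  bad[1, 1, 1] <- 99L
  expect_error(ct_labelmap(bad, toy_geometry(c(4L, 4L, 4L)),
                           default_vocabulary()),
               "vocabulary error.*99")
})

test_that("out-of-range HU values are flagged, not rejected", {
  g <- toy_geometry(c(4L, 4L, 4L))
  dat <- array(0, c(4, 4, 4))
  dat[1, 1, 1] <- -2000
  dat[2, 2, 2] <- 5000
  ct <- ct_volume(dat, g)
  qc <- qc_hu(ct)
  expect_true(qc$flagged)
  expect_equal(qc$n_below, 1)
  expect_equal(qc$n_above, 1)
  expect_false(qc_hu(ct_volume(array(0, c(4, 4, 4)), g))$flagged)
  expect_error(ct_volume(array(NaN, c(4, 4, 4)), g), "finite")
})

test_that("result writer honors the schema and round-trips to 6 significant digits", {
  d <- withr::local_tempdir()
  files <- write_results(NULL, NULL, d)
  empty <- readr::read_csv(files[["profiles"]], show_col_types = FALSE)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("subject", "tissue", "slice_index", "z_mm", "csa_cm2"))

  prof <- tibble::tibble(subject = "S1", tissue = "SM_total",
                         slice_index = 0:2, z_mm = c(0, 2.5, 5),
                         csa_cm2 = c(41.732915, 39.1, 0.0061237))
  meas <- tibble::tibble(subject = "S1", tissue = "SM_total",
                         csa_cm2 = 41.732915)
  files <- write_results(prof, meas, d)
  back <- readr::read_csv(files[["profiles"]], show_col_types = FALSE)
  expect_equal(nrow(back), 3)
  expect_equal(signif(back$csa_cm2, 6), signif(prof$csa_cm2, 6))
  expect_true(file.exists(files[["summary"]]))
})

test_that("a DICOM series ingests with the HU rescale applied", {
  d <- withr::local_tempdir()
  script <- sprintf('
import numpy as np, pydicom, os
from pydicom.dataset import FileDataset
from pydicom.uid import generate_uid, ExplicitVRLittleEndian
out = %s
series = generate_uid(); study = generate_uid(); frame = generate_uid()
for k in range(3):
    p = os.path.join(out, "s%%d.dcm" %% k)
    ds = FileDataset(p, {}, file_meta=None, preamble=b"\\0"*128)
    ds.file_meta = pydicom.dataset.FileMetaDataset()
    ds.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    ds.file_meta.MediaStorageSOPInstanceUID = generate_uid()
    ds.SOPClassUID = pydicom.uid.CTImageStorage
    ds.SOPInstanceUID = ds.file_meta.MediaStorageSOPInstanceUID
    ds.Modality = "CT"; ds.SeriesInstanceUID = series
    ds.StudyInstanceUID = study; ds.FrameOfReferenceUID = frame
    ds.Rows = ds.Columns = 8
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 1; ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.PixelSpacing = [1.0, 1.0]; ds.SliceThickness = 2.0
    ds.ImagePositionPatient = [0.0, 0.0, float(2 * k)]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.InstanceNumber = k + 1
    ds.RescaleSlope = 1.0; ds.RescaleIntercept = -1024.0
    arr = np.full((8, 8), 1024, dtype=np.int16)
    ds.PixelData = arr.tobytes()
    ds.save_as(p, write_like_original=False)
', deparse(d))
  status <- system2("python", c("-c", shQuote(script)))
  expect_equal(status, 0)
  ct <- load_ct(d)
  # stored value 1024 with slope 1, intercept -1024 -> HU 0
  expect_equal(unique(as.vector(ct$data)), 0)
  expect_equal(ct$geometry$shape, c(8L, 8L, 3L))
  expect_equal(ct$geometry$spacing, c(1, 1, 2), tolerance = 1e-6)
})
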