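# DICOM series and raw-bundle reading: calibration, geometry and
# round-trip fidelity.

test_that("DICOM write/read round-trips an integer-valued phantom exactly", {
  ph <- phantomSpec(c(5, 8, 8), c(0.7, 0.7), 2.0,
                    stones = stoneSpec(c(5, 2.8, 2.8), c(3, 3, 3)),
                    backgroundHuSd = 0, blurSigmaMm = 0)
  vol <- renderPhantom(ph)$volume
  d <- withr::local_tempdir()
  files <- writePhantomDicom(vol, d)
  expect_length(files, 5L)

  back <- readDicomSeries(d)
  expect_identical(dim(back), dim(vol))
  expect_equal(voxels(back), voxels(vol))
  expect_equal(pixelSpacing(back), c(0.7, 0.7))
  expect_equal(sliceThickness(back), 2.0)
  expect_equal(slicePositions(back), slicePositions(vol))
  expect_equal(seriesID(back), seriesID(vol))
})

test_that("stored values are rescaled to HU via slope and intercept", {
  # stored 1000 with intercept -1024, slope 1 must read back as -24 HU
  hu <- matrix(-24, 4, 4)
  d <- withr::local_tempdir()
  stonevol:::writeDicomSlice(
    file.path(d, "s1.dcm"), hu, pixelSpacing = c(1, 1),
    sliceThickness = 1, slicePosition = 0, seriesUID = "1.2.3",
    instanceNumber = 1, rescaleSlope = 1, rescaleIntercept = -1024)
  sl <- stonevol:::readDicomFile(file.path(d, "s1.dcm"))
  expect_equal(unique(as.vector(sl$hu)), -24)

  # a non-unit slope is inverted exactly on integer-representable HU
  stonevol:::writeDicomSlice(
    file.path(d, "s2.dcm"), matrix(500, 4, 4), pixelSpacing = c(1, 1),
    sliceThickness = 1, slicePosition = 0, seriesUID = "1.2.3",
    instanceNumber = 2, rescaleSlope = 2, rescaleIntercept = -1024)
  expect_equal(
    unique(as.vector(stonevol:::readDicomFile(file.path(d, "s2.dcm"))$hu)),
    500)
})

test_that("missing slice-thickness attribute falls back to median gap", {
  hu <- matrix(0, 4, 4)
  d <- withr::local_tempdir()
  for (i in 1:3)
    stonevol:::writeDicomSlice(
      file.path(d, sprintf("s%d.dcm", i)), hu, pixelSpacing = c(1, 1),
      sliceThickness = NA, slicePosition = (i - 1) * 2,
      seriesUID = "1.2.3", instanceNumber = i, includeThickness = FALSE)
  vol <- readDicomSeries(d)
  expect_equal(sliceThickness(vol), 2.0)
})

test_that("slice order on disk does not affect the volume", {
  ph <- phantomSpec(c(6, 6, 6), c(1, 1), 1,
                    stones = stoneSpec(c(3, 3, 3), c(3, 2, 2)),
                    backgroundHuSd = 0, blurSigmaMm = 0)
  vol <- renderPhantom(ph)$volume
  d1 <- withr::local_tempdir()
  writePhantomDicom(vol, d1)
  # rewrite under names that reverse the lexicographic file order
  d2 <- withr::local_tempdir()
  files <- list.files(d1, full.names = TRUE)
  for (i in seq_along(files))
    file.copy(files[i], file.path(d2, sprintf("z_%04d.dcm",
                                              length(files) - i + 1L)))
  expect_equal(voxels(readDicomSeries(d2)), voxels(readDicomSeries(d1)))
})

test_that("degenerate series inputs raise the contracted errors", {
  d <- withr::local_tempdir()
  expect_error(readDicomSeries(d), "no input")

  hu <- matrix(0, 4, 4)
  stonevol:::writeDicomSlice(file.path(d, "a.dcm"), hu, c(1, 1), 1, 0,
                             "1.2.3", 1)
  stonevol:::writeDicomSlice(file.path(d, "b.dcm"), hu, c(1, 1), 1, 1,
                             "9.9.9", 2)
  expect_error(readDicomSeries(d), "ambiguous series")

  d3 <- withr::local_tempdir()
  stonevol:::writeDicomSlice(file.path(d3, "a.dcm"), hu, c(1, 1), 1, 0,
                             "1.2.3", 1)
  stonevol:::writeDicomSlice(file.path(d3, "b.dcm"), matrix(0, 6, 6),
                             c(1, 1), 1, 1, "1.2.3", 2)
  expect_error(readDicomSeries(d3), "in-plane dimensions")
})

test_that("thickness attribute disagreeing with slice gaps warns", {
  hu <- matrix(0, 4, 4)
  d <- withr::local_tempdir()
  for (i in 1:3)
    stonevol:::writeDicomSlice(
      file.path(d, sprintf("s%d.dcm", i)), hu, c(1, 1),
      sliceThickness = 5, slicePosition = (i - 1) * 2,
      seriesUID = "1.2.3", instanceNumber = i)
  expect_warning(vol <- readDicomSeries(d), "disagrees")
  expect_equal(sliceThickness(vol), 5)   # attribute takes precedence
})

test_that("raw bundle round-trips and matches the DICOM path", {
  ph <- phantomSpec(c(4, 5, 6), c(0.5, 0.5), 1.2,
                    stones = stoneSpec(c(2.4, 1.25, 1.5), c(2, 2, 2)),
                    backgroundHuSd = 0, blurSigmaMm = 0)
  vol <- renderPhantom(ph)$volume
  vf <- withr::local_tempfile(); mf <- withr::local_tempfile()
  writeRawBundle(vol, vf, mf)
  back <- readRawBundle(vf, mf)
  expect_equal(voxels(back), voxels(vol))
  expect_equal(pixelSpacing(back), pixelSpacing(vol))
  expect_equal(sliceThickness(back), sliceThickness(vol))

  dd <- withr::local_tempdir()
  writePhantomDicom(vol, dd)
  viaDicom <- readDicomSeries(dd)
  expect_equal(voxels(back), voxels(viaDicom))
})

test_that("bundle shape/metadata mismatch is a geometry error", {
  vol <- ctVolume(array(0, c(3, 4, 4)), c(0.5, 0.5), 1)
  vf <- withr::local_tempfile(); mf <- withr::local_tempfile()
  writeRawBundle(vol, vf, mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  meta$grid_shape <- c(4L, 4L, 4L)
  meta$slice_positions <- (1:4) - 0.5
  jsonlite::write_json(meta, mf, digits = NA)
  expect_error(readRawBundle(vf, mf), "geometry error")
})

test_that("metrics JSON round-trips, keeps stone order, handles empty", {
  mf <- withr::local_tempfile(fileext = ".json")

  writeMetrics(stonevol:::emptyMetrics(), mf)
  doc <- jsonlite::read_json(mf, simplifyVector = TRUE)
  expect_identical(doc$schema_version, 1L)
  expect_equal(nrow(readMetrics(mf)), 0L)

  m <- data.frame(
    stone_id = c(1L, 2L), voxel_count = c(100L, 40L),
    volume_mm3 = c(12.5, 5.0),
    major_horizontal_axis_mm = c(4, 2),
    major_vertical_axis_mm = c(3, 2),
    largest_slice_area_mm2 = c(6, 2),
    largest_slice_index = c(5L, 9L),
    craniocaudal_extent_mm = c(4, 2))
  writeMetrics(m, mf)
  back <- readMetrics(mf)
  expect_equal(back$stone_id, c(1L, 2L))
  expect_equal(back$volume_mm3, m$volume_mm3)
})
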