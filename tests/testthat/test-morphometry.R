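# Voxel-count volumetry, bounding-box axes, largest-slice area and the
# manual ellipsoid estimators.

test_that("a single labelled voxel yields the single-voxel identities", {
  vox <- array(0, c(3, 3, 3)); vox[2, 2, 2] <- 500
  vol <- ctVolume(vox, c(0.5, 0.5), 1.0)
  lab <- labelStones(vox >= 130, segmentationParams(minVoxels = 1))
  m <- measureStone(vol, lab, 1L)
  expect_identical(m$voxel_count, 1L)
  expect_equal(m$volume_mm3, 0.25)
  expect_equal(m$major_horizontal_axis_mm, 0.5)
  expect_equal(m$major_vertical_axis_mm, 0.5)
  expect_equal(m$largest_slice_area_mm2, 0.25)
  expect_identical(m$largest_slice_index, 2L)
  expect_equal(m$craniocaudal_extent_mm, 1.0)
})

test_that("an unknown stone label is rejected", {
  vox <- array(0, c(3, 3, 3)); vox[2, 2, 2] <- 500
  vol <- ctVolume(vox, c(0.5, 0.5), 1.0)
  lab <- labelStones(vox >= 130, segmentationParams(minVoxels = 1))
  expect_error(measureStone(vol, lab, 2L), "unknown label")
})

test_that("digitized ellipsoid volume is within 5% and axes within one voxel", {
  rp <- renderPhantom(cleanEllipsoidPhantom(c(10, 6, 4), spacing = 0.5))
  lab <- segmentStones(rp$volume, segmentationParams(huThreshold = MID_HU))
  m <- measureStones(rp$volume, lab)
  truth <- pi / 6 * 10 * 6 * 4
  expect_lt(abs(m$volume_mm3 - truth) / truth, 0.05)
  # diameters are laid out (x, y, z): d1 = 10 runs along the columns
  expect_lt(abs(m$major_horizontal_axis_mm - 10), 0.5 + 1e-9)
  expect_lt(abs(m$major_vertical_axis_mm - 6), 0.5 + 1e-9)
  expect_lt(abs(m$craniocaudal_extent_mm - 4), 0.5 + 1e-9)
  # invariants
  expect_equal(m$volume_mm3 / m$voxel_count, voxelVolume(rp$volume))
  expect_lte(m$largest_slice_area_mm2,
             m$major_horizontal_axis_mm * m$major_vertical_axis_mm)
})

test_that("halving the voxel size shrinks the digitization error", {
  errAt <- function(spacing) {
    rp <- renderPhantom(cleanEllipsoidPhantom(c(10, 6, 4),
                                              spacing = spacing))
    lab <- segmentStones(rp$volume,
                         segmentationParams(huThreshold = MID_HU))
    m <- measureStones(rp$volume, lab)
    truth <- rp$manifest$stones[[1]]$analytic_volume_mm3
    abs(m$volume_mm3 - truth) / truth
  }
  expect_lt(errAt(0.25), errAt(0.5))
})

test_that("volume identity holds for every stone of a multi-stone phantom", {
  stones <- list(stoneSpec(c(4, 4, 4), c(4, 3, 3)),
                 stoneSpec(c(4, 14, 14), c(3, 3, 2)))
  ph <- phantomSpec(c(24, 42, 30), c(0.4, 0.6), 0.8, stones = stones,
                    backgroundHuSd = 0, blurSigmaMm = 0)
  rp <- renderPhantom(ph)
  lab <- segmentStones(rp$volume, segmentationParams(huThreshold = MID_HU))
  m <- measureStones(rp$volume, lab)
  expect_equal(m$volume_mm3, m$voxel_count * 0.4 * 0.6 * 0.8)
})

test_that("total burden sums volumes and counts; empty list gives zeros", {
  m <- data.frame(volume_mm3 = c(10, 15), voxel_count = c(40L, 60L),
                  major_horizontal_axis_mm = c(3, 5))
  tb <- totalBurden(m)
  expect_equal(tb$total_volume_mm3, 25)
  expect_identical(tb$total_voxel_count, 100L)
  expect_equal(tb$max_major_axis_mm, 5)

  z <- totalBurden(stonevol:::emptyMetrics())
  expect_equal(z$total_volume_mm3, 0)
  expect_equal(z$max_major_axis_mm, 0)

  # five residual fragments of the worked example sum to 65.02 mm^3
  fr <- fragmentGroups()$notFree
  tb5 <- totalBurden(data.frame(volume_mm3 = fr$volume_mm3,
                                voxel_count = 0L,
                                major_horizontal_axis_mm = fr$major_axis_mm))
  expect_equal(tb5$total_volume_mm3, 65.02)
})

test_that("axisTriple sorts any permutation into a >= c >= b", {
  t1 <- axisTriple(6, 10, 4)
  expect_equal(t1$a, 10); expect_equal(t1$b, 4); expect_equal(t1$c, 6)
  for (p in list(c(10, 6, 4), c(4, 10, 6), c(6, 4, 10)))
    expect_equal(do.call(axisTriple, as.list(p)), t1)
  tie <- axisTriple(5, 5, 5)
  expect_equal(unlist(tie[c("a", "b", "c")]), c(a = 5, b = 5, c = 5))
  expect_error(axisTriple(1, -1, 2), "domain error")
  expect_error(axisTriple(0, 1, 2), "domain error")
})

test_that("ellipsoid estimators evaluate the three printed formulas", {
  # sphere: all three coincide at pi/6 d^3
  sph <- ellipsoidVolumes(axisTriple(10, 10, 10))
  expect_equal(sph$scalene_mm3, pi / 6 * 1000)
  expect_equal(sph$oblate_mm3, sph$scalene_mm3)
  expect_equal(sph$prolate_mm3, sph$scalene_mm3)

  ev <- ellipsoidVolumes(axisTriple(10, 6, 4))
  expect_equal(ev$scalene_mm3, pi / 6 * 10 * 4 * 6)   # 125.66
  expect_equal(ev$oblate_mm3, pi / 6 * 10 * 10 * 6)   # 314.16
  expect_equal(ev$prolate_mm3, pi / 6 * 10 * 4 * 4)   #  83.78
  expect_equal(round(ev$scalene_mm3, 2), 125.66)
  expect_equal(round(ev$oblate_mm3, 2), 314.16)
  expect_equal(round(ev$prolate_mm3, 2), 83.78)
})

test_that("oblate >= scalene >= prolate for random diameter triples", {
  set.seed(7)
  for (i in 1:500) {
    ev <- ellipsoidVolumes(axisTriple(runif(1, 0.5, 30), runif(1, 0.5, 30),
                                      runif(1, 0.5, 30)))
    expect_gte(ev$oblate_mm3, ev$scalene_mm3)
    expect_gte(ev$scalene_mm3, ev$prolate_mm3)
  }
})

test_that("scalene estimate from measured axes agrees with voxel volume", {
  rp <- renderPhantom(cleanEllipsoidPhantom(c(12, 8, 6), spacing = 0.5))
  lab <- segmentStones(rp$volume, segmentationParams(huThreshold = MID_HU))
  m <- measureStones(rp$volume, lab)
  ax <- axisTriple(m$major_horizontal_axis_mm, m$major_vertical_axis_mm,
                   m$craniocaudal_extent_mm)
  ev <- ellipsoidVolumes(ax)
  expect_lt(abs(ev$scalene_mm3 - m$volume_mm3) / m$volume_mm3, 0.10)
})

test_that("largest-slice ties resolve to the lowest slice index", {
  vox <- array(0, c(4, 4, 4))
  vox[2, 2, 2:3] <- 500     # two voxels on slice 2
  vox[3, 2:3, 2] <- 500     # two voxels on slice 3
  vol <- ctVolume(vox, c(1, 1), 1)
  lab <- labelStones(vox >= 130, segmentationParams(minVoxels = 1,
                                                    connectivity = 26))
  m <- measureStone(vol, lab, 1L)
  expect_identical(m$largest_slice_index, 2L)
})
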