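# Per-stone burden measures: the voxel-count volume
# (N_voxels x pixel area x slice thickness), in-plane bounding-box axes
# and largest-slice area of the segmented stone, plus the three manual
# ellipsoid volume estimators computed from measured diameters.

#' Measure one segmented stone
#'
#' Voxel-count volumetry and axis/area morphometry for stone `stoneId`:
#' * `volume_mm3 = voxel_count * row_spacing * col_spacing * slice_thickness`
#'   (exact identity);
#' * the largest slice is the axial slice holding the most stone voxels
#'   (ties: lowest slice index);
#' * `major_horizontal_axis_mm` / `major_vertical_axis_mm` are the
#'   whole-pixel bounding-box extents of that slice along the image
#'   column / row direction (`(max - min + 1) * spacing`);
#' * `largest_slice_area_mm2` is that slice's pixel count times the pixel
#'   area;
#' * `craniocaudal_extent_mm` is the whole-slice extent along z.
#'
#' @param volume the source [CTVolume-class] (geometry provider).
#' @param labels a [StoneLabelMap-class] congruent with `volume`.
#' @param stoneId integer label present in `labels`.
#' @return A one-row data.frame of per-stone metrics.
#' @export
measureStone <- function(volume, labels, stoneId) {
  stopifnot(is(volume, "CTVolume"), is(labels, "StoneLabelMap"))
  if (!identical(dim(volume), dim(labels)))
    stop("geometry error: label map and volume dimensions differ")
  if (!(stoneId %in% seq_len(labels@nStones)))
    stop("unknown label: stone ", stoneId, " not present in label map")
  idx <- which(labels@labels == stoneId)
  sub <- arrayInd(idx, dim(labels))   # (slice, row, col)
  rs <- volume@pixelSpacing[1]; cs <- volume@pixelSpacing[2]
  thk <- volume@sliceThickness

  counts <- tabulate(sub[, 1], nbins = dim(volume)[1])
  largestSlice <- which.max(counts)   # which.max takes the lowest on ties
  on <- sub[, 1] == largestSlice
  rows <- sub[on, 2]; cols <- sub[on, 3]

  data.frame(
    stone_id = as.integer(stoneId),
    voxel_count = length(idx),
    volume_mm3 = length(idx) * rs * cs * thk,
    major_horizontal_axis_mm = (max(cols) - min(cols) + 1L) * cs,
    major_vertical_axis_mm = (max(rows) - min(rows) + 1L) * rs,
    largest_slice_area_mm2 = counts[largestSlice] * rs * cs,
    largest_slice_index = as.integer(largestSlice),
    craniocaudal_extent_mm = (max(sub[, 1]) - min(sub[, 1]) + 1L) * thk
  )
}

#' Measure every stone in a label map
#'
#' @param volume the source [CTVolume-class].
#' @param labels a [StoneLabelMap-class].
#' @return A data.frame with one row per stone (zero rows when the map
#'   is empty), in label order.
#' @export
measureStones <- function(volume, labels) {
  if (labels@nStones == 0L) return(emptyMetrics())
  do.call(rbind, lapply(seq_len(labels@nStones), function(k)
    measureStone(volume, labels, k)))
}

#' Aggregate stone burden over a set of stones
#'
#' The total treatable burden: volumes and voxel counts sum over stones,
#' and the largest single major axis is retained.
#'
#' @param metrics data.frame of per-stone metrics ([measureStones()]
#'   output, or any frame with `volume_mm3`, `voxel_count`,
#'   `major_horizontal_axis_mm`).
#' @return A list with `total_volume_mm3`, `total_voxel_count`,
#'   `max_major_axis_mm` (all 0 for an empty list).
#' @export
totalBurden <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) == 0L)
    return(list(total_volume_mm3 = 0, total_voxel_count = 0L,
                max_major_axis_mm = 0))
  list(
    total_volume_mm3 = sum(metrics$volume_mm3),
    total_voxel_count = sum(metrics$voxel_count),
    max_major_axis_mm = max(metrics$major_horizontal_axis_mm)
  )
}

#' Order three measured diameters into the manual a/b/c convention
#'
#' The manual protocol measures the maximum diameter along the two
#' perpendicular axial axes and one further view. For the ellipsoid
#' estimators: `a` is the largest diameter (equatorial), `b` the
#' smallest (polar) and `c` the middle one — the assignment under which
#' the oblate >= scalene >= prolate estimator ordering is an algebraic
#' identity.
#'
#' @param d1,d2,d3 measured diameters in mm (any order, all > 0).
#' @return A list of class `AxisTriple` with fields `a >= c >= b > 0`.
#' @examples
#' axisTriple(6, 10, 4)   # a = 10, b = 4, c = 6
#' @export
axisTriple <- function(d1, d2, d3) {
  d <- c(d1, d2, d3)
  if (length(d) != 3L || any(!is.finite(d)) || any(d <= 0))
    stop("domain error: all three diameters must be positive and finite")
  s <- sort(d)
  structure(list(a = s[3], b = s[1], c = s[2]), class = "AxisTriple")
}

#' Manual ellipsoid volume estimates from measured diameters
#'
#' The three manual stone-volume formulas:
#' scalene `pi/6 * a * b * c`, oblate `pi/6 * a * a * c`, prolate
#' `pi/6 * a * b * b`. With `a >= c >= b` the estimates always order
#' oblate >= scalene >= prolate.
#'
#' @param axes an [axisTriple()].
#' @return A list of class `EllipsoidEstimates` with `scalene_mm3`,
#'   `oblate_mm3`, `prolate_mm3`.
#' @examples
#' ellipsoidVolumes(axisTriple(10, 6, 4))
#' @export
ellipsoidVolumes <- function(axes) {
  stopifnot(inherits(axes, "AxisTriple"))
  structure(list(
    scalene_mm3 = pi / 6 * axes$a * axes$b * axes$c,
    oblate_mm3 = pi / 6 * axes$a * axes$a * axes$c,
    prolate_mm3 = pi / 6 * axes$a * axes$b * axes$b
  ), class = "EllipsoidEstimates")
}
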