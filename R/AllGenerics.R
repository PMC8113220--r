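#' @name CTVolume-accessors
#' @title Accessors for CTVolume and StoneLabelMap
#' @description Slot accessors: `voxels()` returns the HU array,
#'   `pixelSpacing()` the in-plane spacing `(row_mm, col_mm)`,
#'   `sliceThickness()` the slice thickness in mm, `slicePositions()` the
#'   craniocaudal slice positions, `seriesID()` the series identifier and
#'   `voxelVolume()` the physical volume of one voxel in mm^3.
#'   For label maps, `stoneLabels()` returns the integer label array and
#'   `nStones()` the number of labelled stones.
#' @param x a [CTVolume-class] or [StoneLabelMap-class] object.
#' @return See description; scalars are numeric(1).
NULL

#' @rdname CTVolume-accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname CTVolume-accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname CTVolume-accessors
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))
#' @rdname CTVolume-accessors
#' @export
setGeneric("slicePositions", function(x) standardGeneric("slicePositions"))
#' @rdname CTVolume-accessors
#' @export
setGeneric("seriesID", function(x) standardGeneric("seriesID"))
#' @rdname CTVolume-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname CTVolume-accessors
#' @export
setGeneric("stoneLabels", function(x) standardGeneric("stoneLabels"))
#' @rdname CTVolume-accessors
#' @export
setGeneric("nStones", function(x) standardGeneric("nStones"))

#' @rdname CTVolume-accessors
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)
#' @rdname CTVolume-accessors
#' @export
setMethod("pixelSpacing", "CTVolume", function(x) x@pixelSpacing)
#' @rdname CTVolume-accessors
#' @export
setMethod("sliceThickness", "CTVolume", function(x) x@sliceThickness)
#' @rdname CTVolume-accessors
#' @export
setMethod("slicePositions", "CTVolume", function(x) x@slicePositions)
#' @rdname CTVolume-accessors
#' @export
setMethod("seriesID", "CTVolume", function(x) x@seriesID)
#' @rdname CTVolume-accessors
#' @export
setMethod("voxelVolume", "CTVolume", function(x)
  prod(x@pixelSpacing) * x@sliceThickness)
#' @rdname CTVolume-accessors
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

#' @rdname CTVolume-accessors
#' @export
setMethod("stoneLabels", "StoneLabelMap", function(x) x@labels)
#' @rdname CTVolume-accessors
#' @export
setMethod("nStones", "StoneLabelMap", function(x) x@nStones)
#' @rdname CTVolume-accessors
#' @export
setMethod("dim", "StoneLabelMap", function(x) dim(x@labels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume '%s': %d slices x %d rows x %d cols\n",
              object@seriesID, d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing %.4g x %.4g mm, slice thickness %.4g mm\n",
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@sliceThickness))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "StoneLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("StoneLabelMap: %d stone(s) in %d x %d x %d grid\n",
              object@nStones, d[1], d[2], d[3]))
  if (length(object@params))
    cat(sprintf("  threshold %s HU, connectivity %s, minVoxels %s\n",
                format(object@params$huThreshold),
                format(object@params$connectivity),
                format(object@params$minVoxels)))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson correlation %s vs %s: r = %.4f (n = %d)\n",
              object@pair[1], object@pair[2], object@r, object@n))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("Logistic fit: outcome ~ %s (n = %d)\n",
              object@predictor, object@n))
  cat(sprintf("  intercept %.4f, slope %.4f (SE %.4f), p = %.4g\n",
              object@coefficients[1], object@coefficients[2],
              object@se[2], object@pValue))
  cat(sprintf("  Exp(B) %.4f (95%% CI %.4f-%.4f)\n",
              object@expB, object@ci95ExpB[1], object@ci95ExpB[2]))
  cat(sprintf("  Cox-Snell R2 %.4f, Nagelkerke R2 %.4f\n",
              object@r2CoxSnell, object@r2Nagelkerke))
  if (!object@reliable)
    cat("  WARNING: fit flagged unreliable (separation or non-convergence)\n")
})
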