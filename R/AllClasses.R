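#' CTVolume: a physically calibrated CT voxel grid
#'
#' A 3D grid of Hounsfield-unit (HU) values together with the physical
#' geometry needed to convert voxel counts into millimetre measurements.
#' Axis order is `(slice, row, col)`: the first array dimension indexes
#' axial slices along the craniocaudal direction, the second the image
#' rows ("vertical" on the radiological display), the third the image
#' columns ("horizontal").
#'
#' @slot voxels numeric 3D array of HU values, dimensions
#'   `(slices, rows, cols)`. Kept as floating point after rescale.
#' @slot pixelSpacing numeric(2), in-plane spacing `(row_mm, col_mm)`.
#' @slot sliceThickness numeric(1), slice thickness in mm.
#' @slot slicePositions numeric, craniocaudal position (mm) of each slice,
#'   strictly monotonic, one per slice.
#' @slot seriesID character(1), opaque series identifier.
#'
#' @seealso [ctVolume()] for construction, [readDicomSeries()],
#'   [readRawBundle()], [renderPhantom()].
#' @export
setClass("CTVolume",
  slots = c(
    voxels = "array",
    pixelSpacing = "numeric",
    sliceThickness = "numeric",
    slicePositions = "numeric",
    seriesID = "character"
  )
)

setValidity("CTVolume", function(object) {
  msgs <- character(0)
  d <- dim(object@voxels)
  if (length(d) != 3L)
    msgs <- c(msgs, "voxels must be a 3D array (slice, row, col)")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msgs <- c(msgs, "pixelSpacing must be two positive values (row_mm, col_mm)")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msgs <- c(msgs, "sliceThickness must be a single positive value")
  if (length(d) == 3L) {
    if (d[1] < 1L)
      msgs <- c(msgs, "volume must contain at least one slice")
    if (length(object@slicePositions) != d[1])
      msgs <- c(msgs, "slicePositions must have one entry per slice")
  }
  if (length(object@slicePositions) > 1L) {
    dp <- diff(object@slicePositions)
    if (!(all(dp > 0) || all(dp < 0)))
      msgs <- c(msgs, "slicePositions must be strictly monotonic")
  }
  if (!all(is.finite(object@voxels)))
    msgs <- c(msgs, "all HU values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array of HU values `(slice, row, col)`.
#' @param pixelSpacing numeric(2), `(row_mm, col_mm)`.
#' @param sliceThickness slice thickness in mm.
#' @param slicePositions craniocaudal slice positions in mm; defaults to
#'   slice centres at `(i - 0.5) * sliceThickness`.
#' @param seriesID opaque series identifier.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- ctVolume(array(0, c(3, 4, 4)), c(0.5, 0.5), 1)
#' dim(vol)
#' @export
ctVolume <- function(voxels, pixelSpacing, sliceThickness,
                     slicePositions = NULL, seriesID = "volume") {
  if (is.null(slicePositions))
    slicePositions <- (seq_len(dim(voxels)[1]) - 0.5) * sliceThickness
  new("CTVolume",
      voxels = voxels,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness),
      slicePositions = as.numeric(slicePositions),
      seriesID = as.character(seriesID))
}

#' StoneLabelMap: per-voxel stone instance labels
#'
#' Integer labels congruent with a source [CTVolume-class]: 0 marks
#' background, k marks voxels belonging to stone k. Labels are contiguous
#' 1..nStones, assigned in decreasing order of voxel count.
#'
#' @slot labels integer 3D array, same dimensions as the source volume.
#' @slot nStones integer(1), number of labelled stones.
#' @slot params list, the segmentation parameters used
#'   (`huThreshold`, `connectivity`, `minVoxels`).
#' @seealso [labelStones()], [segmentStones()].
#' @export
setClass("StoneLabelMap",
  slots = c(
    labels = "array",
    nStones = "integer",
    params = "list"
  )
)

setValidity("StoneLabelMap", function(object) {
  msgs <- character(0)
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "labels must be a 3D array")
  lv <- sort(unique(as.integer(object@labels)))
  expected <- 0:object@nStones
  if (!all(lv %in% expected) ||
      !all(seq_len(object@nStones) %in% lv))
    msgs <- c(msgs, "label values must be exactly {0, 1, ..., nStones}")
  if (length(msgs)) msgs else TRUE
})

#' CorrelationResult: a Pearson product-moment correlation
#'
#' @slot pair character(2), labels of the correlated variables.
#' @slot r numeric(1), Pearson r in [-1, 1].
#' @slot n integer(1), number of paired observations.
#' @seealso [pearsonR()]
#' @export
setClass("CorrelationResult",
  slots = c(pair = "character", r = "numeric", n = "integer")
)

setValidity("CorrelationResult", function(object) {
  msgs <- character(0)
  if (abs(object@r) > 1 + 1e-12) msgs <- c(msgs, "|r| must be <= 1")
  if (object@n < 3L) msgs <- c(msgs, "n must be >= 3")
  if (length(msgs)) msgs else TRUE
})

#' LogisticFit: a univariable binary logistic regression
#'
#' Maximum-likelihood fit of `logit P(y = 1) = b0 + b1 x` by iteratively
#' reweighted least squares, with Wald inference on the slope and the
#' Cox-Snell and Nagelkerke pseudo R-squared computed against the
#' intercept-only null model.
#'
#' @slot predictor character(1), predictor label.
#' @slot coefficients numeric(2), `(intercept, slope)`.
#' @slot se numeric(2), Wald standard errors.
#' @slot expB numeric(1), odds ratio per unit predictor, `exp(slope)`.
#' @slot ci95ExpB numeric(2), 95% Wald CI for the odds ratio.
#' @slot pValue numeric(1), two-sided Wald p-value for the slope.
#' @slot loglikNull,loglikModel numeric(1), log-likelihoods of the
#'   intercept-only and fitted models.
#' @slot n integer(1), observations used.
#' @slot r2CoxSnell,r2Nagelkerke numeric(1), pseudo R-squared values.
#' @slot converged logical(1), IRLS convergence flag.
#' @slot reliable logical(1), FALSE when (quasi-)complete separation or
#'   non-convergence makes the Wald machinery untrustworthy.
#' @seealso [fitLogistic()], [nagelkerkeR2()], [rankPredictors()]
#' @export
setClass("LogisticFit",
  slots = c(
    predictor = "character",
    coefficients = "numeric",
    se = "numeric",
    expB = "numeric",
    ci95ExpB = "numeric",
    pValue = "numeric",
    loglikNull = "numeric",
    loglikModel = "numeric",
    n = "integer",
    r2CoxSnell = "numeric",
    r2Nagelkerke = "numeric",
    converged = "logical",
    reliable = "logical"
  )
)

setValidity("LogisticFit", function(object) {
  msgs <- character(0)
  if (object@loglikModel < object@loglikNull - 1e-8)
    msgs <- c(msgs, "model log-likelihood cannot be below the null's")
  if (object@r2Nagelkerke < -1e-12 || object@r2Nagelkerke > 1 + 1e-12)
    msgs <- c(msgs, "Nagelkerke R2 must lie in [0, 1]")
  if (object@r2CoxSnell > object@r2Nagelkerke + 1e-12)
    msgs <- c(msgs, "Cox-Snell R2 cannot exceed Nagelkerke R2")
  if (object@reliable &&
      (object@expB < object@ci95ExpB[1] - 1e-12 ||
       object@expB > object@ci95ExpB[2] + 1e-12))
    msgs <- c(msgs, "ci95ExpB must bracket expB")
  if (length(msgs)) msgs else TRUE
})
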