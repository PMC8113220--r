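# Raw-volume bundle and metrics JSON I/O.

#' Write / read a raw volume bundle
#'
#' A platform-neutral serialization of a [CTVolume-class]: the HU grid as
#' little-endian float64 in `(slice, row, col)` C order, plus a JSON
#' metadata file carrying `grid_shape`, `pixel_spacing`,
#' `slice_thickness`, `slice_positions` and `series_id`.
#'
#' @param volume a [CTVolume-class].
#' @param volumeFile path for the binary grid.
#' @param metadataFile path for the JSON metadata.
#' @return `writeRawBundle()` returns the paths invisibly;
#'   `readRawBundle()` returns a [CTVolume-class].
#' @export
writeRawBundle <- function(volume, volumeFile, metadataFile) {
  stopifnot(is(volume, "CTVolume"))
  d <- dim(volume)
  # C order (col fastest): permute so R's column-major write matches
  con <- file(volumeFile, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(volume@voxels, c(3, 2, 1))), con,
           size = 8, endian = "little")
  meta <- list(
    grid_shape = d,
    pixel_spacing = volume@pixelSpacing,
    slice_thickness = volume@sliceThickness,
    slice_positions = volume@slicePositions,
    series_id = volume@seriesID
  )
  jsonlite::write_json(meta, metadataFile, digits = NA, auto_unbox = FALSE)
  invisible(c(volumeFile, metadataFile))
}

#' @rdname writeRawBundle
#' @export
readRawBundle <- function(volumeFile, metadataFile) {
  meta <- jsonlite::read_json(metadataFile, simplifyVector = TRUE)
  shape <- as.integer(meta$grid_shape)
  if (length(shape) != 3L)
    stop("geometry error: metadata grid_shape must have 3 entries")
  n <- prod(shape)
  vals <- readBin(volumeFile, numeric(), n = n + 1L, size = 8,
                  endian = "little")
  if (length(vals) != n)
    stop("geometry error: volume file holds ", length(vals),
         " values but metadata declares ", n)
  vox <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  ctVolume(vox,
           pixelSpacing = as.numeric(meta$pixel_spacing),
           sliceThickness = as.numeric(meta$slice_thickness),
           slicePositions = as.numeric(meta$slice_positions),
           seriesID = as.character(meta$series_id))
}

#' Write / read per-stone metrics as JSON
#'
#' Serializes a stone metrics table (one row per stone, as returned by
#' [measureStones()]) to a versioned JSON document. All lengths are mm,
#' areas mm^2, volumes mm^3, as the column names state.
#'
#' @param metrics data.frame of per-stone metrics.
#' @param out output path.
#' @param path path of a metrics JSON document.
#' @return `readMetrics()` returns the metrics data.frame (zero rows for
#'   an empty stone list).
#' @export
writeMetrics <- function(metrics, out) {
  stopifnot(is.data.frame(metrics))
  doc <- list(
    schema = "stonevol-metrics",
    schema_version = 1L,
    stones = metrics
  )
  ok <- tryCatch({
    jsonlite::write_json(doc, out, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error writing metrics to ", out, ": ",
         conditionMessage(ok))
  invisible(out)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "stonevol-metrics"))
    stop("not a stonevol metrics document: ", path)
  st <- doc$stones
  if (is.null(st) || length(st) == 0L) return(emptyMetrics())
  as.data.frame(st)
}

emptyMetrics <- function() {
  data.frame(
    stone_id = integer(0),
    voxel_count = integer(0),
    volume_mm3 = numeric(0),
    major_horizontal_axis_mm = numeric(0),
    major_vertical_axis_mm = numeric(0),
    largest_slice_area_mm2 = numeric(0),
    largest_slice_index = integer(0),
    craniocaudal_extent_mm = numeric(0)
  )
}
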