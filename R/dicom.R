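# Minimal single-frame CT DICOM codec (explicit VR little endian).
#
# Covers exactly the attributes the volumetry pipeline needs: pixel
# geometry, slice position/thickness, rescale slope/intercept and 16-bit
# signed pixel data. Multi-frame objects, compressed transfer syntaxes,
# sequences and gantry tilt are out of scope.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")

# one explicit-VR element as a raw vector; `value` is raw for OW, a string
# for string VRs, an integer vector for US
dcmElement <- function(group, element, vr, value) {
  if (vr == "US") {
    v <- uint16le(value)
  } else if (vr == "OW") {
    v <- value
  } else {
    v <- charToRaw(as.character(value))
    if (length(v) %% 2L == 1L)
      v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  hdr <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), uint32le(length(v)), v)
  } else {
    c(hdr, uint16le(length(v)), v)
  }
}

# Write one axial slice. `hu` is a rows x cols matrix in HU; stored values
# are round((hu - intercept) / slope), written row-major as signed int16.
writeDicomSlice <- function(path, hu, pixelSpacing, sliceThickness,
                            slicePosition, seriesUID, instanceNumber,
                            rescaleSlope = 1, rescaleIntercept = -1024,
                            includeThickness = TRUE) {
  stored <- round((hu - rescaleIntercept) / rescaleSlope)
  if (any(stored < -32768 | stored > 32767))
    stop("stored pixel values exceed the signed 16-bit range")
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

  meta <- dcmElement(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE)
  ds <- c(
    dcmElement(0x0008, 0x0016, "UI", SOP_CLASS_CT),
    dcmElement(0x0008, 0x0018, "UI",
               paste0(seriesUID, ".", instanceNumber)),
    dcmElement(0x0008, 0x0060, "CS", "CT"),
    if (includeThickness)
      dcmElement(0x0018, 0x0050, "DS", format(sliceThickness, digits = 15)),
    dcmElement(0x0020, 0x000E, "UI", seriesUID),
    dcmElement(0x0020, 0x0013, "IS", as.character(instanceNumber)),
    dcmElement(0x0020, 0x0032, "DS",
               paste(c("0", "0", format(slicePosition, digits = 15)),
                     collapse = "\\")),
    dcmElement(0x0028, 0x0002, "US", 1L),
    dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcmElement(0x0028, 0x0010, "US", nrow(hu)),
    dcmElement(0x0028, 0x0011, "US", ncol(hu)),
    dcmElement(0x0028, 0x0030, "DS",
               paste(format(pixelSpacing, digits = 15), collapse = "\\")),
    dcmElement(0x0028, 0x0100, "US", 16L),
    dcmElement(0x0028, 0x0101, "US", 16L),
    dcmElement(0x0028, 0x0102, "US", 15L),
    dcmElement(0x0028, 0x0103, "US", 1L),
    dcmElement(0x0028, 0x1052, "DS", format(rescaleIntercept, digits = 15)),
    dcmElement(0x0028, 0x1053, "DS", format(rescaleSlope, digits = 15)),
    dcmElement(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcmGroupLength(length(meta)), con)
  writeBin(meta, con)
  writeBin(ds, con)
  invisible(path)
}

# (0002,0000) file-meta group length: UL holds a binary uint32, not a string
dcmGroupLength <- function(nbytes) {
  c(uint16le(0x0002), uint16le(0x0000), charToRaw("UL"),
    uint16le(4L), uint32le(nbytes))
}

# Parse one single-frame explicit-VR-LE DICOM file into a list of the
# attributes of interest.
readDicomFile <- function(path) {
  raw <- readBin(path, raw(), n = file.info(path)$size)
  if (length(raw) < 132L ||
      rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  out <- list()
  u16 <- function(i) readBin(raw[i:(i + 1L)], integer(), size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(raw[i:(i + 3L)], integer(), size = 4,
                             endian = "little")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    vend <- vstart + len - 1L
    if (len > 0 && vend > length(raw))
      stop("truncated DICOM element in ", path)
    val <- if (len > 0) raw[vstart:vend] else raw(0)
    tag <- sprintf("%04X%04X", group, element)
    out[[tag]] <- list(vr = vr, value = val)
    pos <- vend + 1L
  }
  getStr <- function(tag) {
    e <- out[[tag]]
    if (is.null(e)) return(NULL)
    trimws(rawToChar(e$value[e$value != as.raw(0L)]))
  }
  getNum <- function(tag) {
    s <- getStr(tag)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  getUS <- function(tag) {
    e <- out[[tag]]
    if (is.null(e)) return(NULL)
    readBin(e$value, integer(), n = length(e$value) / 2L, size = 2,
            signed = FALSE, endian = "little")
  }
  rows <- getUS("00280010"); cols <- getUS("00280011")
  pixElem <- out[["7FE00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pixElem))
    stop("DICOM file lacks image dimensions or pixel data: ", path)
  signed <- isTRUE(getUS("00280103") == 1L)
  stored <- readBin(pixElem$value, integer(),
                    n = length(pixElem$value) / 2L, size = 2,
                    signed = signed, endian = "little")
  slope <- getNum("00281053"); intercept <- getNum("00281052")
  if (is.null(slope)) slope <- 1
  if (is.null(intercept)) intercept <- 0
  hu <- matrix(stored * slope + intercept, nrow = cols, ncol = rows)
  pos3 <- getNum("00200032")
  list(
    hu = t(hu),                              # rows x cols
    rows = rows, cols = cols,
    pixelSpacing = getNum("00280030"),       # (row_mm, col_mm)
    sliceThickness = getNum("00180050"),
    slicePosition = if (!is.null(pos3)) pos3[3] else NA_real_,
    seriesUID = getStr("0020000E")
  )
}

#' Read a DICOM series into a CTVolume
#'
#' Reads every single-frame CT file in `directory`, applies the stored
#' rescale (`stored * RescaleSlope + RescaleIntercept`) so voxels are in
#' HU, and stacks the slices sorted by craniocaudal position. Slice
#' thickness is taken from the slice-thickness attribute; when absent it
#' falls back to the median inter-slice position difference, and a warning
#' is issued if the two disagree by more than 10%.
#'
#' @param directory path containing one DICOM series (>= 1 file).
#' @return A [CTVolume-class] in HU with axis order `(slice, row, col)`.
#' @seealso [writePhantomDicom()] for the matching writer.
#' @export
readDicomSeries <- function(directory) {
  files <- sort(list.files(directory, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no input: directory contains no files: ", directory)
  slices <- lapply(files, readDicomFile)

  uids <- unique(vapply(slices, function(s)
    if (is.null(s$seriesUID)) "" else s$seriesUID, character(1)))
  if (length(uids) > 1L)
    stop("ambiguous series: directory mixes series identifiers: ",
         paste(uids, collapse = ", "))
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols),
                          integer(2))))
  if (nrow(dims) > 1L)
    stop("geometry error: slices have inconsistent in-plane dimensions")

  z <- vapply(slices, function(s) s$slicePosition, numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]

  vox <- array(NA_real_, c(length(slices), dims[1, 1], dims[1, 2]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$hu

  thkAttr <- slices[[1]]$sliceThickness
  thkGap <- if (length(z) > 1L) stats::median(diff(z)) else NA_real_
  if (is.null(thkAttr) || length(thkAttr) == 0L || is.na(thkAttr)) {
    if (is.na(thkGap))
      stop("geometry error: single slice with no slice-thickness attribute")
    thk <- thkGap
  } else {
    thk <- thkAttr
    if (!is.na(thkGap) && thkGap > 0 &&
        abs(thkAttr - thkGap) / thkGap > 0.10)
      warning(sprintf(
        "slice-thickness attribute (%.4g mm) disagrees with inter-slice spacing (%.4g mm) by > 10%%",
        thkAttr, thkGap))
  }

  ctVolume(vox,
           pixelSpacing = slices[[1]]$pixelSpacing,
           sliceThickness = thk,
           slicePositions = z,
           seriesID = if (is.null(slices[[1]]$seriesUID)) "series"
                      else slices[[1]]$seriesUID)
}

#' Write a CTVolume as a DICOM series
#'
#' Emits one single-frame explicit-VR little-endian CT file per slice,
#' carrying pixel spacing, slice thickness, slice positions and rescale
#' attributes such that [readDicomSeries()] round-trips the volume
#' (HU values are quantized to the integer stored-value grid).
#'
#' @param volume a [CTVolume-class].
#' @param directory output directory (created if needed).
#' @param rescaleSlope,rescaleIntercept stored-value affine calibration;
#'   the defaults mirror common CT calibration (slope 1, intercept -1024).
#' @param includeThickness if FALSE, omit the slice-thickness attribute
#'   (readers then fall back to inter-slice spacing).
#' @return Invisibly, the vector of files written.
#' @export
writePhantomDicom <- function(volume, directory,
                              rescaleSlope = 1, rescaleIntercept = -1024,
                              includeThickness = TRUE) {
  stopifnot(is(volume, "CTVolume"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", directory)
  d <- dim(volume)
  files <- character(d[1])
  for (i in seq_len(d[1])) {
    files[i] <- file.path(directory, sprintf("slice_%04d.dcm", i))
    writeDicomSlice(files[i],
                    hu = volume@voxels[i, , ],
                    pixelSpacing = volume@pixelSpacing,
                    sliceThickness = volume@sliceThickness,
                    slicePosition = volume@slicePositions[i],
                    seriesUID = volume@seriesID,
                    instanceNumber = i,
                    rescaleSlope = rescaleSlope,
                    rescaleIntercept = rescaleIntercept,
                    includeThickness = includeThickness)
  }
  invisible(files)
}
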