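# Synthetic CT phantoms: ellipsoidal stones of analytically known
# geometry rendered into an axial HU stack, so segmentation and
# morphometry can be validated against closed-form ground truth.

#' Specify a synthetic stone
#'
#' An ellipsoid with known centre, full axis lengths (diameters), 3D
#' orientation and HU statistics. Its analytic volume
#' `pi/6 * d1 * d2 * d3` is stored with the spec as ground truth.
#'
#' @param centerMm numeric(3), centre in physical `(z, y, x)` mm.
#' @param diametersMm numeric(3), full axis lengths `(d1, d2, d3)` in mm,
#'   aligned with the stone's local x/y/z axes before rotation.
#' @param rotationDeg numeric(3), intrinsic z-y-x Euler angles in degrees.
#' @param stoneHuMean,stoneHuSd stone HU mean and per-voxel noise SD.
#' @return A list of class `StoneSpec` including `analyticVolumeMm3`.
#' @export
stoneSpec <- function(centerMm, diametersMm, rotationDeg = c(0, 0, 0),
                      stoneHuMean = 800, stoneHuSd = 0) {
  stopifnot(length(centerMm) == 3L, length(diametersMm) == 3L,
            length(rotationDeg) == 3L)
  if (any(diametersMm <= 0)) stop("diameters must be positive")
  if (stoneHuSd < 0) stop("stoneHuSd must be >= 0")
  structure(list(
    centerMm = as.numeric(centerMm),
    diametersMm = as.numeric(diametersMm),
    rotationDeg = as.numeric(rotationDeg),
    stoneHuMean = stoneHuMean,
    stoneHuSd = stoneHuSd,
    analyticVolumeMm3 = pi / 6 * prod(diametersMm)
  ), class = "StoneSpec")
}

#' Specify a synthetic CT phantom
#'
#' Grid geometry, the stones it contains and the HU noise/blur model.
#' Defaults emulate typical renal-stone contrast on CT KUB: soft-tissue
#' background 30 +/- 15 HU, stones around 800 HU, 0.4 mm reconstruction
#' blur. These are rendering fixtures, not claims about any scanner.
#'
#' @param gridShape integer(3), `(slices, rows, cols)`.
#' @param pixelSpacing numeric(2), in-plane `(row_mm, col_mm)`.
#' @param sliceThickness slice thickness in mm.
#' @param stones list of [stoneSpec()] objects (possibly empty).
#' @param backgroundHuMean,backgroundHuSd background HU mean / noise SD.
#' @param blurSigmaMm isotropic Gaussian blur sigma in mm (0 disables).
#' @param seed integer RNG seed for the noise field.
#' @return A list of class `PhantomSpec`.
#' @export
phantomSpec <- function(gridShape, pixelSpacing = c(0.5, 0.5),
                        sliceThickness = 0.5, stones = list(),
                        backgroundHuMean = 30, backgroundHuSd = 15,
                        blurSigmaMm = 0.4, seed = 1L) {
  stopifnot(length(gridShape) == 3L, length(pixelSpacing) == 2L)
  if (any(pixelSpacing <= 0) || sliceThickness <= 0)
    stop("all spacings must be positive")
  if (blurSigmaMm < 0 || backgroundHuSd < 0)
    stop("blurSigmaMm and backgroundHuSd must be >= 0")
  if (inherits(stones, "StoneSpec")) stones <- list(stones)
  extent <- c(gridShape[1] * sliceThickness,
              gridShape[2] * pixelSpacing[1],
              gridShape[3] * pixelSpacing[2])
  for (s in stones) {
    if (s$stoneHuMean <= backgroundHuMean)
      stop("stone HU mean must exceed background HU mean")
    r <- max(s$diametersMm) / 2   # enclosing sphere, conservative
    if (any(s$centerMm - r < 0) || any(s$centerMm + r > extent))
      stop("geometry error: stone extends outside the grid's physical extent")
  }
  structure(list(
    gridShape = as.integer(gridShape),
    pixelSpacing = as.numeric(pixelSpacing),
    sliceThickness = as.numeric(sliceThickness),
    stones = stones,
    backgroundHuMean = backgroundHuMean,
    backgroundHuSd = backgroundHuSd,
    blurSigmaMm = blurSigmaMm,
    seed = as.integer(seed)
  ), class = "PhantomSpec")
}

#' Render a phantom into a CTVolume
#'
#' Each voxel whose centre lies inside a stone's rotated ellipsoid takes
#' the stone's HU mean (plus per-voxel Gaussian noise at the stone's SD);
#' all other voxels take the background mean (plus background noise).
#' Noise is added before the Gaussian blur, mimicking reconstruction
#' smoothing of detector noise. Rendering is deterministic for a fixed
#' `spec$seed`.
#'
#' The inside test uses voxel centres (matching the per-voxel threshold
#' behaviour of the segmentation the phantom exists to exercise); set
#' `supersample = TRUE` for a 3x3x3 subvoxel majority test in
#' convergence studies.
#'
#' @param spec a [phantomSpec()].
#' @param supersample logical; 3x supersampled inside test.
#' @return A list with `volume` (a [CTVolume-class]) and `manifest`
#'   (ground truth: per stone centre, diameters, rotation and analytic
#'   volume `pi/6 * d1 * d2 * d3`).
#' @examples
#' ph <- phantomSpec(c(24, 32, 32), c(0.5, 0.5), 0.5,
#'                   stones = stoneSpec(c(6, 8, 8), c(5, 4, 3)),
#'                   backgroundHuSd = 0, blurSigmaMm = 0)
#' rp <- renderPhantom(ph)
#' rp$manifest$stones[[1]]$analytic_volume_mm3
#' @export
renderPhantom <- function(spec, supersample = FALSE) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$gridShape
  zc <- (seq_len(d[1]) - 0.5) * spec$sliceThickness
  yc <- (seq_len(d[2]) - 0.5) * spec$pixelSpacing[1]
  xc <- (seq_len(d[3]) - 0.5) * spec$pixelSpacing[2]

  inside <- array(0L, d)   # index of owning stone, 0 = background
  for (k in seq_along(spec$stones)) {
    s <- spec$stones[[k]]
    hit <- insideEllipsoid(s, zc, yc, xc, d, supersample,
                           dz = spec$sliceThickness,
                           dy = spec$pixelSpacing[1],
                           dx = spec$pixelSpacing[2])
    inside[hit] <- k
  }

  vox <- withSeed(spec$seed, {
    v <- array(spec$backgroundHuMean, d)
    if (spec$backgroundHuSd > 0)
      v <- v + array(stats::rnorm(prod(d), 0, spec$backgroundHuSd), d)
    for (k in seq_along(spec$stones)) {
      s <- spec$stones[[k]]
      idx <- which(inside == k)
      v[idx] <- s$stoneHuMean +
        if (s$stoneHuSd > 0) stats::rnorm(length(idx), 0, s$stoneHuSd) else 0
    }
    v
  })

  if (spec$blurSigmaMm > 0) {
    sigmaVox <- spec$blurSigmaMm /
      c(spec$sliceThickness, spec$pixelSpacing[1], spec$pixelSpacing[2])
    vox <- gaussianBlur3D(vox, sigmaVox)
  }

  manifest <- list(stones = lapply(seq_along(spec$stones), function(k) {
    s <- spec$stones[[k]]
    list(stone_id = k,
         center_mm = s$centerMm,
         diameters_mm = s$diametersMm,
         rotation_deg = s$rotationDeg,
         analytic_volume_mm3 = s$analyticVolumeMm3)
  }))

  list(volume = ctVolume(vox, spec$pixelSpacing, spec$sliceThickness,
                         slicePositions = zc,
                         seriesID = sprintf("phantom-%d", spec$seed)),
       manifest = manifest)
}

# logical array: which voxels fall inside the rotated ellipsoid.
# Works on the stone's bounding box only.
insideEllipsoid <- function(s, zc, yc, xc, d, supersample, dz, dy, dx) {
  R <- eulerRotation(s$rotationDeg)
  radii <- s$diametersMm / 2
  rmax <- max(radii)
  zi <- which(zc >= s$centerMm[1] - rmax - dz & zc <= s$centerMm[1] + rmax + dz)
  yi <- which(yc >= s$centerMm[2] - rmax - dy & yc <= s$centerMm[2] + rmax + dy)
  xi <- which(xc >= s$centerMm[3] - rmax - dx & xc <= s$centerMm[3] + rmax + dx)
  out <- array(FALSE, d)
  if (!length(zi) || !length(yi) || !length(xi)) return(out)
  g <- expand.grid(z = zc[zi], y = yc[yi], x = xc[xi])
  testPts <- function(px, py, pz) {
    # rotate physical offsets into the stone frame: q = R^T (p - c)
    ox <- px - s$centerMm[3]; oy <- py - s$centerMm[2]; oz <- pz - s$centerMm[1]
    q1 <- R[1, 1] * ox + R[2, 1] * oy + R[3, 1] * oz
    q2 <- R[1, 2] * ox + R[2, 2] * oy + R[3, 2] * oz
    q3 <- R[1, 3] * ox + R[2, 3] * oy + R[3, 3] * oz
    (q1 / radii[1])^2 + (q2 / radii[2])^2 + (q3 / radii[3])^2 <= 1
  }
  if (!supersample) {
    hit <- testPts(g$x, g$y, g$z)
  } else {
    off <- c(-1, 0, 1) / 3
    votes <- 0L
    for (oz in off) for (oy in off) for (ox in off)
      votes <- votes + testPts(g$x + ox * dx, g$y + oy * dy, g$z + oz * dz)
    hit <- votes > 13L   # majority of the 27 subsamples
  }
  sub <- as.matrix(expand.grid(zi = zi, yi = yi, xi = xi))
  out[sub[hit, , drop = FALSE]] <- TRUE
  out
}
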