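# HU-threshold stone segmentation: a global Hounsfield threshold selects
# every voxel that could represent stone rather than soft tissue or
# urine, and 3D connected components group those voxels into individual
# stones. Thresholding is deliberately the whole delineation step — no
# morphological clean-up — so the voxel count is exactly what the
# threshold admits.

#' Segmentation parameters
#'
#' @param huThreshold HU cut-off; voxels with HU >= threshold are
#'   candidate stone. The 130 HU default is the conventional
#'   calcification cut-off; the workflow treats it as per-case tunable.
#' @param connectivity 6 (face neighbours) or 26 (face+edge+corner, the
#'   default: a stone spanning slices with sub-voxel lateral shift stays
#'   one object).
#' @param minVoxels components smaller than this are discarded
#'   (default 2 suppresses single-voxel noise speckle; 1 disables).
#' @return A list of class `SegmentationParams`.
#' @export
segmentationParams <- function(huThreshold = 130, connectivity = 26L,
                               minVoxels = 2L) {
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  if (minVoxels < 1L) stop("minVoxels must be >= 1")
  structure(list(huThreshold = huThreshold,
                 connectivity = as.integer(connectivity),
                 minVoxels = as.integer(minVoxels)),
            class = "SegmentationParams")
}

#' Threshold a CT volume
#'
#' @param volume a [CTVolume-class].
#' @param huThreshold HU cut-off (inclusive: mask is TRUE exactly where
#'   HU >= threshold).
#' @return A logical array congruent with the volume.
#' @export
thresholdMask <- function(volume, huThreshold = 130) {
  stopifnot(is(volume, "CTVolume"))
  volume@voxels >= huThreshold
}

#' Group a binary mask into labelled stones
#'
#' Connected components of the foreground under the requested voxel
#' adjacency; components below `minVoxels` are dropped and the remainder
#' relabelled 1..n by decreasing voxel count (ties broken by the
#' lexicographically smallest `(slice, row, col)` voxel).
#'
#' @param mask logical 3D array (e.g. from [thresholdMask()]).
#' @param params a [segmentationParams()].
#' @return A [StoneLabelMap-class].
#' @export
labelStones <- function(mask, params = segmentationParams()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (length(fg) == 0L)
    return(new("StoneLabelMap", labels = lab, nStones = 0L,
               params = unclass(params)))

  ids <- array(0L, d)
  ids[fg] <- seq_along(fg)

  offsets <- connectivityOffsets(params$connectivity)
  edges <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    az <- seq_len(d[1] - abs(o[1])); bz <- az + abs(o[1])
    if (o[1] < 0) { tmp <- az; az <- bz; bz <- tmp }
    ay <- seq_len(d[2] - abs(o[2])); by <- ay + abs(o[2])
    if (o[2] < 0) { tmp <- ay; ay <- by; by <- tmp }
    ax <- seq_len(d[3] - abs(o[3])); bx <- ax + abs(o[3])
    if (o[3] < 0) { tmp <- ax; ax <- bx; bx <- tmp }
    A <- ids[az, ay, ax, drop = FALSE]
    B <- ids[bz, by, bx, drop = FALSE]
    keep <- A > 0L & B > 0L
    if (any(keep)) edges[[i]] <- cbind(A[keep], B[keep])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && nrow(em) > 0L)
    g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)$membership

  # size filter, then order by decreasing size with lexicographic
  # (slice,row,col) tie-break on each component's smallest voxel
  sizes <- tabulate(comp)
  keepComp <- which(sizes >= params$minVoxels)
  if (length(keepComp) == 0L)
    return(new("StoneLabelMap", labels = lab, nStones = 0L,
               params = unclass(params)))
  sub <- arrayInd(fg, d)   # (slice, row, col) per foreground voxel
  lex <- order(sub[, 1], sub[, 2], sub[, 3])
  firstLex <- integer(max(comp))
  for (i in rev(seq_along(lex)))
    firstLex[comp[lex[i]]] <- i   # last write = lex-smallest voxel's rank
  rank <- order(-sizes[keepComp], firstLex[keepComp])
  newLabel <- integer(max(comp))
  newLabel[keepComp[rank]] <- seq_along(keepComp)
  lab[fg] <- newLabel[comp]
  new("StoneLabelMap", labels = lab, nStones = length(keepComp),
      params = unclass(params))
}

# half-space neighbour offsets (each unordered pair once)
connectivityOffsets <- function(connectivity) {
  if (connectivity == 6L) {
    matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  } else {
    g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    # lexicographically positive half
    pos <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
    unname(g[pos, , drop = FALSE])
  }
}

#' Threshold and label in one step
#'
#' @param volume a [CTVolume-class].
#' @param params a [segmentationParams()].
#' @return A [StoneLabelMap-class].
#' @examples
#' ph <- phantomSpec(c(24, 32, 32), c(0.5, 0.5), 0.5,
#'                   stones = stoneSpec(c(6, 8, 8), c(5, 4, 3)),
#'                   backgroundHuSd = 0, blurSigmaMm = 0)
#' vol <- renderPhantom(ph)$volume
#' nStones(segmentStones(vol))
#' @export
segmentStones <- function(volume, params = segmentationParams()) {
  labelStones(thresholdMask(volume, params$huThreshold), params)
}
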