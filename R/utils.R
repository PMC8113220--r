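# internal helpers

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Separable Gaussian blur of a 3D array, sigma given per axis in voxels.
# Reflection padding at the borders; sigma of 0 along an axis is a no-op.
gaussianBlur3D <- function(a, sigmaVox) {
  stopifnot(length(dim(a)) == 3L, length(sigmaVox) == 3L)
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    n <- dim(a)[axis]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    # dense n x n convolution matrix with reflected indices
    K <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n) + j
      idx[idx < 1L] <- 2L - idx[idx < 1L]        # reflect low edge
      idx[idx > n] <- 2L * n - idx[idx > n]      # reflect high edge
      K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + k[j + r + 1L]
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, nrow = dp[1])
    dim(m) <- dp
    a <- aperm(m, order(perm))
  }
  a
}

# Rotation matrix from intrinsic z-y-x Euler angles in degrees, acting on
# physical (x, y, z) coordinates.
eulerRotation <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}
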