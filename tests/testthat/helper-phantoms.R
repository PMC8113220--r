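# Shared fixture builders: small deterministic phantoms.

# noise-free, blur-free phantom holding one axis-aligned ellipsoid near
# the grid centre. The centre is offset by a grid-incommensurate amount:
# a stone centred exactly on voxel boundaries is a degenerate alignment
# real scans never show, and it can make digitization errors tie across
# resolutions.
cleanEllipsoidPhantom <- function(diameters, spacing = 0.5,
                                  thickness = spacing, margin = 2,
                                  rotationDeg = c(0, 0, 0),
                                  stoneHu = 800, backgroundHu = 30) {
  half <- max(diameters) / 2 + margin
  shape <- c(ceiling(2 * half / thickness),
             ceiling(2 * half / spacing),
             ceiling(2 * half / spacing))
  center <- c(shape[1] * thickness, shape[2] * spacing,
              shape[3] * spacing) / 2 + c(0.137, 0.071, -0.053)
  phantomSpec(shape, c(spacing, spacing), thickness,
              stones = stoneSpec(center, diameters,
                                 rotationDeg = rotationDeg,
                                 stoneHuMean = stoneHu),
              backgroundHuMean = backgroundHu,
              backgroundHuSd = 0, blurSigmaMm = 0)
}

# midpoint threshold between the helper's background and stone HU
MID_HU <- (800 + 30) / 2

# Table 3 worked-example fragment records shipped with the package
fragmentGroups <- function() {
  fr <- exampleFragments()
  list(cirf = fr[fr$group == "stone_free_with_cirfs", ],
       notFree = fr[fr$group == "not_stone_free", ])
}

# brute-force Bernoulli log-likelihood for the logistic model
bruteLoglik <- function(b0, b1, y, x) {
  sum(stats::dbinom(y, 1, stats::plogis(b0 + b1 * x), log = TRUE))
}

# independent oracle: maximise the logistic likelihood by nested grid
# refinement (no IRLS, no glm)
gridLogistic <- function(y, x, center = c(0, 0), width = c(10, 10),
                         stages = 6, pts = 41) {
  best <- center
  for (s in seq_len(stages)) {
    b0s <- seq(best[1] - width[1], best[1] + width[1], length.out = pts)
    b1s <- seq(best[2] - width[2], best[2] + width[2], length.out = pts)
    ll <- outer(b0s, b1s, Vectorize(function(b0, b1)
      bruteLoglik(b0, b1, y, x)))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(b0s[idx[1]], b1s[idx[2]])
    width <- width * 2.5 / (pts - 1)   # shrink around the argmax
  }
  list(coef = best, loglik = bruteLoglik(best[1], best[2], y, x))
}
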