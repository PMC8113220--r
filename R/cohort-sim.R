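# Simulated SWL treatment cohorts: log-normal stone volumes, random
# ellipsoid axes of matching volume, multiplicative measurement noise and
# a logistic stone-free outcome model. A synthetic twin of a treated
# cohort's structure, used to exercise the statistical layer.

#' Specify a simulated treatment cohort
#'
#' Defaults are calibrated to a published 72-case SWL cohort: stone
#' volume log-normal with median 113 mm^3 and IQR 62-276 mm^3
#' (`meanlog = log(113)`, `sdlog = 1.107`), a stone-free odds ratio of
#' 0.994 per mm^3 (`slope = log(0.994)`) and an intercept placing the
#' stone-free probability at the median volume near 44%, and 5%
#' multiplicative measurement noise.
#'
#' @param nCases number of cases (>= 1).
#' @param volumeMeanlog,volumeSdlog log-normal parameters of the true
#'   stone volume in mm^3.
#' @param outcomeIntercept,outcomeSlope logistic model of the binary
#'   stone-free outcome: `logit P(stone_free) = intercept + slope * volume`.
#' @param measurementNoiseSd SD of the multiplicative Gaussian
#'   measurement error (fraction; 0 means measured = true).
#' @param seed integer RNG seed.
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(nCases = 72L,
                       volumeMeanlog = log(113), volumeSdlog = 1.107,
                       outcomeIntercept = 0.45,
                       outcomeSlope = log(0.994),
                       measurementNoiseSd = 0.05,
                       seed = 1L) {
  if (nCases < 1L) stop("nCases must be >= 1")
  if (measurementNoiseSd < 0) stop("measurementNoiseSd must be >= 0")
  structure(list(
    nCases = as.integer(nCases),
    volumeMeanlog = volumeMeanlog,
    volumeSdlog = volumeSdlog,
    outcomeIntercept = outcomeIntercept,
    outcomeSlope = outcomeSlope,
    measurementNoiseSd = measurementNoiseSd,
    seed = as.integer(seed)
  ), class = "CohortSpec")
}

#' Simulate a treatment cohort
#'
#' Draws per-case true stone volumes from the spec's log-normal, derives
#' the three axis lengths of a random ellipsoid of that exact volume
#' (log-normal aspect ratios), applies multiplicative measurement noise
#' (`measured = true * (1 + e)`, `e ~ N(0, sd)`) to the volume and axes,
#' and draws the binary stone-free outcome with probability
#' `plogis(intercept + slope * true_volume)`. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [cohortSpec()].
#' @return A data.frame with columns `case_id`, `true_volume_mm3`,
#'   `true_axis_a_mm`, `true_axis_b_mm`, `true_axis_c_mm` (sorted
#'   a >= c >= b), measured counterparts (`measured_*`), and
#'   `stone_free` (1 = stone-free).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$nCases
  withSeed(spec$seed, {
    vol <- stats::rlnorm(n, spec$volumeMeanlog, spec$volumeSdlog)
    # random ellipsoid of exactly that volume: draw two log-normal
    # aspect ratios, then scale so pi/6 * d1 * d2 * d3 = volume
    r1 <- stats::rlnorm(n, 0, 0.25)
    r2 <- stats::rlnorm(n, 0, 0.25)
    base <- (6 * vol / (pi * r1 * r2))^(1 / 3)
    dmat <- cbind(base * r1, base * r2, base)
    dsort <- t(apply(dmat, 1, sort, decreasing = TRUE))
    a <- dsort[, 1]; c_ <- dsort[, 2]; b <- dsort[, 3]

    noisy <- function(x) {
      if (spec$measurementNoiseSd == 0) x
      else x * (1 + stats::rnorm(length(x), 0, spec$measurementNoiseSd))
    }
    p <- stats::plogis(spec$outcomeIntercept + spec$outcomeSlope * vol)
    outcome <- stats::rbinom(n, 1L, p)

    data.frame(
      case_id = sprintf("case_%04d", seq_len(n)),
      true_volume_mm3 = vol,
      true_axis_a_mm = a,
      true_axis_b_mm = b,
      true_axis_c_mm = c_,
      measured_volume_mm3 = noisy(vol),
      measured_axis_a_mm = noisy(a),
      measured_axis_b_mm = noisy(b),
      measured_axis_c_mm = noisy(c_),
      stone_free = outcome
    )
  })
}
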