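# Statistical comparison layer: Pearson correlation between manual and
# automated burden measures, and univariable binary logistic regression
# (IRLS) with Wald inference and Cox-Snell / Nagelkerke pseudo
# R-squared for stone-free outcome prediction.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param labels character(2) naming the variable pair.
#' @return A [CorrelationResult-class].
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 2, 3, 5))
#' @export
pearsonR <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  new("CorrelationResult", pair = as.character(labels),
      r = stats::cor(x, y), n = length(x))
}

# closed-form log-likelihood of the intercept-only Bernoulli model
nullLoglik <- function(y) {
  p <- mean(y)
  if (p == 0 || p == 1) return(0)
  sum(y) * log(p) + sum(1 - y) * log(1 - p)
}

#' Univariable binary logistic regression by IRLS
#'
#' Fits `logit P(y = 1) = b0 + b1 x` by iteratively reweighted least
#' squares, stopping when the largest coefficient change falls below
#' 1e-8 or after 100 iterations. Reports the odds ratio `exp(b1)` with
#' its 95% Wald interval `exp(b1 +/- 1.96 SE)`, the two-sided Wald
#' p-value, and Cox-Snell / Nagelkerke pseudo R-squared against the
#' intercept-only null. (Quasi-)complete separation is detected (the two
#' outcome classes occupy non-overlapping predictor ranges, so the slope
#' MLE diverges) and the fit is flagged unreliable rather than silently
#' returned.
#'
#' @param outcome binary vector (0/1 or logical), both classes present.
#' @param predictor numeric vector, non-constant.
#' @param predictorName label for reporting.
#' @return A [LogisticFit-class].
#' @seealso [nagelkerkeR2()], [rankPredictors()]
#' @export
fitLogistic <- function(outcome, predictor, predictorName = "predictor") {
  y <- as.numeric(outcome)
  x <- as.numeric(predictor)
  if (length(y) != length(x)) stop("outcome and predictor lengths differ")
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  if (stats::sd(x) == 0)
    stop("degenerate input: predictor is constant")

  X <- unname(cbind(1, x))
  beta <- c(0, 0)
  converged <- FALSE
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    betaNew <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                        error = function(e) rep(NA_real_, 2))
    if (any(!is.finite(betaNew))) break
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (delta < 1e-8) { converged <- TRUE; break }
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # (quasi-)complete separation: the predictor ranges of the two classes
  # do not overlap, so the slope MLE diverges
  sep <- max(x[y == 1]) <= min(x[y == 0]) ||
         max(x[y == 0]) <= min(x[y == 1])
  reliable <- converged && !sep && all(is.finite(beta))

  w <- pmax(mu * (1 - mu), 1e-12)
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) c(NA, NA))
  ll1 <- sum(y * log(pmax(mu, 1e-300)) +
             (1 - y) * log(pmax(1 - mu, 1e-300)))
  ll0 <- nullLoglik(y)
  ll1 <- max(ll1, ll0)   # ML fit cannot undercut its nested null
  r2 <- pseudoR2(ll0, ll1, n)

  zstat <- beta[2] / se[2]
  new("LogisticFit",
      predictor = predictorName,
      coefficients = beta,
      se = as.numeric(se),
      expB = exp(beta[2]),
      ci95ExpB = exp(beta[2] + c(-1, 1) * 1.96 * se[2]),
      pValue = 2 * stats::pnorm(-abs(zstat)),
      loglikNull = ll0,
      loglikModel = ll1,
      n = n,
      r2CoxSnell = r2$coxSnell,
      r2Nagelkerke = r2$nagelkerke,
      converged = converged,
      reliable = reliable)
}

# Cox-Snell and max-rescaled (Nagelkerke) pseudo R-squared from the two
# log-likelihoods
pseudoR2 <- function(loglikNull, loglikModel, n) {
  cs <- 1 - exp((2 / n) * (loglikNull - loglikModel))
  denom <- 1 - exp((2 / n) * loglikNull)
  list(coxSnell = cs,
       nagelkerke = if (denom <= 0) 0 else cs / denom)
}

#' Nagelkerke pseudo R-squared
#'
#' The max-rescaled Cox-Snell statistic,
#' `R2_N = (1 - exp((2/n)(L0 - L1))) / (1 - exp((2/n) L0))`,
#' in `[0, 1]`, where `L0`/`L1` are the null and model log-likelihoods.
#' Dispatches on a [LogisticFit-class] or on raw log-likelihoods.
#'
#' @param fit a [LogisticFit-class], or the null-model log-likelihood.
#' @param loglikModel,n model log-likelihood and sample size (numeric
#'   method only).
#' @return Nagelkerke R-squared, numeric(1).
#' @export
setGeneric("nagelkerkeR2", function(fit, loglikModel, n)
  standardGeneric("nagelkerkeR2"))

#' @rdname nagelkerkeR2
#' @export
setMethod("nagelkerkeR2", "LogisticFit", function(fit, loglikModel, n)
  pseudoR2(fit@loglikNull, fit@loglikModel, fit@n)$nagelkerke)

#' @rdname nagelkerkeR2
#' @export
setMethod("nagelkerkeR2", "numeric", function(fit, loglikModel, n)
  pseudoR2(fit, loglikModel, n)$nagelkerke)

#' Rank burden measures by stone-free predictive value
#'
#' Fits one univariable logistic model per predictor column against the
#' binary outcome column and ranks them by Nagelkerke R-squared,
#' descending — the comparison used to ask which burden measure best
#' explains treatment outcome.
#'
#' @param cohort data.frame holding the outcome and predictor columns.
#' @param predictors character vector of predictor column names.
#' @param outcome name of the binary outcome column (1 = stone-free).
#' @return A data.frame with columns `predictor`, `p`, `exp_b`,
#'   `ci_low`, `ci_high`, `nagelkerke_r2`, `reliable`, sorted by
#'   `nagelkerke_r2` descending; attribute `fits` carries the
#'   [LogisticFit-class] objects.
#' @export
rankPredictors <- function(cohort, predictors, outcome = "stone_free") {
  stopifnot(is.data.frame(cohort))
  missing <- setdiff(c(predictors, outcome), names(cohort))
  if (length(missing))
    stop("columns absent from cohort: ", paste(missing, collapse = ", "))
  fits <- lapply(predictors, function(p)
    fitLogistic(cohort[[outcome]], cohort[[p]], predictorName = p))
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    predictor = f@predictor,
    p = f@pValue,
    exp_b = f@expB,
    ci_low = f@ci95ExpB[1],
    ci_high = f@ci95ExpB[2],
    nagelkerke_r2 = f@r2Nagelkerke,
    reliable = f@reliable
  )))
  ord <- order(-tab$nagelkerke_r2)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
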