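# Three-way SWL outcome classification and the volume-vs-axis
# reclassification comparison. "Stone-free" means no residual fragments
# on follow-up CT; fragments whose major axis is <= the CIRF threshold
# (4 mm by convention) count as clinically insignificant.

OUTCOME_LEVELS <- c("completely_stone_free", "stone_free_with_cirfs",
                    "not_stone_free")

#' Classify a post-SWL case from its residual fragments
#'
#' * no fragments -> `completely_stone_free`
#' * fragments present, every major axis <= threshold ->
#'   `stone_free_with_cirfs`
#' * any fragment's major axis > threshold -> `not_stone_free`
#'
#' The comparison is inclusive (a fragment of exactly the threshold size
#' is a CIRF), and the rule is per fragment: every fragment must qualify.
#'
#' @param fragments numeric vector of fragment major-axis lengths in mm,
#'   or a per-fragment metrics data.frame with a
#'   `major_horizontal_axis_mm` column; empty means stone-free.
#' @param cirfThresholdMm CIRF size threshold in mm (> 0), default 4.
#' @return One of `"completely_stone_free"`, `"stone_free_with_cirfs"`,
#'   `"not_stone_free"`.
#' @examples
#' classifyOutcome(numeric(0))   # completely_stone_free
#' classifyOutcome(3.854)        # stone_free_with_cirfs
#' classifyOutcome(4.238)        # not_stone_free
#' @export
classifyOutcome <- function(fragments, cirfThresholdMm = 4.0) {
  if (cirfThresholdMm <= 0) stop("cirfThresholdMm must be > 0")
  axes <- if (is.data.frame(fragments))
    fragments$major_horizontal_axis_mm else as.numeric(fragments)
  if (length(axes) == 0L) return("completely_stone_free")
  if (any(!is.finite(axes) | axes <= 0))
    stop("fragment axes must be positive and finite")
  if (all(axes <= cirfThresholdMm)) "stone_free_with_cirfs"
  else "not_stone_free"
}

#' Compare volume-based and axis-based residual-fragment classification
#'
#' Given the residual fragments of cases originally classed
#' `stone_free_with_cirfs` and `not_stone_free` (by manual axis
#' measurement), reports
#' 1. the minimum total residual volume among not-stone-free cases,
#' 2. the CIRF-classed cases whose total residual volume strictly
#'    exceeds that minimum (i.e. cases whose burden was underestimated
#'    by the axis rule), and
#' 3. the not-stone-free cases whose every fragment axis is <= the CIRF
#'    threshold under re-measurement (i.e. cases the axis rule would now
#'    call stone-free with CIRFs).
#'
#' Multi-fragment cases aggregate by total volume but use the
#' per-fragment maximum axis for the size rule.
#'
#' @param cirfCases,notFreeCases data.frames with one row per fragment:
#'   columns `case_id`, `major_axis_mm`, `volume_mm3`.
#' @param cirfThresholdMm CIRF size threshold in mm, default 4.
#' @return A list of class `ReclassificationReport` with elements
#'   `min_not_stone_free_volume_mm3`, `cirf_above_min` (data.frame
#'   `case_id`, `total_volume_mm3`), `n_cirf_above_min`,
#'   `not_free_axis_cirf` (data.frame `case_id`, `max_axis_mm`),
#'   `n_not_free_axis_cirf`, `cirf_threshold_mm`.
#' @export
reclassificationReport <- function(cirfCases, notFreeCases,
                                   cirfThresholdMm = 4.0) {
  checkFragFrame <- function(df, nm) {
    need <- c("case_id", "major_axis_mm", "volume_mm3")
    if (!is.data.frame(df) || !all(need %in% names(df)))
      stop(nm, " must be a data.frame with columns ",
           paste(need, collapse = ", "))
  }
  checkFragFrame(cirfCases, "cirfCases")
  checkFragFrame(notFreeCases, "notFreeCases")
  if (nrow(notFreeCases) == 0L)
    stop("undefined minimum: notFreeCases is empty")

  perCase <- function(df) {
    vol <- tapply(df$volume_mm3, df$case_id, sum)
    ax <- tapply(df$major_axis_mm, df$case_id, max)
    data.frame(case_id = names(vol),
               total_volume_mm3 = as.numeric(vol),
               max_axis_mm = as.numeric(ax[names(vol)]),
               row.names = NULL)
  }
  cirf <- perCase(cirfCases)
  nfree <- perCase(notFreeCases)

  minVol <- min(nfree$total_volume_mm3)
  above <- cirf[cirf$total_volume_mm3 > minVol,
                c("case_id", "total_volume_mm3")]
  axisCirf <- nfree[nfree$max_axis_mm <= cirfThresholdMm,
                    c("case_id", "max_axis_mm")]
  structure(list(
    min_not_stone_free_volume_mm3 = minVol,
    cirf_above_min = above,
    n_cirf_above_min = nrow(above),
    not_free_axis_cirf = axisCirf,
    n_not_free_axis_cirf = nrow(axisCirf),
    cirf_threshold_mm = cirfThresholdMm
  ), class = "ReclassificationReport")
}

#' @export
print.ReclassificationReport <- function(x, ...) {
  cat("Residual-fragment reclassification report\n")
  cat(sprintf("  smallest not-stone-free total volume: %.2f mm^3\n",
              x$min_not_stone_free_volume_mm3))
  cat(sprintf("  CIRF cases with larger total volume:  %d\n",
              x$n_cirf_above_min))
  if (x$n_cirf_above_min > 0)
    cat(sprintf("    %s (%.2f mm^3)\n", x$cirf_above_min$case_id,
                x$cirf_above_min$total_volume_mm3), sep = "")
  cat(sprintf("  not-stone-free cases with all axes <= %.1f mm: %d\n",
              x$cirf_threshold_mm, x$n_not_free_axis_cirf))
  if (x$n_not_free_axis_cirf > 0)
    cat(sprintf("    %s (%.3f mm)\n", x$not_free_axis_cirf$case_id,
                x$not_free_axis_cirf$max_axis_mm), sep = "")
  invisible(x)
}

#' Summarise a treated cohort
#'
#' Counts and percentages (one decimal) per outcome category and per
#' number of treatment sessions, plus median (IQR [range]) of any
#' numeric burden columns per outcome group.
#'
#' @param cohort data.frame with a `case_id` column, an `outcome` column
#'   (values among the three outcome categories), optionally
#'   `n_sessions`, and optionally numeric burden columns named in
#'   `burdenCols`.
#' @param burdenCols character vector of numeric columns to summarise
#'   per group (default: none).
#' @return A list with `n_cases`, `outcome_counts` (data.frame
#'   `outcome`, `n`, `pct`), `session_counts` (or NULL), and `burden`
#'   (per-group median/IQR/range per requested column, or NULL). For an
#'   empty cohort, counts are 0 and percentages `NA`.
#' @export
cohortSummary <- function(cohort, burdenCols = character(0)) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  pct <- function(k) if (n == 0L) NA_real_ else round(100 * k / n, 1)
  oc <- data.frame(
    outcome = OUTCOME_LEVELS,
    n = vapply(OUTCOME_LEVELS, function(l)
      sum(cohort$outcome == l), integer(1)),
    pct = NA_real_, row.names = NULL
  )
  oc$pct <- pct(oc$n)
  sess <- NULL
  if ("n_sessions" %in% names(cohort) && n > 0L) {
    tb <- table(cohort$n_sessions)
    sess <- data.frame(n_sessions = names(tb), n = as.integer(tb),
                       pct = pct(as.integer(tb)), row.names = NULL)
  }
  burden <- NULL
  if (length(burdenCols) && n > 0L) {
    burden <- lapply(stats::setNames(burdenCols, burdenCols), function(col) {
      do.call(rbind, lapply(c("all", OUTCOME_LEVELS), function(g) {
        x <- if (g == "all") cohort[[col]]
             else cohort[[col]][cohort$outcome == g]
        if (length(x) == 0L)
          return(data.frame(group = g, n = 0L, median = NA_real_,
                            q1 = NA_real_, q3 = NA_real_,
                            min = NA_real_, max = NA_real_))
        q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
        data.frame(group = g, n = length(x),
                   median = stats::median(x), q1 = q[1], q3 = q[2],
                   min = min(x), max = max(x))
      }))
    })
  }
  list(n_cases = n, outcome_counts = oc, session_counts = sess,
       burden = burden)
}
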