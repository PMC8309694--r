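# Survival curves, two-period monotone postprocessing, and validation
# metrics (per-class hit rates and curve errors).

#' Construct a survival curve
#'
#' Per-day live counts plus the initial population size. No correction is
#' applied; postprocessing is explicit via [monotone_correct()].
#'
#' @param counts non-negative per-day live counts (day 1..length(counts)).
#' @param initial_live initial population (> 0 for percentage queries).
#' @param plate_id optional identifier.
#' @return object of class `survival_curve`.
#' @export
build_curve <- function(counts, initial_live, plate_id = NA) {
  if (length(counts) == 0) stop("counts must be non-empty")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = as.numeric(counts),
                 initial_live = initial_live, plate_id = plate_id),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("survival_curve (plate ", x$plate_id, "): initial ", x$initial_live,
      ", days 1-", length(x$counts), "\n  counts: ",
      paste(x$counts, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Percentage of the initial population alive on a day
#'
#' `100 * counts[d] / initial_live`. Values above 100 (counts exceeding the
#' initial population, a counting error) are returned as-is with a warning,
#' never clamped.
#'
#' @param curve a [build_curve()] survival curve.
#' @param d day index.
#' @return percentage.
#' @export
percent_live <- function(curve, d) {
  stopifnot(inherits(curve, "survival_curve"))
  if (curve$initial_live <= 0) stop("initial_live must be positive")
  if (d < 1 || d > length(curve$counts)) stop("day out of range")
  p <- 100 * curve$counts[d] / curve$initial_live
  if (p > 100) warning("live count exceeds initial population on day ", d)
  p
}

#' Absolute survival-percentage error on one day
#'
#' @param manual,automatic survival curves spanning the same days.
#' @param d day index.
#' @return `|% live_manual(d) - % live_automatic(d)|`.
#' @export
daily_error <- function(manual, automatic, d) {
  abs(percent_live(manual, d) - percent_live(automatic, d))
}

#' Mean daily survival error of a plate
#'
#' The average of [daily_error()] over all days of the experiment.
#'
#' @param manual,automatic survival curves spanning the same days.
#' @return percentage.
#' @export
plate_error <- function(manual, automatic) {
  if (length(manual$counts) != length(automatic$counts))
    stop("curves must span the same days")
  mean(vapply(seq_along(manual$counts),
              function(d) daily_error(manual, automatic, d), numeric(1)))
}

#' Mean daily survival error of a condition
#'
#' Pools the counts of all plates of a condition per day for each method,
#' computes the pooled survival percentages, and averages the absolute
#' daily differences. Not equal, in general, to the mean of the per-plate
#' errors.
#'
#' @param manual_curves,automatic_curves non-empty lists of day-aligned
#'   survival curves.
#' @return percentage.
#' @export
condition_error <- function(manual_curves, automatic_curves) {
  stopifnot(length(manual_curves) > 0,
            length(manual_curves) == length(automatic_curves))
  days <- unique(c(vapply(manual_curves, function(x) length(x$counts), integer(1)),
                   vapply(automatic_curves, function(x) length(x$counts), integer(1))))
  if (length(days) != 1) stop("curves are not day-aligned")
  pool <- function(curves) {
    counts <- rowSums(vapply(curves, `[[`, numeric(days), "counts"))
    init <- sum(vapply(curves, `[[`, numeric(1), "initial_live"))
    build_curve(counts, init)
  }
  plate_error(pool(manual_curves), pool(automatic_curves))
}

#' Two-period monotone correction of a survival curve
#'
#' Lifespan curves must be non-increasing; a day whose count exceeds the
#' previous day's reveals a counting error. Early errors are mostly missed
#' worms (occlusion, aggregation), so in the first period (days up to
#' `split_day`, the strain's mean life) the curve is corrected upwards:
#' scanning backward, whenever a day's count exceeds the previous day's,
#' the previous day's count is raised to it. Late errors are mostly false
#' positives (dirt), so after `split_day` the curve is corrected downwards:
#' scanning forward, a count exceeding the previous day's is lowered to it.
#' Corrections run to a fixed point; the result is non-increasing and the
#' operation idempotent.
#'
#' @param curve a survival curve.
#' @param split_day boundary between the two periods (14 days for N2).
#' @return a corrected `survival_curve`.
#' @export
monotone_correct <- function(curve, split_day = 14L) {
  stopifnot(inherits(curve, "survival_curve"), split_day >= 1)
  x <- curve$counts
  n <- length(x)
  s <- min(split_day, n)
  repeat {
    changed <- FALSE
    if (s >= 2) for (d in s:2) {
      if (x[d] > x[d - 1]) { x[d - 1] <- x[d]; changed <- TRUE }
    }
    if (!changed) break
  }
  if (n > s) for (d in (s + 1):n) {
    if (x[d] > x[d - 1]) x[d] <- x[d - 1]
  }
  out <- curve
  out$counts <- x
  out
}

#' Confusion matrix for dead/alive classification
#'
#' Rows are the true label, columns the prediction: TD true dead, FA false
#' alive (dead predicted alive), FD false dead, TA true alive.
#'
#' @param TD,FA,FD,TA non-negative counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TD, FA, FD, TA) {
  stopifnot(TD >= 0, FA >= 0, FD >= 0, TA >= 0)
  structure(list(TD = TD, FA = FA, FD = FD, TA = TA),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TD, x$FA, x$FD, x$TA), 2, 2, byrow = TRUE,
              dimnames = list(c("dead", "alive"),
                              c("pred dead", "pred alive")))
  print(m)
  invisible(x)
}

#' Per-class hit rates
#'
#' `true_dead_rate` = 100 TD / (TD + FA): percentage of dead worms
#' correctly predicted dead. `true_live_rate` = 100 TA / (TA + FD).
#' `mean_hit_rate` is their arithmetic mean.
#'
#' @param m a [confusion_matrix()].
#' @return percentage.
#' @export
true_dead_rate <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$TD + m$FA == 0) stop("no dead samples: rate undefined")
  100 * m$TD / (m$TD + m$FA)
}

#' @rdname true_dead_rate
#' @export
true_live_rate <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$TA + m$FD == 0) stop("no alive samples: rate undefined")
  100 * m$TA / (m$TA + m$FD)
}

#' @rdname true_dead_rate
#' @export
mean_hit_rate <- function(m) {
  (true_dead_rate(m) + true_live_rate(m)) / 2
}
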