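# Calibration of minimum limits of prediction from pre-evaluation scores.
#
# For each sink activity two score samples are collected: the similarities
# it obtains while it is truly being performed (positives) and while other
# activities are being performed (negatives). A usable limit must separate
# the two: above every negative, below every positive.

#' Score samples for one activity's limit calibration
#'
#' @param activity Activity name.
#' @param positives Similarity percents observed while the activity was
#'   truly performed.
#' @param negatives Similarity percents of this activity's template while
#'   other activities were performed.
#' @return An object of class `score_samples`.
#' @export
score_samples <- function(activity, positives, negatives) {
  for (v in list(positives, negatives)) {
    if (length(v) > 0L) {
      stopifnot(is.numeric(v), all(is.finite(v)), all(v >= 0), all(v <= 100))
    }
  }
  structure(
    list(
      activity = activity,
      positives = as.numeric(positives),
      negatives = as.numeric(negatives)
    ),
    class = "score_samples"
  )
}

#' Selection interval for an activity's minimum limit of prediction
#'
#' Strict rule: the interval runs from the maximum of the negatives (the
#' largest similarity the activity reached while not being performed) up to
#' the minimum of the positives. When those bounds cross — the activity
#' scores higher while absent than its worst score while present — the rule
#' falls back to the means of the two samples. If even the means do not
#' separate, the interval is flagged degenerate and surfaced for manual
#' choice rather than silently resolved.
#'
#' @param samples A [score_samples()] with non-empty positives and
#'   negatives.
#' @return An object of class `calibration_interval`: list with `activity`,
#'   `lower`, `upper`, `rule_used` (`"strict"` or `"mean"`) and
#'   `degenerate`.
#' @export
#' @examples
#' calibration_interval(score_samples("Stay Seated",
#'   positives = c(90, 92, 95), negatives = c(70, 75, 80)
#' ))
calibration_interval <- function(samples) {
  stopifnot(inherits(samples, "score_samples"))
  if (length(samples$positives) == 0L || length(samples$negatives) == 0L) {
    stop("insufficient data: positives and negatives must both be non-empty",
      call. = FALSE
    )
  }
  lower <- max(samples$negatives)
  upper <- min(samples$positives)
  rule <- "strict"
  if (lower >= upper) {
    lower <- mean(samples$negatives)
    upper <- mean(samples$positives)
    rule <- "mean"
  }
  structure(
    list(
      activity = samples$activity, lower = lower, upper = upper,
      rule_used = rule, degenerate = lower >= upper
    ),
    class = "calibration_interval"
  )
}

#' @export
print.calibration_interval <- function(x, ...) {
  cat(sprintf(
    "<calibration_interval> %s: (%.2f, %.2f) [%s%s]\n",
    x$activity, x$lower, x$upper, x$rule_used,
    if (x$degenerate) ", degenerate" else ""
  ))
  invisible(x)
}

#' Select a minimum limit of prediction from an interval
#'
#' The limit is the interval midpoint rounded to 0.1 percentage point. A
#' degenerate interval, or one so narrow that the rounded midpoint touches
#' a bound, raises an unreliable-limit error carrying the interval so the
#' choice can be made manually.
#'
#' @param interval A [calibration_interval()].
#' @return Limit percent, strictly inside the interval.
#' @export
#' @examples
#' select_limit(structure(
#'   list(
#'     activity = "Walk [D]", lower = 80, upper = 90,
#'     rule_used = "strict", degenerate = FALSE
#'   ),
#'   class = "calibration_interval"
#' ))
select_limit <- function(interval) {
  stopifnot(inherits(interval, "calibration_interval"))
  if (interval$degenerate) {
    cond <- structure(
      class = c("skelmatch_unreliable_limit", "error", "condition"),
      list(
        message = sprintf(
          "degenerate interval for %s: (%.3f, %.3f); choose a limit manually",
          interval$activity, interval$lower, interval$upper
        ),
        call = NULL, interval = interval
      )
    )
    stop(cond)
  }
  limit <- round((interval$lower + interval$upper) / 2, 1)
  if (limit <= interval$lower || limit >= interval$upper) {
    cond <- structure(
      class = c("skelmatch_unreliable_limit", "error", "condition"),
      list(
        message = sprintf(
          "interval for %s too narrow: (%.3f, %.3f); choose a limit manually",
          interval$activity, interval$lower, interval$upper
        ),
        call = NULL, interval = interval
      )
    )
    stop(cond)
  }
  limit
}

#' Calibrate limits for several activities
#'
#' With `per_activity = TRUE` (the recommended mode) each activity gets its
#' own limit from its own interval. With `per_activity = FALSE` a single
#' shared limit is taken from the midpoint of the intersection of all
#' non-degenerate intervals; disjoint intervals raise a no-shared-limit
#' error — the typical situation when one activity's interval (e.g., a
#' hard-to-separate posture) sits apart from the others.
#'
#' @param score_sets List of [score_samples()].
#' @param per_activity Logical (default `TRUE`).
#' @param global_limit Global limit stored in the resulting table.
#' @return A [limit_table()]. Activities whose interval is degenerate are
#'   omitted from the table with a warning (per-activity mode).
#' @export
calibrate_all <- function(score_sets, per_activity = TRUE,
                          global_limit = 50) {
  stopifnot(length(score_sets) >= 1L)
  intervals <- lapply(score_sets, calibration_interval)
  names(intervals) <- vapply(intervals, `[[`, character(1), "activity")
  if (per_activity) {
    limits <- numeric(0)
    for (iv in intervals) {
      lim <- tryCatch(select_limit(iv), skelmatch_unreliable_limit = function(e) {
        warning("no reliable limit for ", iv$activity, ": ",
          conditionMessage(e),
          call. = FALSE
        )
        NA_real_
      })
      if (!is.na(lim)) limits[iv$activity] <- lim
    }
    return(limit_table(limits, global_limit))
  }
  ok <- intervals[!vapply(intervals, `[[`, logical(1), "degenerate")]
  if (length(ok) == 0L) {
    stop("no non-degenerate interval to intersect", call. = FALSE)
  }
  lo <- max(vapply(ok, `[[`, numeric(1), "lower"))
  up <- min(vapply(ok, `[[`, numeric(1), "upper"))
  if (lo >= up) {
    stop("no shared limit: intervals are disjoint (",
      paste(sprintf(
        "%s (%.1f, %.1f)", names(ok),
        vapply(ok, `[[`, numeric(1), "lower"),
        vapply(ok, `[[`, numeric(1), "upper")
      ), collapse = "; "),
      ")",
      call. = FALSE
    )
  }
  shared <- select_limit(structure(
    list(
      activity = "shared", lower = lo, upper = up,
      rule_used = "strict", degenerate = FALSE
    ),
    class = "calibration_interval"
  ))
  limit_table(
    stats::setNames(rep(shared, length(ok)), names(ok)),
    global_limit
  )
}

#' Write / read pre-evaluation score samples as CSV
#'
#' CSV schema: `activity,truth,similarity` with `truth` one of `pos`/`neg`.
#'
#' @param score_sets List of [score_samples()].
#' @param path File path.
#' @return `write_score_samples` returns `path` invisibly;
#'   `read_score_samples` returns a list of [score_samples()].
#' @export
write_score_samples <- function(score_sets, path) {
  rows <- do.call(rbind, lapply(score_sets, function(s) {
    rbind(
      if (length(s$positives) > 0L) {
        data.frame(
          activity = s$activity, truth = "pos",
          similarity = s$positives
        )
      },
      if (length(s$negatives) > 0L) {
        data.frame(
          activity = s$activity, truth = "neg",
          similarity = s$negatives
        )
      }
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_score_samples
#' @export
read_score_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("activity", "truth", "similarity")
  if (!all(need %in% names(df))) {
    stop("score-sample CSV needs columns activity, truth, similarity",
      call. = FALSE
    )
  }
  if (!all(df$truth %in% c("pos", "neg"))) {
    stop("truth column must be 'pos' or 'neg'", call. = FALSE)
  }
  lapply(unique(df$activity), function(a) {
    sub <- df[df$activity == a, ]
    score_samples(
      a,
      positives = sub$similarity[sub$truth == "pos"],
      negatives = sub$similarity[sub$truth == "neg"]
    )
  })
}
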