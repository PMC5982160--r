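# Scoring a registry of templates and predicting with minimum limits of
# prediction (sink gating) and an unknown-activity fallback.

#' Table of minimum limits of prediction
#'
#' Per-activity similarity thresholds that an activity's score must reach to
#' stay eligible as the prediction, plus a global limit below which the
#' prediction falls back to `"UNKNOWN"`.
#'
#' @param per_activity Named numeric vector of percents (may be empty).
#' @param global_limit Global minimum limit of prediction, percent.
#' @return An object of class `limit_table`.
#' @export
limit_table <- function(per_activity = numeric(0), global_limit = 50) {
  per_activity <- unlist(per_activity)
  if (length(per_activity) > 0L) {
    stopifnot(
      is.numeric(per_activity), !is.null(names(per_activity)),
      all(per_activity >= 0), all(per_activity <= 100)
    )
  } else {
    per_activity <- stats::setNames(numeric(0), character(0))
  }
  stopifnot(
    is.numeric(global_limit), length(global_limit) == 1L,
    global_limit >= 0, global_limit <= 100
  )
  structure(
    list(per_activity = per_activity, global_limit = global_limit),
    class = "limit_table"
  )
}

#' @export
print.limit_table <- function(x, ...) {
  cat("<limit_table> global", x$global_limit, "%\n")
  if (length(x$per_activity) > 0L) {
    for (a in names(x$per_activity)) {
      cat(sprintf("  %-20s %.1f%%\n", a, x$per_activity[[a]]))
    }
  }
  invisible(x)
}

#' Packaged default minimum limits for the sink activities
#'
#' The calibrated per-activity limits for the four sink activities
#' (Stand 85.4, Stay Seated 78.0, Walk \[D\] 78.0, Walk Backwards \[D\]
#' 79.0), with a configurable global limit.
#'
#' @param global_limit Global minimum limit of prediction (default 50).
#' @return A [limit_table()].
#' @export
#' @examples
#' default_limits()$per_activity[["Stand"]]
default_limits <- function(global_limit = 50) {
  limit_table(
    per_activity = c(
      "Stand" = 85.4,
      "Stay Seated" = 78.0,
      "Walk [D]" = 78.0,
      "Walk Backwards [D]" = 79.0
    ),
    global_limit = global_limit
  )
}

#' Write / read a limit table as JSON
#'
#' JSON schema: `{per_activity: {<name>: percent, ...}, global_limit}`.
#'
#' @param limits A [limit_table()].
#' @param path File path.
#' @return `write_limits` returns `path` invisibly; `read_limits` returns
#'   the [limit_table()].
#' @export
write_limits <- function(limits, path) {
  stopifnot(inherits(limits, "limit_table"))
  jsonlite::write_json(
    list(
      per_activity = as.list(limits$per_activity),
      global_limit = limits$global_limit
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_limits
#' @export
read_limits <- function(path) {
  obj <- jsonlite::fromJSON(path)
  limit_table(
    per_activity = unlist(obj$per_activity),
    global_limit = obj$global_limit
  )
}

# trailing window of a sequence covering the last `duration` seconds
.trailing_window <- function(seq, duration, tolerance = 0.2) {
  ts <- vapply(seq$frames, `[[`, numeric(1), "timestamp")
  t_end <- ts[length(ts)]
  keep <- which(ts >= t_end - duration - 1e-9)
  if (length(keep) < 2L) {
    return(NULL)
  }
  win <- skeleton_sequence(seq$frames[keep], seq$fps, seq$label)
  if (abs(sequence_duration(win) - duration) > tolerance * duration) {
    return(NULL)
  }
  win
}

#' Score an observation against every registered template
#'
#' Postures and movements are scored the same way — as a mean of per-frame
#' body similarities over a trailing window ending at the decision instant.
#' For a movement template the window matches the template's duration and
#' is compared frame-to-frame via [sequence_similarity()]; for a posture
#' template (a posture is held over time, not exhibited in one sensor
#' sample) every frame of the last `posture_window` seconds is compared to
#' the single key frame and the similarities averaged. A template that
#' cannot be scored (e.g., the observation is shorter than its window) is
#' recorded as unscorable rather than raising an error.
#'
#' @param observation A [skeleton_sequence()] ending at the decision
#'   instant.
#' @param templates List of [activity_template()] objects; their order is
#'   the registration order used for deterministic tie-breaking.
#' @param tolerance Duration tolerance passed to [sequence_similarity()].
#' @param posture_window Seconds of trailing context averaged when scoring
#'   a posture template (clipped to the available observation; a one-frame
#'   observation scores on that frame alone).
#' @return Named list (by template name) whose elements are
#'   `similarity_report`s, or a character error message for unscorable
#'   templates.
#' @export
score_all <- function(observation, templates, tolerance = 0.2,
                      posture_window = 1) {
  stopifnot(inherits(observation, "skeleton_sequence"))
  if (length(observation$frames) == 0L) {
    stop("observation has no frames", call. = FALSE)
  }
  out <- list()
  for (tpl in templates) {
    stopifnot(inherits(tpl, "activity_template"))
    res <- tryCatch(
      {
        if (tpl$kind == "posture") {
          ts <- vapply(observation$frames, `[[`, numeric(1), "timestamp")
          keep <- which(ts >= ts[length(ts)] - posture_window - 1e-9)
          per_frame <- vapply(keep, function(i) {
            body_similarity(
              observation$frames[[i]], tpl$key_sample, tpl$relevant_bones
            )$bone_sims
          }, numeric(length(tpl$relevant_bones)))
          bone_sims <- stats::setNames(
            if (is.matrix(per_frame)) rowMeans(per_frame) else mean(per_frame),
            tpl$relevant_bones
          )
          structure(
            list(
              template_name = tpl$name, bone_sims = bone_sims,
              body_similarity = mean(bone_sims)
            ),
            class = "similarity_report"
          )
        } else {
          win <- .trailing_window(
            observation, sequence_duration(tpl$key_sample), tolerance
          )
          if (is.null(win)) {
            stop("observation window does not match template duration",
              call. = FALSE
            )
          }
          s <- sequence_similarity(win, tpl$key_sample, tpl$relevant_bones,
            tolerance = tolerance
          )
          structure(
            list(
              template_name = tpl$name, bone_sims = NULL,
              body_similarity = s
            ),
            class = "similarity_report"
          )
        }
      },
      error = function(e) conditionMessage(e)
    )
    out[[tpl$name]] <- res
  }
  out
}

# label + gated set from a named score vector (in registration order) and a
# limit table; shared by predict_activity and the evaluation harness
.predict_from_scores <- function(scores, templates_min_limit, limits) {
  per <- if (is.null(limits)) numeric(0) else limits$per_activity
  global <- if (is.null(limits)) 0 else limits$global_limit
  eff_limit <- vapply(names(scores), function(a) {
    if (a %in% names(per)) {
      per[[a]]
    } else if (!is.null(templates_min_limit[[a]])) {
      templates_min_limit[[a]]
    } else {
      NA_real_
    }
  }, numeric(1))
  gated <- names(scores)[!is.na(eff_limit) & scores < eff_limit]
  eligible <- setdiff(names(scores), gated)
  if (length(eligible) == 0L) {
    return(list(label = "UNKNOWN", gated = gated))
  }
  best <- eligible[which.max(scores[eligible])]
  if (scores[[best]] < global) {
    return(list(label = "UNKNOWN", gated = gated))
  }
  list(label = best, gated = gated)
}

#' Predict the activity being performed
#'
#' Scores every template with [score_all()], removes ("gates") each
#' activity whose score is below its minimum limit of prediction — even if
#' it scored highest — then picks the highest-scoring remaining activity.
#' If that maximum is below the global limit the observation is labelled
#' `"UNKNOWN"`. Exact ties are broken by template registration order.
#'
#' Per-activity limits come from `limits$per_activity` when present there,
#' falling back to each template's own `min_limit`.
#'
#' @param observation A [skeleton_sequence()] ending at the decision
#'   instant.
#' @param templates List of [activity_template()] objects in registration
#'   order.
#' @param limits A [limit_table()] (or `NULL` for pure argmax).
#' @param tolerance Duration tolerance for movement windows.
#' @param posture_window Trailing seconds averaged when scoring posture
#'   templates (see [score_all()]).
#' @return An object of class `activity_prediction`: list with `label`
#'   (activity name or `"UNKNOWN"`), `scores` (named percents over scorable
#'   templates), `gated` (activities excluded by their limit) and
#'   `reports` (the full [score_all()] output).
#' @export
predict_activity <- function(observation, templates, limits = NULL,
                             tolerance = 0.2, posture_window = 1) {
  if (!is.null(limits)) stopifnot(inherits(limits, "limit_table"))
  reports <- score_all(observation, templates,
    tolerance = tolerance, posture_window = posture_window
  )
  scorable <- vapply(reports, inherits, logical(1), "similarity_report")
  if (!any(scorable)) {
    stop("no template could be scored against the observation",
      call. = FALSE
    )
  }
  scores <- vapply(
    reports[scorable], `[[`, numeric(1), "body_similarity"
  )
  tpl_limits <- stats::setNames(
    lapply(templates, `[[`, "min_limit"),
    vapply(templates, `[[`, character(1), "name")
  )
  dec <- .predict_from_scores(scores, tpl_limits, limits)
  structure(
    list(
      label = dec$label, scores = scores, gated = dec$gated,
      reports = reports
    ),
    class = "activity_prediction"
  )
}

#' @export
print.activity_prediction <- function(x, ...) {
  cat("<activity_prediction>", x$label, "\n")
  ord <- order(-x$scores)
  for (i in ord) {
    cat(sprintf(
      "  %-24s %6.2f%%%s\n", names(x$scores)[i], x$scores[i],
      if (names(x$scores)[i] %in% x$gated) "  [gated]" else ""
    ))
  }
  invisible(x)
}
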