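# Activity templates and the vB/vT/vC joint-set variants.

.TRUNK_JOINTS <- c("HIP_CENTER", "SPINE", "SHOULDER_CENTER")
.GIRDLE_JOINTS <- c("SHOULDER_L", "SHOULDER_R", "HIP_L", "HIP_R")
.VC_JOINTS <- setdiff(
  KINECT_JOINTS,
  c("HAND_L", "HAND_R", "FOOT_L", "FOOT_R", "HEAD")
)

#' Declare an activity for joint-set selection
#'
#' Records which extremity chain(s) an activity uses and on which side, the
#' inputs needed to derive its relevant joints under each variant.
#'
#' @param name Activity name (conventionally suffixed `[D]` for right-side
#'   and `[I]` for left-side versions of asymmetric activities).
#' @param extremity `"arm"`, `"leg"` or `"both"` (global activities that use
#'   arms and legs).
#' @param laterality `"D"` (right), `"I"` (left) or `"symmetric"`.
#' @return An object of class `activity_spec`.
#' @export
#' @examples
#' activity_spec("Drink [D]", "arm", "D")
activity_spec <- function(name, extremity = c("arm", "leg", "both"),
                          laterality = c("D", "I", "symmetric")) {
  extremity <- match.arg(extremity)
  laterality <- match.arg(laterality)
  structure(
    list(name = name, extremity = extremity, laterality = laterality),
    class = "activity_spec"
  )
}

.chain_joints <- function(extremity, laterality) {
  sides <- switch(laterality,
    D = "R",
    I = "L",
    symmetric = c("L", "R")
  )
  chains <- list(
    arm = c("SHOULDER_%s", "ELBOW_%s", "WRIST_%s"),
    leg = c("HIP_%s", "KNEE_%s", "ANKLE_%s")
  )
  kinds <- if (extremity == "both") c("arm", "leg") else extremity
  out <- character(0)
  for (k in kinds) {
    for (s in if (extremity == "both") c("L", "R") else sides) {
      out <- c(out, sprintf(chains[[k]], s))
    }
  }
  unique(out)
}

#' Relevant joints of an activity under a joint-set variant
#'
#' The three variants trade off focus against stability:
#' * `vB`: the joints of the extremity chain(s) used by the activity,
#'   without hands and feet, plus both shoulders and both hips (the
#'   union points between trunk and extremities).
#' * `vT`: `vB` plus the trunk joints (`HIP_CENTER`, `SPINE`,
#'   `SHOULDER_CENTER`).
#' * `vC`: all 20 joints except hands, feet and head (15 joints),
#'   independent of the activity.
#'
#' @param spec An [activity_spec()].
#' @param variant `"vB"`, `"vT"` or `"vC"`.
#' @return Character vector of joint names.
#' @export
#' @examples
#' variant_joints(activity_spec("Drink [D]", "arm", "D"), "vB")
variant_joints <- function(spec, variant = c("vB", "vT", "vC")) {
  stopifnot(inherits(spec, "activity_spec"))
  variant <- match.arg(variant)
  if (variant == "vC") {
    return(.VC_JOINTS)
  }
  vb <- unique(c(
    .chain_joints(spec$extremity, spec$laterality),
    .GIRDLE_JOINTS
  ))
  vb <- setdiff(vb, c("HAND_L", "HAND_R", "FOOT_L", "FOOT_R"))
  if (variant == "vB") {
    return(vb)
  }
  unique(c(vb, .TRUNK_JOINTS))
}

#' Construct an activity template
#'
#' A template packages the single key sample of an activity together with
#' the metadata the recognizer needs: its relevant joints (which determine
#' the relevant bones), laterality, whether its body use is global or
#' bounded, whether it is a "sink" activity (easily detected, prone to
#' absorbing other activities' samples), and an optional minimum limit of
#' prediction.
#'
#' @param name Activity name.
#' @param kind `"posture"` (key sample is one frame) or `"movement"` (key
#'   sample is a sequence of >= 2 frames).
#' @param key_sample A [skeleton_frame()] for postures or a
#'   [skeleton_sequence()] for movements.
#' @param relevant_joints Joint names inducing at least one bone.
#' @param laterality `"D"`, `"I"` or `"symmetric"`.
#' @param body_use `"global"` or `"bounded"`.
#' @param sink Logical; sink templates should carry a `min_limit` (a warning
#'   is raised otherwise).
#' @param min_limit Optional minimum limit of prediction, percent.
#' @return An object of class `activity_template`.
#' @export
activity_template <- function(name, kind = c("posture", "movement"),
                              key_sample, relevant_joints,
                              laterality = c("symmetric", "D", "I"),
                              body_use = c("bounded", "global"),
                              sink = FALSE, min_limit = NULL) {
  kind <- match.arg(kind)
  laterality <- match.arg(laterality)
  body_use <- match.arg(body_use)
  .check_joints(relevant_joints)
  bones <- bones_induced(relevant_joints)
  if (length(bones) == 0L) {
    stop("relevant_joints induce no bone", call. = FALSE)
  }
  if (kind == "posture") {
    if (!inherits(key_sample, "skeleton_frame")) {
      stop("posture key_sample must be a skeleton_frame", call. = FALSE)
    }
  } else {
    if (!inherits(key_sample, "skeleton_sequence") ||
      length(key_sample$frames) < 2L) {
      stop("movement key_sample must be a skeleton_sequence with >= 2 frames",
        call. = FALSE
      )
    }
  }
  if (!is.null(min_limit)) {
    stopifnot(is.numeric(min_limit), length(min_limit) == 1L,
      min_limit >= 0, min_limit <= 100
    )
  }
  if (isTRUE(sink) && is.null(min_limit)) {
    warning("sink template \"", name,
      "\" has no minimum limit of prediction",
      call. = FALSE
    )
  }
  structure(
    list(
      name = name, kind = kind, key_sample = key_sample,
      relevant_joints = relevant_joints, relevant_bones = bones,
      laterality = laterality, body_use = body_use,
      sink = isTRUE(sink), min_limit = min_limit
    ),
    class = "activity_template"
  )
}

#' @export
print.activity_template <- function(x, ...) {
  cat(sprintf(
    "<activity_template> %s (%s, %s, %s%s): %d joints / %d bones%s\n",
    x$name, x$kind, x$body_use, x$laterality,
    if (x$sink) ", sink" else "",
    length(x$relevant_joints), length(x$relevant_bones),
    if (!is.null(x$min_limit)) sprintf(", limit %.1f%%", x$min_limit) else ""
  ))
  invisible(x)
}

.flip_name_suffix <- function(name) {
  if (grepl("\\[D\\]", name)) {
    sub("\\[D\\]", "[I]", name)
  } else if (grepl("\\[I\\]", name)) {
    sub("\\[I\\]", "[D]", name)
  } else {
    name
  }
}

#' Mirror an asymmetric template to the other body side
#'
#' Produces the opposite-side version of a `[D]`/`[I]` template: the key
#' sample is mirrored frame-wise, relevant joints have left/right swapped,
#' laterality is flipped, and the `[D]`/`[I]` name suffix is exchanged.
#'
#' @param template An [activity_template()] with laterality `"D"` or `"I"`.
#' @return The mirrored `activity_template`.
#' @export
mirror_template <- function(template) {
  stopifnot(inherits(template, "activity_template"))
  if (template$laterality == "symmetric") {
    stop("cannot mirror a symmetric template", call. = FALSE)
  }
  key <- if (template$kind == "posture") {
    mirror_frame(template$key_sample)
  } else {
    mirror_sequence(template$key_sample)
  }
  activity_template(
    name = .flip_name_suffix(template$name),
    kind = template$kind,
    key_sample = key,
    relevant_joints = mirror_joint(template$relevant_joints),
    laterality = if (template$laterality == "D") "I" else "D",
    body_use = template$body_use,
    sink = template$sink,
    min_limit = template$min_limit
  )
}

#' Write / read an activity template as JSON
#'
#' Template files are JSON objects `{name, kind, laterality, body_use,
#' sink, min_limit, relevant_joints, key_sample}` where `key_sample` uses
#' the sequence JSON dialect of [write_sequence()] (a posture is stored as
#' a one-frame sequence).
#'
#' @param template An [activity_template()].
#' @param path File path.
#' @return `write_template` returns `path` invisibly; `read_template`
#'   returns the template.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "activity_template"))
  key_seq <- if (template$kind == "posture") {
    skeleton_sequence(list(template$key_sample), fps = 1)
  } else {
    template$key_sample
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  .write_sequence_json(key_seq, tmp)
  key_json <- readLines(tmp, warn = FALSE)
  obj <- sprintf(
    paste0(
      "{\"name\":%s,\"kind\":%s,\"laterality\":%s,\"body_use\":%s,",
      "\"sink\":%s,\"min_limit\":%s,\"relevant_joints\":[%s],",
      "\"key_sample\":%s}"
    ),
    jsonlite::toJSON(template$name, auto_unbox = TRUE),
    jsonlite::toJSON(template$kind, auto_unbox = TRUE),
    jsonlite::toJSON(template$laterality, auto_unbox = TRUE),
    jsonlite::toJSON(template$body_use, auto_unbox = TRUE),
    if (template$sink) "true" else "false",
    if (is.null(template$min_limit)) "null" else .num17(template$min_limit),
    paste(sprintf("\"%s\"", template$relevant_joints), collapse = ","),
    paste(key_json, collapse = "")
  )
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE, after = FALSE)
  writeLines(obj, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
    simplifyMatrix = FALSE, simplifyDataFrame = FALSE
  )
  key_joints <- names(obj$key_sample$frames[[1L]]$positions)
  key_seq <- .sequence_from_obj(obj$key_sample, joints = key_joints)
  key <- if (obj$kind == "posture") key_seq$frames[[1L]] else key_seq
  activity_template(
    name = obj$name, kind = obj$kind, key_sample = key,
    relevant_joints = unlist(obj$relevant_joints),
    laterality = obj$laterality, body_use = obj$body_use,
    sink = isTRUE(obj$sink),
    min_limit = if (is.null(obj$min_limit)) NULL else as.numeric(obj$min_limit)
  )
}
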