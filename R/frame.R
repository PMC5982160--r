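# Skeleton frames and sequences.

#' Construct a skeleton frame
#'
#' A frame is a timestamped snapshot of joint positions: a numeric matrix
#' with one row per tracked joint and columns `x`, `y`, `z` in meters.
#' Coordinates follow a Kinect-like sensor convention: right-handed, `y` up,
#' `z` along the sensor axis, origin at the sensor.
#'
#' @param positions Numeric matrix with row names from [joint_names()] and
#'   three columns (x, y, z), all values finite.
#' @param timestamp Non-negative time in seconds.
#' @param joints Joints required to be present. Defaults to all 20; pass a
#'   subset to accept partially tracked frames.
#' @return An object of class `skeleton_frame`: a list with elements
#'   `timestamp` and `positions` (rows ordered as in `joints`).
#' @export
#' @examples
#' f <- skeleton_frame(standing_positions(), timestamp = 0)
skeleton_frame <- function(positions, timestamp = 0,
                           joints = joint_names()) {
  .check_joints(joints)
  if (!is.matrix(positions) || !is.numeric(positions) ||
    ncol(positions) != 3L) {
    stop("positions must be a numeric matrix with 3 columns (x, y, z)",
      call. = FALSE
    )
  }
  if (is.null(rownames(positions))) {
    stop("positions must have joint names as row names", call. = FALSE)
  }
  .check_joints(rownames(positions))
  missing <- setdiff(joints, rownames(positions))
  if (length(missing) > 0L) {
    stop("missing joint(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  pos <- positions[joints, , drop = FALSE]
  if (!all(is.finite(pos))) {
    stop("joint coordinates must be finite", call. = FALSE)
  }
  if (!is.numeric(timestamp) || length(timestamp) != 1L ||
    !is.finite(timestamp) || timestamp < 0) {
    stop("timestamp must be a single non-negative number", call. = FALSE)
  }
  colnames(pos) <- c("x", "y", "z")
  structure(
    list(timestamp = as.numeric(timestamp), positions = pos),
    class = "skeleton_frame"
  )
}

#' @export
print.skeleton_frame <- function(x, ...) {
  cat(
    "<skeleton_frame> t =", format(x$timestamp), "s,",
    nrow(x$positions), "joints\n"
  )
  invisible(x)
}

#' Construct a skeleton sequence
#'
#' An ordered list of frames with strictly increasing timestamps, a nominal
#' frame rate, and an optional activity label. The frame rate is stored
#' redundantly; when the sequence spans more than one frame, it is checked
#' against the timestamp span and a mismatch beyond 1% raises a warning.
#'
#' @param frames List of [skeleton_frame()] objects.
#' @param fps Nominal frames per second (> 0).
#' @param label Optional activity name.
#' @return An object of class `skeleton_sequence`: a list with elements
#'   `frames`, `fps` and `label`.
#' @export
skeleton_sequence <- function(frames, fps, label = NULL) {
  if (!is.list(frames) ||
    !all(vapply(frames, inherits, logical(1), "skeleton_frame"))) {
    stop("frames must be a list of skeleton_frame objects", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  ts <- vapply(frames, `[[`, numeric(1), "timestamp")
  if (length(ts) > 1L && any(diff(ts) <= 0)) {
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  }
  if (length(ts) > 1L) {
    implied <- (length(ts) - 1L) / (ts[length(ts)] - ts[1L])
    if (abs(implied - fps) / fps > 0.01) {
      warning(sprintf(
        "declared fps %.6g inconsistent with timestamps (implied %.6g)",
        fps, implied
      ), call. = FALSE)
    }
  }
  structure(
    list(frames = frames, fps = as.numeric(fps), label = label),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(
    "<skeleton_sequence>", length(x$frames), "frames @", x$fps, "fps",
    if (!is.null(x$label)) paste0("[", x$label, "]") else "", "\n"
  )
  invisible(x)
}

#' Duration of a skeleton sequence
#'
#' Timestamp span from first to last frame, in seconds (0 for sequences with
#' fewer than two frames).
#'
#' @param seq A [skeleton_sequence()].
#' @return Duration in seconds.
#' @export
sequence_duration <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  n <- length(seq$frames)
  if (n < 2L) {
    return(0)
  }
  seq$frames[[n]]$timestamp - seq$frames[[1L]]$timestamp
}

#' Mirror a skeleton frame across the body midline
#'
#' Swaps left/right joint labels and reflects the `x` coordinate about the
#' body midline (the `x` of `HIP_CENTER`). Center-line joints keep their
#' labels with `x` reflected. The operation is an involution and preserves
#' all inter-joint distances.
#'
#' @param frame A [skeleton_frame()] containing `HIP_CENTER`.
#' @return The mirrored `skeleton_frame`.
#' @export
#' @examples
#' f <- skeleton_frame(standing_positions())
#' identical_frames <- all.equal(f, mirror_frame(mirror_frame(f)))
mirror_frame <- function(frame) {
  stopifnot(inherits(frame, "skeleton_frame"))
  pos <- frame$positions
  if (!"HIP_CENTER" %in% rownames(pos)) {
    stop("mirror_frame needs HIP_CENTER to define the body midline",
      call. = FALSE
    )
  }
  mid <- pos["HIP_CENTER", "x"]
  out <- pos
  rownames(out) <- mirror_joint(rownames(pos))
  out[, "x"] <- 2 * mid - out[, "x"]
  skeleton_frame(out, frame$timestamp, joints = sort(rownames(out)))
}

#' Mirror every frame of a sequence
#'
#' @param seq A [skeleton_sequence()].
#' @return The sequence with every frame passed through [mirror_frame()].
#' @export
mirror_sequence <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  skeleton_sequence(lapply(seq$frames, mirror_frame), seq$fps, seq$label)
}

#' A neutral standing posture
#'
#' Convenience joint-position matrix for a symmetric subject standing
#' upright facing the sensor, used in examples and tests.
#'
#' @param body Optional body model from [generate_participant()]; defaults
#'   to mid-range segment lengths.
#' @return 20 x 3 numeric matrix of joint positions in meters.
#' @export
standing_positions <- function(body = NULL) {
  if (is.null(body)) {
    body <- .midrange_body()
  }
  .build_frame_positions(body, .neutral_pose())
}
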