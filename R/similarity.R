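# Bone-angle similarity: the recognizer's unit of information is the angle
# formed by each relevant bone in the observation vs. the key sample.

.DEGENERATE_BONE_TOL <- 1e-6

#' Direction of a bone within a frame
#'
#' The unit vector from the proximal to the distal endpoint of a bone.
#'
#' @param frame A [skeleton_frame()] containing both endpoints.
#' @param bone A canonical bone identifier (see [bone_id()]).
#' @return An object of class `bone_direction`: list with `bone` and the
#'   unit 3-vector `v`.
#' @export
#' @examples
#' f <- skeleton_frame(standing_positions())
#' bone_direction(f, "SHOULDER_R-ELBOW_R")
bone_direction <- function(frame, bone) {
  stopifnot(inherits(frame, "skeleton_frame"), length(bone) == 1L)
  ep <- .bone_endpoints(bone)
  nm <- c(KINECT_JOINTS[ep[1L, 1L]], KINECT_JOINTS[ep[1L, 2L]])
  missing <- setdiff(nm, rownames(frame$positions))
  if (length(missing) > 0L) {
    stop("joint ", missing[1L], " not present in frame", call. = FALSE)
  }
  d <- frame$positions[nm[2L], ] - frame$positions[nm[1L], ]
  len <- sqrt(sum(d^2))
  if (len < .DEGENERATE_BONE_TOL) {
    stop("degenerate bone ", bone, ": endpoints coincide within 1e-6 m",
      call. = FALSE
    )
  }
  structure(list(bone = bone, v = d / len), class = "bone_direction")
}

#' Similarity between two bone directions
#'
#' `100 * (1 - theta / 180)` where `theta` is the 3-D angle (degrees)
#' between the two unit vectors: 100 for parallel, 50 for perpendicular,
#' 0 for antiparallel. Symmetric in its arguments and bounded in
#' \[0, 100\].
#'
#' @param dir_a,dir_b [bone_direction()] objects (or plain unit 3-vectors)
#'   for the same bone.
#' @return Similarity percent in \[0, 100\].
#' @export
bone_similarity <- function(dir_a, dir_b) {
  va <- if (inherits(dir_a, "bone_direction")) dir_a$v else dir_a
  vb <- if (inherits(dir_b, "bone_direction")) dir_b$v else dir_b
  if (inherits(dir_a, "bone_direction") && inherits(dir_b, "bone_direction") &&
    !identical(dir_a$bone, dir_b$bone)) {
    stop("directions belong to different bones (", dir_a$bone, " vs ",
      dir_b$bone, ")",
      call. = FALSE
    )
  }
  d <- sum(va * vb)
  theta <- acos(min(1, max(-1, d)))
  100 * (1 - theta / pi)
}

# vectorized: unit-direction matrix (k x 3) for a position matrix and
# endpoint index matrix; NA rows for degenerate bones if allow_na, else error
.dir_matrix <- function(pos, ep, allow_na = FALSE) {
  d <- pos[ep[, 2L], , drop = FALSE] - pos[ep[, 1L], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  deg <- len < .DEGENERATE_BONE_TOL
  if (any(deg)) {
    if (!allow_na) {
      stop("degenerate bone: endpoints coincide within 1e-6 m", call. = FALSE)
    }
    len[deg] <- NA_real_
  }
  d / len
}

# vectorized row-wise bone similarity between two direction matrices
.sim_rows <- function(da, db) {
  d <- rowSums(da * db)
  d[d > 1] <- 1
  d[d < -1] <- -1
  100 * (1 - acos(d) / pi)
}

#' Body similarity between two frames over relevant bones
#'
#' Computes the per-bone similarity for every relevant bone and aggregates
#' them as an unweighted arithmetic mean, so with `n` relevant bones each
#' bone contributes `1/n` of the final score: fewer relevant bones give each
#' bone proportionally more influence. Joints that are not endpoints of a
#' relevant bone never affect the result.
#'
#' @param frame Observation [skeleton_frame()].
#' @param template_frame Key-sample [skeleton_frame()].
#' @param relevant_bones Non-empty character vector of canonical bone ids.
#' @param template_name Name recorded in the report.
#' @return An object of class `similarity_report`: list with
#'   `template_name`, `bone_sims` (named percent vector) and
#'   `body_similarity` (their mean).
#' @export
body_similarity <- function(frame, template_frame, relevant_bones,
                            template_name = "template") {
  stopifnot(
    inherits(frame, "skeleton_frame"),
    inherits(template_frame, "skeleton_frame")
  )
  if (length(relevant_bones) == 0L) {
    stop("relevant_bones must be non-empty", call. = FALSE)
  }
  ep <- .bone_endpoints(relevant_bones)
  need <- unique(KINECT_JOINTS[as.vector(ep)])
  for (fr in list(frame, template_frame)) {
    missing <- setdiff(need, rownames(fr$positions))
    if (length(missing) > 0L) {
      stop("joint ", missing[1L], " not present in frame", call. = FALSE)
    }
  }
  ia <- .reindex_endpoints(ep, rownames(frame$positions))
  ib <- .reindex_endpoints(ep, rownames(template_frame$positions))
  sims <- .sim_rows(
    .dir_matrix(frame$positions, ia),
    .dir_matrix(template_frame$positions, ib)
  )
  names(sims) <- relevant_bones
  structure(
    list(
      template_name = template_name,
      bone_sims = sims,
      body_similarity = mean(sims)
    ),
    class = "similarity_report"
  )
}

# endpoint indices are defined against the full 20-joint ordering; remap
# them to the row order of an arbitrary (possibly partial) position matrix
.reindex_endpoints <- function(ep, rn) {
  cbind(
    match(KINECT_JOINTS[ep[, 1L]], rn),
    match(KINECT_JOINTS[ep[, 2L]], rn)
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report> %s: body %.2f%% over %d bones\n",
    x$template_name, x$body_similarity, length(x$bone_sims)
  ))
  invisible(x)
}

#' Similarity between an observation window and a movement template
#'
#' The window is uniformly resampled (nearest frame) to the template's frame
#' count and the result is the mean over template frames of the body
#' similarity between matched frames. Matching assumes the movement is
#' performed at the template's speed: windows whose duration differs from
#' the template's by more than `tolerance` raise a speed-mismatch error.
#'
#' @param window Observation [skeleton_sequence()] (>= 2 frames).
#' @param template Key-sample [skeleton_sequence()] (>= 2 frames).
#' @param relevant_bones Non-empty character vector of canonical bone ids.
#' @param tolerance Allowed relative duration mismatch (default 0.2).
#' @return Similarity percent in \[0, 100\].
#' @export
sequence_similarity <- function(window, template, relevant_bones,
                                tolerance = 0.2) {
  stopifnot(
    inherits(window, "skeleton_sequence"),
    inherits(template, "skeleton_sequence")
  )
  if (length(relevant_bones) == 0L) {
    stop("relevant_bones must be non-empty", call. = FALSE)
  }
  if (length(window$frames) < 2L || length(template$frames) < 2L) {
    stop("window and template need at least 2 frames", call. = FALSE)
  }
  dw <- sequence_duration(window)
  dt <- sequence_duration(template)
  if (abs(dw - dt) > tolerance * dt) {
    stop(sprintf(
      "speed mismatch: window duration %.3f s outside %.0f%% of template %.3f s",
      dw, 100 * tolerance, dt
    ), call. = FALSE)
  }
  m <- length(template$frames)
  n <- length(window$frames)
  map <- .resample_map(n, m)
  sims <- vapply(seq_len(m), function(i) {
    body_similarity(
      window$frames[[map[i]]], template$frames[[i]],
      relevant_bones
    )$body_similarity
  }, numeric(1))
  mean(sims)
}

# nearest-frame uniform resampling: indices into an n-frame window for each
# of m template frames
.resample_map <- function(n, m) {
  phase <- if (m == 1L) 1 else (seq_len(m) - 1L) / (m - 1L)
  pmin(n, pmax(1L, as.integer(round(phase * (n - 1L))) + 1L))
}
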