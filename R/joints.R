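# Joint enumeration and bone topology (Kinect-v1 skeleton).

KINECT_JOINTS <- c(
  "HIP_CENTER", "SPINE", "SHOULDER_CENTER", "HEAD",
  "SHOULDER_L", "SHOULDER_R", "ELBOW_L", "ELBOW_R",
  "WRIST_L", "WRIST_R", "HAND_L", "HAND_R",
  "HIP_L", "HIP_R", "KNEE_L", "KNEE_R",
  "ANKLE_L", "ANKLE_R", "FOOT_L", "FOOT_R"
)

# 19 tree edges spanning all 20 joints, plus the two girdle edges
# (SHOULDER_L-SHOULDER_R, HIP_L-HIP_R) so that extremity-only joint sets
# still induce a cross-body reference bone.
.TOPOLOGY_EDGES <- matrix(c(
  "HIP_CENTER",      "SPINE",
  "SPINE",           "SHOULDER_CENTER",
  "SHOULDER_CENTER", "HEAD",
  "SHOULDER_CENTER", "SHOULDER_L",
  "SHOULDER_CENTER", "SHOULDER_R",
  "SHOULDER_L",      "ELBOW_L",
  "SHOULDER_R",      "ELBOW_R",
  "ELBOW_L",         "WRIST_L",
  "ELBOW_R",         "WRIST_R",
  "WRIST_L",         "HAND_L",
  "WRIST_R",         "HAND_R",
  "HIP_CENTER",      "HIP_L",
  "HIP_CENTER",      "HIP_R",
  "HIP_L",           "KNEE_L",
  "HIP_R",           "KNEE_R",
  "KNEE_L",          "ANKLE_L",
  "KNEE_R",          "ANKLE_R",
  "ANKLE_L",         "FOOT_L",
  "ANKLE_R",         "FOOT_R",
  "SHOULDER_L",      "SHOULDER_R",
  "HIP_L",           "HIP_R"
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("proximal", "distal")))

#' Names of the 20 tracked skeleton joints
#'
#' The joint vocabulary of Kinect-v1 style skeletal tracking: four center-line
#' joints (hip center, spine, shoulder center, head) and eight left/right
#' pairs covering arms (shoulder, elbow, wrist, hand) and legs (hip, knee,
#' ankle, foot).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' joint_names()
joint_names <- function() KINECT_JOINTS

#' Mirror partner of a joint
#'
#' Swaps the `_L`/`_R` suffix; center-line joints are their own mirror.
#'
#' @param joints Character vector of joint names.
#' @return Character vector of the same length with sides swapped.
#' @export
#' @examples
#' mirror_joint(c("WRIST_R", "SPINE"))
mirror_joint <- function(joints) {
  .check_joints(joints)
  out <- joints
  left <- grepl("_L$", joints)
  right <- grepl("_R$", joints)
  out[left] <- sub("_L$", "_R", joints[left])
  out[right] <- sub("_R$", "_L", joints[right])
  out
}

.check_joints <- function(joints) {
  bad <- setdiff(joints, KINECT_JOINTS)
  if (length(bad) > 0L) {
    stop("unknown joint name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(joints)
}

#' Skeleton bone topology
#'
#' The fixed edge set connecting the 20 joints: the 19 standard Kinect-v1
#' edges (which form a spanning tree) augmented with two girdle edges,
#' `SHOULDER_L-SHOULDER_R` and `HIP_L-HIP_R`. The girdle edges ensure that
#' joint subsets restricted to the extremities plus shoulders and hips still
#' induce at least one stable cross-body bone.
#'
#' @return A data frame with columns `proximal`, `distal` and `bone`
#'   (the canonical `"PROXIMAL-DISTAL"` identifier), one row per edge (21).
#' @export
#' @examples
#' skeleton_topology()
skeleton_topology <- function() {
  data.frame(
    proximal = .TOPOLOGY_EDGES[, "proximal"],
    distal = .TOPOLOGY_EDGES[, "distal"],
    bone = paste(.TOPOLOGY_EDGES[, "proximal"], .TOPOLOGY_EDGES[, "distal"],
      sep = "-"
    ),
    stringsAsFactors = FALSE
  )
}

#' Canonical bone identifier
#'
#' A bone is an edge of the topology, identified regardless of endpoint
#' order; the canonical form orders endpoints as in [skeleton_topology()].
#'
#' @param a,b Joint names (vectors of equal length).
#' @return Character vector of canonical bone identifiers.
#' @export
#' @examples
#' bone_id("ELBOW_R", "SHOULDER_R") # "SHOULDER_R-ELBOW_R"
bone_id <- function(a, b) {
  .check_joints(a)
  .check_joints(b)
  topo <- skeleton_topology()
  fwd <- match(paste(a, b, sep = "-"), topo$bone)
  rev <- match(paste(b, a, sep = "-"), topo$bone)
  idx <- ifelse(is.na(fwd), rev, fwd)
  if (anyNA(idx)) {
    bad <- paste(a[is.na(idx)], b[is.na(idx)], sep = "-")
    stop("not a bone of the topology: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  topo$bone[idx]
}

#' Bones induced by a joint subset
#'
#' Returns the topology edges whose endpoints both lie in `joints`. This is
#' how an activity's relevant-joint set determines its relevant bones: a
#' smaller joint set induces fewer bones, so each bone weighs more in the
#' aggregated body similarity.
#'
#' @param joints Character vector of joint names (may be empty).
#' @param topology Bone topology as returned by [skeleton_topology()].
#' @return Character vector of canonical bone identifiers, in topology order.
#' @export
#' @examples
#' bones_induced(c("SHOULDER_R", "ELBOW_R", "WRIST_R"))
bones_induced <- function(joints, topology = skeleton_topology()) {
  .check_joints(joints)
  keep <- topology$proximal %in% joints & topology$distal %in% joints
  topology$bone[keep]
}

# endpoint row indices (into the 20-joint position matrix) for a bone vector
.bone_endpoints <- function(bones) {
  topo <- skeleton_topology()
  idx <- match(bones, topo$bone)
  if (anyNA(idx)) {
    stop("unknown bone identifier(s): ",
      paste(bones[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  cbind(
    proximal = match(topo$proximal[idx], KINECT_JOINTS),
    distal = match(topo$distal[idx], KINECT_JOINTS)
  )
}

# mirror a canonical bone id (swap sides of both endpoints, re-canonicalize)
.mirror_bone <- function(bones) {
  ep <- .bone_endpoints(bones)
  bone_id(
    mirror_joint(KINECT_JOINTS[ep[, "proximal"]]),
    mirror_joint(KINECT_JOINTS[ep[, "distal"]])
  )
}
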