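# Shared fixtures and independent oracles.

# random joint positions: well spread so no bone is near-degenerate
rand_positions <- function() {
  m <- matrix(stats::runif(60, -1, 2), ncol = 3,
    dimnames = list(joint_names(), c("x", "y", "z"))
  )
  m
}

rand_frame <- function(t = 0) skeleton_frame(rand_positions(), t)

# independent oracle: mean over bones of 100 * (1 - angle/180), written as
# a plain loop from the bone-id strings (no package internals)
oracle_body_similarity <- function(f1, f2, bones) {
  sims <- numeric(length(bones))
  for (i in seq_along(bones)) {
    ep <- strsplit(bones[i], "-", fixed = TRUE)[[1]]
    u <- f1$positions[ep[2], ] - f1$positions[ep[1], ]
    v <- f2$positions[ep[2], ] - f2$positions[ep[1], ]
    u <- u / sqrt(sum(u^2))
    v <- v / sqrt(sum(v^2))
    theta <- acos(min(1, max(-1, sum(u * v))))
    sims[i] <- 100 * (1 - theta / pi)
  }
  mean(sims)
}

# independent oracle for movement matching: resample then average
oracle_sequence_similarity <- function(window, template, bones) {
  m <- length(template$frames)
  n <- length(window$frames)
  total <- 0
  for (i in seq_len(m)) {
    phase <- (i - 1) / (m - 1)
    j <- round(phase * (n - 1)) + 1
    total <- total + oracle_body_similarity(
      window$frames[[j]], template$frames[[i]], bones
    )
  }
  total / m
}

# a small posture-template registry built from perturbations of a base
# frame; rotate_arm tilts the right forearm by `deg` about the x axis
tilt_wrist <- function(pos, deg) {
  rad <- deg * pi / 180
  d <- pos["WRIST_R", ] - pos["ELBOW_R", ]
  len <- sqrt(sum(d^2))
  rot <- c(
    d[1],
    d[2] * cos(rad) - d[3] * sin(rad),
    d[2] * sin(rad) + d[3] * cos(rad)
  )
  pos["WRIST_R", ] <- pos["ELBOW_R", ] + rot
  pos["HAND_R", ] <- pos["WRIST_R", ] + c(0, -len / 3, 0)
  pos
}
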