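# Seeded parametric generator of labeled skeleton sequences: a stand-in for
# sensor recordings. Motion is angle-driven forward kinematics on a rigid
# segment model, so noiseless frames preserve every segment length exactly.

.d2r <- pi / 180

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  }
  set.seed(seed)
  code
}

#' Derive a reproducible RNG seed from a master seed and labels
#'
#' Folds the labels into a 31-bit integer so every (participant, activity,
#' repetition) trial gets its own deterministic RNG stream.
#'
#' @param master_seed Integer master seed.
#' @param ... Further labels (coerced to character).
#' @return Integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, ...) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

#' Default body-proportion ranges
#'
#' Uniform sampling ranges (meters) for each rigid segment of the body
#' model, spanning typical adult proportions.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_body_ranges <- function() {
  list(
    trunk_lower = c(0.18, 0.24),
    trunk_upper = c(0.20, 0.26),
    neck = c(0.08, 0.12),
    shoulder_halfwidth = c(0.17, 0.21),
    hip_halfwidth = c(0.10, 0.14),
    upper_arm = c(0.25, 0.32),
    forearm = c(0.22, 0.28),
    hand = c(0.08, 0.10),
    thigh = c(0.38, 0.46),
    shank = c(0.36, 0.44),
    foot = c(0.18, 0.24)
  )
}

.body_model <- function(id, segments) {
  structure(
    list(
      participant_id = id,
      segments = segments,
      stance_height = 0.08 + segments[["shank"]] + segments[["thigh"]] +
        segments[["trunk_lower"]] + segments[["trunk_upper"]] +
        segments[["neck"]]
    ),
    class = "body_model"
  )
}

.midrange_body <- function() {
  r <- default_body_ranges()
  .body_model("midrange", vapply(r, mean, numeric(1)))
}

#' Sample a participant's body model
#'
#' Draws each segment length uniformly within its range; left/right
#' symmetric by construction. Reproducible per seed.
#'
#' @param ranges Ranges as from [default_body_ranges()].
#' @param seed Integer seed.
#' @return An object of class `body_model` with `participant_id`,
#'   `segments` (named meters) and `stance_height`.
#' @export
generate_participant <- function(ranges = default_body_ranges(), seed = 1L) {
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] > r[2L] || r[1L] <= 0) {
      stop("invalid range for segment ", nm, call. = FALSE)
    }
  }
  segs <- .with_seed(seed, vapply(
    ranges, function(r) stats::runif(1, r[1L], r[2L]), numeric(1)
  ))
  .body_model(paste0("P", seed), segs)
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf(
    "<body_model> %s: stance %.2f m, %d segments\n",
    x$participant_id, x$stance_height, length(x$segments)
  ))
  invisible(x)
}

#' Expected bone lengths of a body model
#'
#' Every generated noiseless frame reproduces these lengths exactly (the
#' kinematics only rotate segments).
#'
#' @param body A `body_model`.
#' @return Named numeric vector over the 21 topology bones (meters).
#' @export
body_bone_lengths <- function(body) {
  s <- body$segments
  c(
    "HIP_CENTER-SPINE" = s[["trunk_lower"]],
    "SPINE-SHOULDER_CENTER" = s[["trunk_upper"]],
    "SHOULDER_CENTER-HEAD" = s[["neck"]],
    "SHOULDER_CENTER-SHOULDER_L" = s[["shoulder_halfwidth"]],
    "SHOULDER_CENTER-SHOULDER_R" = s[["shoulder_halfwidth"]],
    "SHOULDER_L-ELBOW_L" = s[["upper_arm"]],
    "SHOULDER_R-ELBOW_R" = s[["upper_arm"]],
    "ELBOW_L-WRIST_L" = s[["forearm"]],
    "ELBOW_R-WRIST_R" = s[["forearm"]],
    "WRIST_L-HAND_L" = s[["hand"]],
    "WRIST_R-HAND_R" = s[["hand"]],
    "HIP_CENTER-HIP_L" = s[["hip_halfwidth"]],
    "HIP_CENTER-HIP_R" = s[["hip_halfwidth"]],
    "HIP_L-KNEE_L" = s[["thigh"]],
    "HIP_R-KNEE_R" = s[["thigh"]],
    "KNEE_L-ANKLE_L" = s[["shank"]],
    "KNEE_R-ANKLE_R" = s[["shank"]],
    "ANKLE_L-FOOT_L" = s[["foot"]],
    "ANKLE_R-FOOT_R" = s[["foot"]],
    "SHOULDER_L-SHOULDER_R" = 2 * s[["shoulder_halfwidth"]],
    "HIP_L-HIP_R" = 2 * s[["hip_halfwidth"]]
  )
}

# --- pose model ------------------------------------------------------------
# A pose holds joint angles (radians) and the root position. Convention:
# subject faces the sensor; forward (toward the sensor) is -z, up is +y.
# flex > 0 swings a limb forward, abd > 0 swings a leg outward, knee/elbow
# flexion folds the distal segment backward/upward.

.neutral_pose <- function() {
  list(
    root = c(0, NA, 2.5), # NA root height = standing height for the body
    lean = 0,
    arm_L = c(flex = 0, elbow = 0),
    arm_R = c(flex = 0, elbow = 0),
    leg_L = c(flex = 0, abd = 0, knee = 0),
    leg_R = c(flex = 0, abd = 0, knee = 0)
  )
}

.rot_x <- function(v, a) {
  c(
    v[1L],
    v[2L] * cos(a) - v[3L] * sin(a),
    v[2L] * sin(a) + v[3L] * cos(a)
  )
}

.rot_z <- function(v, a) {
  c(
    v[1L] * cos(a) - v[2L] * sin(a),
    v[1L] * sin(a) + v[2L] * cos(a),
    v[3L]
  )
}

# forward kinematics: 20 x 3 position matrix from body + pose
.build_frame_positions <- function(body, pose) {
  s <- body$segments
  root <- pose$root
  if (is.na(root[2L])) {
    root[2L] <- 0.08 + s[["shank"]] + s[["thigh"]]
  }
  pos <- matrix(NA_real_, nrow = 20L, ncol = 3L,
    dimnames = list(KINECT_JOINTS, c("x", "y", "z"))
  )
  up <- c(0, 1, 0)
  trunk_dir <- .rot_x(up, -pose$lean) # lean > 0 tips the trunk forward (-z)
  pos["HIP_CENTER", ] <- root
  pos["SPINE", ] <- root + s[["trunk_lower"]] * trunk_dir
  pos["SHOULDER_CENTER", ] <- pos["SPINE", ] + s[["trunk_upper"]] * trunk_dir
  pos["HEAD", ] <- pos["SHOULDER_CENTER", ] + s[["neck"]] * trunk_dir
  for (side in c("L", "R")) {
    sgn <- if (side == "R") 1 else -1
    sh <- pos["SHOULDER_CENTER", ] + c(sgn * s[["shoulder_halfwidth"]], 0, 0)
    pos[paste0("SHOULDER_", side), ] <- sh
    arm <- pose[[paste0("arm_", side)]]
    u_dir <- .rot_x(c(0, -1, 0), arm[["flex"]])
    f_dir <- .rot_x(c(0, -1, 0), arm[["flex"]] + arm[["elbow"]])
    pos[paste0("ELBOW_", side), ] <- sh + s[["upper_arm"]] * u_dir
    pos[paste0("WRIST_", side), ] <-
      pos[paste0("ELBOW_", side), ] + s[["forearm"]] * f_dir
    pos[paste0("HAND_", side), ] <-
      pos[paste0("WRIST_", side), ] + s[["hand"]] * f_dir

    hip <- root + c(sgn * s[["hip_halfwidth"]], 0, 0)
    pos[paste0("HIP_", side), ] <- hip
    leg <- pose[[paste0("leg_", side)]]
    th_dir <- .rot_x(.rot_z(c(0, -1, 0), sgn * leg[["abd"]]), leg[["flex"]])
    sh_rot <- leg[["flex"]] - leg[["knee"]]
    sk_dir <- .rot_x(.rot_z(c(0, -1, 0), sgn * leg[["abd"]]), sh_rot)
    ft_dir <- .rot_x(.rot_z(c(0, 0, -1), sgn * leg[["abd"]]), sh_rot)
    pos[paste0("KNEE_", side), ] <- hip + s[["thigh"]] * th_dir
    pos[paste0("ANKLE_", side), ] <-
      pos[paste0("KNEE_", side), ] + s[["shank"]] * sk_dir
    pos[paste0("FOOT_", side), ] <-
      pos[paste0("ANKLE_", side), ] + s[["foot"]] * ft_dir
  }
  pos
}

# --- noise model -----------------------------------------------------------

#' Per-joint tracking-noise profile
#'
#' Skeletal tracking precision is strongly joint-dependent: axial and
#' girdle joints (trunk, shoulders, hips) barely move and are tracked most
#' stably; arm joints are intermediate; leg joints suffer self-occlusion
#' and floor clutter and are tracked worst. The generator multiplies the
#' baseline `jitter_sd` and `spike_prob` of [noise_params()] by these
#' factors (spike magnitude is unscaled: an inference error is large
#' wherever it happens).
#'
#' @return Named numeric vector of multipliers over the 20 joints
#'   (axial/girdle 0.25, head 0.5, arm joints 1, leg joints 2.5).
#' @export
joint_noise_profile <- function() {
  prof <- stats::setNames(rep(1, 20L), KINECT_JOINTS)
  prof[c(
    "HIP_CENTER", "SPINE", "SHOULDER_CENTER",
    "SHOULDER_L", "SHOULDER_R", "HIP_L", "HIP_R"
  )] <- 0.25
  prof["HEAD"] <- 0.5
  prof[c(
    "KNEE_L", "KNEE_R", "ANKLE_L", "ANKLE_R", "FOOT_L", "FOOT_R"
  )] <- 2.5
  prof
}

#' Noise and execution-variability parameters
#'
#' Emulates the error sources of skeletal tracking and of human repetition:
#' per-joint Gaussian jitter each frame, occasional large inference spikes
#' (a covered joint being guessed), a per-repetition execution-scale factor
#' (no two repetitions of a movement have exactly the same amplitude), and
#' the amplitude of involuntary compensatory arm sway during leg activities.
#'
#' @param jitter_sd Baseline per-axis Gaussian jitter SD (m) for an
#'   arm-level joint; each joint's actual SD is this times its
#'   [joint_noise_profile()] factor. Default 0.01.
#' @param spike_prob Baseline probability per joint per frame of an
#'   inference spike, likewise scaled by the joint profile. Default 0.02.
#' @param spike_sd Per-axis SD of a spike displacement (m). Default 0.10.
#' @param sway_amplitude Forward-reach amplitude (m) of the compensatory arm
#'   arc applied to leg activities via [with_balance_sway()]. Default 0.15.
#' @param exec_sd SD of the per-repetition amplitude scale (unitless,
#'   around 1). Default 0.08.
#' @param seed Integer RNG seed for this sequence.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(jitter_sd = 0.01, spike_prob = 0.02,
                         spike_sd = 0.10, sway_amplitude = 0.15,
                         exec_sd = 0.08, seed = 1L) {
  stopifnot(
    jitter_sd >= 0, spike_sd >= 0, sway_amplitude >= 0, exec_sd >= 0,
    spike_prob >= 0, spike_prob <= 1
  )
  structure(
    list(
      jitter_sd = jitter_sd, spike_prob = spike_prob, spike_sd = spike_sd,
      sway_amplitude = sway_amplitude, exec_sd = exec_sd,
      seed = as.integer(seed)
    ),
    class = "noise_params"
  )
}

#' Zero-noise parameters
#'
#' All noise and execution variability off: the generator reproduces the
#' script's noiseless kinematics exactly.
#'
#' @param seed RNG seed (unused when all variability is zero, kept for
#'   interface symmetry).
#' @return A [noise_params()] with every source set to 0.
#' @export
noise_none <- function(seed = 1L) {
  noise_params(
    jitter_sd = 0, spike_prob = 0, spike_sd = 0, sway_amplitude = 0,
    exec_sd = 0, seed = seed
  )
}

# --- activity scripts ------------------------------------------------------

.activity_script <- function(name, kind, duration, extremity, laterality,
                             pose_fun, sway_amplitude = 0) {
  structure(
    list(
      name = name, kind = kind, duration = duration,
      extremity = extremity, laterality = laterality,
      pose_fun = pose_fun, sway_amplitude = sway_amplitude
    ),
    class = "activity_script"
  )
}

#' @export
print.activity_script <- function(x, ...) {
  cat(sprintf(
    "<activity_script> %s (%s, %s, %.1f s)%s\n",
    x$name, x$kind, x$extremity, x$duration,
    if (x$sway_amplitude > 0) {
      sprintf(" + sway %.2f m", x$sway_amplitude)
    } else {
      ""
    }
  ))
  invisible(x)
}

# rising envelope ending at the movement apex
.apex_env <- function(phase) sin(pi * phase / 2)

.script_stand <- function() {
  .activity_script(
    "Stand", "posture", 2, "both", "symmetric",
    function(body, phase, scale) .neutral_pose()
  )
}

.script_stay_seated <- function() {
  .activity_script(
    "Stay Seated", "posture", 2, "both", "symmetric",
    function(body, phase, scale) {
      p <- .neutral_pose()
      flex <- scale * 90 * .d2r
      # knee flexion equal to hip flexion keeps the shank vertical
      p$leg_L <- c(flex = flex, abd = 0, knee = flex)
      p$leg_R <- c(flex = flex, abd = 0, knee = flex)
      s <- body$segments
      p$root <- c(0, 0.08 + s[["shank"]] + s[["thigh"]] * cos(flex), 2.5)
      p
    }
  )
}

.script_walk <- function(backwards = FALSE, side = "R") {
  name <- paste0(
    if (backwards) "Walk Backwards" else "Walk",
    " [", if (side == "R") "D" else "I", "]"
  )
  hip_amp <- if (backwards) 15 else 25
  arm_amp <- if (backwards) 10 else 20
  knee_amp <- if (backwards) 45 else 30
  knee_shift <- if (backwards) pi else 0
  lean <- if (backwards) -3 else 5
  vz <- if (backwards) 0.4 else -0.4
  .activity_script(
    name, "movement", 2, "both", if (side == "R") "D" else "I",
    function(body, phase, scale) {
      p <- .neutral_pose()
      theta <- 2 * pi * 2 * phase # two gait cycles per repetition
      lead <- side
      off <- c(0, pi)
      names(off) <- c(lead, setdiff(c("L", "R"), lead))
      for (s2 in c("L", "R")) {
        th <- theta + off[[s2]]
        p[[paste0("leg_", s2)]] <- c(
          flex = scale * hip_amp * .d2r * sin(th),
          abd = 0,
          knee = scale * knee_amp * .d2r * (1 - cos(th + knee_shift)) / 2
        )
        # contralateral arm swing
        p[[paste0("arm_", s2)]] <- c(
          flex = -scale * arm_amp * .d2r * sin(th), elbow = 0
        )
      }
      p$lean <- scale * lean * .d2r
      p$root <- c(0, NA, 2.5 + vz * phase * 2)
      p
    }
  )
}

.script_drink <- function(side = "R") {
  .activity_script(
    paste0("Drink [", if (side == "R") "D" else "I", "]"),
    "movement", 2, "arm", if (side == "R") "D" else "I",
    function(body, phase, scale) {
      p <- .neutral_pose()
      env <- .apex_env(phase)
      p[[paste0("arm_", side)]] <- c(
        flex = scale * 35 * .d2r * env,
        elbow = scale * 110 * .d2r * env
      )
      p
    }
  )
}

.script_grab_object <- function(side = "R") {
  .activity_script(
    paste0("Grab Object [", if (side == "R") "D" else "I", "]"),
    "movement", 2, "arm", if (side == "R") "D" else "I",
    function(body, phase, scale) {
      p <- .neutral_pose()
      env <- .apex_env(phase)
      p[[paste0("arm_", side)]] <- c(
        flex = scale * 25 * .d2r * env,
        elbow = scale * 15 * .d2r * (1 - env)
      )
      # reaching forward recruits the trunk
      p$lean <- scale * 12 * .d2r * env
      p
    }
  )
}

.script_leg_flexion <- function(side = "L") {
  .activity_script(
    paste0("Leg Flexion [", if (side == "R") "D" else "I", "]"),
    "movement", 2, "leg", if (side == "R") "D" else "I",
    function(body, phase, scale) {
      p <- .neutral_pose()
      env <- .apex_env(phase)
      p[[paste0("leg_", side)]] <- c(
        flex = scale * 30 * .d2r * env,
        abd = 0,
        knee = scale * 80 * .d2r * env
      )
      p
    }
  )
}

.script_leg_circular_swing <- function(side = "L") {
  .activity_script(
    paste0("Leg Circular Swing [", if (side == "R") "D" else "I", "]"),
    "movement", 2, "leg", if (side == "R") "D" else "I",
    function(body, phase, scale) {
      p <- .neutral_pose()
      # straight-knee leg whose ankle traces a circle (sagittal x frontal)
      p[[paste0("leg_", side)]] <- c(
        flex = scale * (20 + 12 * sin(2 * pi * phase)) * .d2r,
        abd = scale * (10 + 12 * cos(2 * pi * phase)) * .d2r,
        knee = 0
      )
      p
    }
  )
}

#' Scripts for the eight study activities
#'
#' Deterministic kinematic generators for Stand, Stay Seated, Walk \[D\],
#' Walk Backwards \[D\] (the sink activities) and Drink \[D\], Grab Object
#' \[D\], Leg Flexion \[I\], Leg Circular Swing \[I\] (the bounded
#' activities). Motion primitives are the simplest kinematics that keep the
#' eight classes separable in the noiseless limit while remaining
#' confusable under sensor noise and compensatory sway.
#'
#' @return Named list of `activity_script` objects.
#' @export
#' @examples
#' names(activity_scripts())
activity_scripts <- function() {
  scripts <- list(
    .script_stand(),
    .script_stay_seated(),
    .script_walk(backwards = FALSE, side = "R"),
    .script_walk(backwards = TRUE, side = "R"),
    .script_drink(side = "R"),
    .script_grab_object(side = "R"),
    .script_leg_flexion(side = "L"),
    .script_leg_circular_swing(side = "L")
  )
  stats::setNames(scripts, vapply(scripts, `[[`, character(1), "name"))
}

# internal: side-parametric script factory (for mirror-consistency tests)
.script_factory <- function(name) {
  switch(name,
    "Walk" = function(side) .script_walk(FALSE, side),
    "Walk Backwards" = function(side) .script_walk(TRUE, side),
    "Drink" = .script_drink,
    "Grab Object" = .script_grab_object,
    "Leg Flexion" = .script_leg_flexion,
    "Leg Circular Swing" = .script_leg_circular_swing,
    stop("no side-parametric factory for ", name, call. = FALSE)
  )
}

#' Superimpose compensatory arm sway on a leg activity
#'
#' Adds a slow forward-reach arc of the contralateral (right) arm to a
#' leg-activity script: the involuntary balancing motion that makes leg
#' activities resemble an arm reach. Leg-bone trajectories are unchanged;
#' the label is unchanged.
#'
#' @param script A leg-activity `activity_script`.
#' @param sway_amplitude Forward displacement amplitude of the wrist (m).
#' @return The script with sway superimposed.
#' @export
with_balance_sway <- function(script, sway_amplitude) {
  stopifnot(inherits(script, "activity_script"), sway_amplitude >= 0)
  if (script$extremity != "leg") {
    stop("balance sway applies only to leg activities", call. = FALSE)
  }
  if (sway_amplitude == 0) {
    return(script)
  }
  base_fun <- script$pose_fun
  out <- script
  out$sway_amplitude <- sway_amplitude
  out$pose_fun <- function(body, phase, scale, sway_scale = 1) {
    p <- base_fun(body, phase, scale)
    arm_len <- body$segments[["upper_arm"]] + body$segments[["forearm"]]
    amp <- min(0.99, sway_scale * sway_amplitude / arm_len)
    p$arm_R[["flex"]] <- p$arm_R[["flex"]] + asin(amp) * .apex_env(phase)
    p
  }
  out
}

# --- sequence generation ---------------------------------------------------

#' Generate a labeled synthetic skeleton sequence
#'
#' Builds the noiseless kinematic trajectory from the script (scaled by a
#' per-repetition execution factor drawn from `noise`), then adds per-joint
#' Gaussian jitter and inference spikes. Deterministic given `noise$seed`.
#' With all noise parameters zero the output equals the noiseless script
#' exactly.
#'
#' @param script An `activity_script` (see [activity_scripts()],
#'   [with_balance_sway()]).
#' @param body A `body_model` from [generate_participant()].
#' @param fps Frames per second (> 0).
#' @param noise A [noise_params()].
#' @return A [skeleton_sequence()] labeled with the script name.
#' @export
generate_sequence <- function(script, body, fps = 15, noise = noise_none()) {
  stopifnot(
    inherits(script, "activity_script"), inherits(body, "body_model"),
    inherits(noise, "noise_params"), fps > 0
  )
  n <- as.integer(round(script$duration * fps)) + 1L
  if (script$kind == "movement" && n < 2L) {
    stop("duration * fps must give at least 2 frames for a movement",
      call. = FALSE
    )
  }
  ts <- (seq_len(n) - 1L) / fps
  phase <- if (n == 1L) 0 else ts / script$duration
  takes_sway <- "sway_scale" %in% names(formals(script$pose_fun))
  profile <- joint_noise_profile()
  .with_seed(noise$seed, {
    scale <- max(0.2, 1 + stats::rnorm(1) * noise$exec_sd)
    # involuntary sway varies more across repetitions than the voluntary
    # motion does
    sway_scale <- max(0, 1 + stats::rnorm(1) * 2 * noise$exec_sd)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      pose <- if (takes_sway) {
        script$pose_fun(body, phase[i], scale, sway_scale)
      } else {
        script$pose_fun(body, phase[i], scale)
      }
      pos <- .build_frame_positions(body, pose)
      pos <- pos + matrix(stats::rnorm(60L, sd = noise$jitter_sd),
        nrow = 20L
      ) * profile
      spiked <- stats::runif(20L) < pmin(1, noise$spike_prob * profile)
      if (any(spiked)) {
        pos[spiked, ] <- pos[spiked, , drop = FALSE] +
          matrix(stats::rnorm(3L * sum(spiked), sd = noise$spike_sd),
            ncol = 3L
          )
      }
      frames[[i]] <- skeleton_frame(pos, ts[i])
    }
    skeleton_sequence(frames, fps, label = script$name)
  })
}
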