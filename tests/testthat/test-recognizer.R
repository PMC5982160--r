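test_that("variant joint sets follow the vB/vT/vC rules", {
  drink <- activity_spec("Drink [D]", "arm", "D")
  expect_setequal(
    variant_joints(drink, "vB"),
    c("SHOULDER_R", "ELBOW_R", "WRIST_R", "SHOULDER_L", "HIP_L", "HIP_R")
  )
  expect_setequal(
    variant_joints(drink, "vC"),
    setdiff(joint_names(), c("HAND_L", "HAND_R", "FOOT_L", "FOOT_R", "HEAD"))
  )
  expect_length(variant_joints(drink, "vC"), 15L)

  flex <- activity_spec("Leg Flexion [I]", "leg", "I")
  expect_setequal(
    variant_joints(flex, "vT"),
    c(
      variant_joints(flex, "vB"),
      c("HIP_CENTER", "SPINE", "SHOULDER_CENTER")
    )
  )
  expect_setequal(
    variant_joints(flex, "vB"),
    c("HIP_L", "KNEE_L", "ANKLE_L", "SHOULDER_L", "SHOULDER_R", "HIP_R")
  )
  # hands and feet are never relevant under any variant
  for (v in c("vB", "vT", "vC")) {
    expect_length(
      intersect(
        variant_joints(drink, v),
        c("HAND_L", "HAND_R", "FOOT_L", "FOOT_R")
      ),
      0L
    )
  }
})

test_that("activity_template validates its invariants", {
  f <- rand_frame()
  expect_error(
    activity_template("X", "posture", f, c("HEAD", "FOOT_L")),
    "no bone"
  )
  expect_warning(
    activity_template("Stand", "posture", f,
      relevant_joints = c("HIP_L", "HIP_R"), sink = TRUE
    ),
    "no minimum limit"
  )
  expect_error(
    activity_template("W", "movement", f, c("HIP_L", "HIP_R")),
    ">= 2 frames"
  )
})

test_that("mirror_template flips side, joints and name and is an involution", {
  body <- generate_participant(seed = 3)
  key <- generate_sequence(
    activity_scripts()[["Drink [D]"]], body, 10, noise_none()
  )
  tpl <- activity_template(
    "Drink [D]", "movement", key,
    relevant_joints = variant_joints(activity_spec("Drink [D]", "arm", "D"), "vB"),
    laterality = "D"
  )
  m <- mirror_template(tpl)
  expect_identical(m$name, "Drink [I]")
  expect_identical(m$laterality, "I")
  expect_true("WRIST_L" %in% m$relevant_joints)
  expect_false("WRIST_R" %in% m$relevant_joints)
  mm <- mirror_template(m)
  expect_identical(mm$name, tpl$name)
  expect_setequal(mm$relevant_joints, tpl$relevant_joints)
  for (i in seq_along(key$frames)) {
    expect_equal(
      mm$key_sample$frames[[i]]$positions[joint_names(), ],
      key$frames[[i]]$positions[joint_names(), ],
      tolerance = 1e-12
    )
  }
  sym <- activity_template("Stand", "posture", rand_frame(),
    relevant_joints = c("HIP_L", "HIP_R")
  )
  expect_error(mirror_template(sym), "symmetric")
})

test_that("mirrored observations against mirrored templates score alike", {
  body <- generate_participant(seed = 6)
  key <- generate_sequence(
    activity_scripts()[["Leg Flexion [I]"]], body, 10, noise_none()
  )
  tpl <- activity_template(
    "Leg Flexion [I]", "movement", key,
    relevant_joints = variant_joints(
      activity_spec("Leg Flexion [I]", "leg", "I"), "vT"
    ),
    laterality = "I"
  )
  obs <- generate_sequence(
    activity_scripts()[["Leg Flexion [I]"]], body, 10,
    noise_params(seed = 44)
  )
  m <- mirror_template(tpl)
  expect_equal(
    sequence_similarity(mirror_sequence(obs), m$key_sample, m$relevant_bones),
    sequence_similarity(obs, tpl$key_sample, tpl$relevant_bones),
    tolerance = 1e-9
  )
})

test_that("score_all scores a template's own key sample at 100", {
  body <- generate_participant(seed = 4)
  tpls <- build_study_templates("vT", body, fps = 10)
  obs <- generate_sequence(
    activity_scripts()[["Grab Object [D]"]], body, 10, noise_none()
  )
  reports <- score_all(obs, tpls)
  expect_named(reports, names(tpls))
  expect_equal(reports[["Grab Object [D]"]]$body_similarity, 100)
  expect_identical(score_all(obs, list()), list())
})

test_that("score_all matches independent per-template similarity calls", {
  body <- generate_participant(seed = 12)
  tpls <- build_study_templates("vB", body, fps = 10)[
    c("Drink [D]", "Leg Flexion [I]", "Stand")
  ]
  obs <- generate_sequence(
    activity_scripts()[["Drink [D]"]], body, 10, noise_params(seed = 77)
  )
  reports <- score_all(obs, tpls)
  for (nm in c("Drink [D]", "Leg Flexion [I]")) {
    expect_equal(
      reports[[nm]]$body_similarity,
      oracle_sequence_similarity(
        obs, tpls[[nm]]$key_sample, tpls[[nm]]$relevant_bones
      ),
      tolerance = 1e-9
    )
  }
  # posture: mean over the trailing-second frames vs the key frame
  ts <- vapply(obs$frames, `[[`, numeric(1), "timestamp")
  keep <- which(ts >= max(ts) - 1 - 1e-9)
  manual <- mean(vapply(keep, function(i) {
    oracle_body_similarity(
      obs$frames[[i]], tpls[["Stand"]]$key_sample,
      tpls[["Stand"]]$relevant_bones
    )
  }, numeric(1)))
  expect_equal(reports[["Stand"]]$body_similarity, manual, tolerance = 1e-9)
})

test_that("an activity below its minimum limit is never the prediction", {
  base <- standing_positions()
  obs_pos <- tilt_wrist(base, 10)
  a_pos <- tilt_wrist(base, 13) # closest to the observation
  b_pos <- tilt_wrist(base, 30)
  joints <- c("SHOULDER_R", "ELBOW_R", "WRIST_R")
  mk <- function(name, pos, lim = NULL) {
    activity_template(name, "posture", skeleton_frame(pos),
      relevant_joints = joints, min_limit = lim
    )
  }
  obs <- skeleton_sequence(list(skeleton_frame(obs_pos)), fps = 1)
  # without limits: argmax picks A
  p0 <- predict_activity(obs, list(mk("A", a_pos), mk("B", b_pos)))
  expect_identical(p0$label, "A")
  expect_length(p0$gated, 0L)
  # with a limit above A's score, A is gated even though it scored highest
  lim <- limit_table(c(A = 99.9), global_limit = 0)
  p1 <- predict_activity(obs, list(mk("A", a_pos), mk("B", b_pos)), lim)
  expect_identical(p1$label, "B")
  expect_identical(p1$gated, "A")
  expect_gt(p1$scores[["A"]], p1$scores[["B"]])
  # global limit above every score falls back to UNKNOWN
  p2 <- predict_activity(
    obs, list(mk("A", a_pos), mk("B", b_pos)),
    limit_table(global_limit = 100)
  )
  expect_identical(p2$label, "UNKNOWN")
})

test_that("gating guarantee holds over random observations and limits", {
  set.seed(15)
  joints <- c("SHOULDER_R", "ELBOW_R", "WRIST_R", "HIP_L", "HIP_R")
  tpls <- lapply(1:4, function(k) {
    activity_template(paste0("T", k), "posture", rand_frame(),
      relevant_joints = joints
    )
  })
  for (i in 1:200) {
    obs <- skeleton_sequence(list(rand_frame()), fps = 1)
    lims <- limit_table(
      stats::setNames(stats::runif(4, 0, 100), paste0("T", 1:4)),
      global_limit = stats::runif(1, 0, 60)
    )
    p <- predict_activity(obs, tpls, lims)
    for (g in p$gated) {
      expect_lt(p$scores[[g]], lims$per_activity[[g]])
      expect_false(identical(p$label, g))
    }
    if (p$label != "UNKNOWN") {
      expect_false(p$label %in% p$gated)
      # raising the predicted activity's limit above its score removes it
      lims2 <- lims
      lims2$per_activity[p$label] <- min(100, p$scores[[p$label]] + 1e-6)
      p2 <- predict_activity(obs, tpls, lims2)
      expect_false(identical(p2$label, p$label))
    }
  }
})

test_that("removing all limits reduces prediction to pure argmax", {
  set.seed(16)
  joints <- c("HIP_L", "KNEE_L", "ANKLE_L", "HIP_R")
  tpls <- lapply(1:5, function(k) {
    activity_template(paste0("T", k), "posture", rand_frame(),
      relevant_joints = joints
    )
  })
  for (i in 1:50) {
    obs <- skeleton_sequence(list(rand_frame()), fps = 1)
    p <- predict_activity(obs, tpls, limits = NULL)
    expect_identical(p$label, names(which.max(p$scores)))
  }
})

test_that("prediction is mirror-equivariant", {
  body <- generate_participant(seed = 21)
  tpls <- build_study_templates("vB", body, fps = 10)[
    c("Drink [D]", "Grab Object [D]", "Leg Flexion [I]")
  ]
  mtpls <- lapply(tpls, mirror_template)
  for (s in c(31, 32, 33)) {
    obs <- generate_sequence(
      activity_scripts()[["Drink [D]"]], body, 10, noise_params(seed = s)
    )
    p <- predict_activity(obs, tpls)
    pm <- predict_activity(mirror_sequence(obs), mtpls)
    expect_identical(pm$label, skelmatch:::.flip_name_suffix(p$label))
  }
})

test_that("template files round trip through JSON", {
  body <- generate_participant(seed = 8)
  key <- generate_sequence(
    activity_scripts()[["Walk [D]"]], body, 10, noise_none()
  )
  tpl <- activity_template(
    "Walk [D]", "movement", key,
    relevant_joints = variant_joints(
      activity_spec("Walk [D]", "both", "D"), "vT"
    ),
    laterality = "D", body_use = "global", sink = TRUE, min_limit = 78
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_template(tpl, path)
  back <- read_template(path)
  expect_identical(back$name, tpl$name)
  expect_identical(back$kind, tpl$kind)
  expect_identical(back$min_limit, 78)
  expect_true(back$sink)
  expect_setequal(back$relevant_joints, tpl$relevant_joints)
  expect_identical(
    length(back$key_sample$frames), length(tpl$key_sample$frames)
  )
  expect_identical(
    back$key_sample$frames[[5]]$positions,
    tpl$key_sample$frames[[5]]$positions
  )

  pt <- activity_template("Stand", "posture", rand_frame(),
    relevant_joints = c("HIP_L", "HIP_R")
  )
  write_template(pt, path)
  expect_identical(read_template(path)$kind, "posture")
})
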