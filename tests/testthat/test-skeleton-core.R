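test_that("joint enumeration has 20 members with involutive mirror pairs", {
  j <- joint_names()
  expect_length(j, 20L)
  expect_identical(mirror_joint(mirror_joint(j)), j)
  expect_identical(mirror_joint("WRIST_R"), "WRIST_L")
  expect_identical(mirror_joint("SPINE"), "SPINE")
})

test_that("topology is 21 edges whose 19 standard edges span all joints", {
  topo <- skeleton_topology()
  expect_identical(nrow(topo), 21L)
  girdles <- c("SHOULDER_L-SHOULDER_R", "HIP_L-HIP_R")
  tree <- topo[!topo$bone %in% girdles, ]
  expect_identical(nrow(tree), 19L)
  # connectivity: union-find over the 19 tree edges reaches every joint
  parent <- stats::setNames(joint_names(), joint_names())
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(tree))) {
    parent[[find(tree$proximal[i])]] <- find(tree$distal[i])
  }
  expect_length(unique(vapply(joint_names(), find, character(1))), 1L)
})

test_that("bones_induced returns edges with both endpoints in the set", {
  expect_identical(bones_induced(character(0)), character(0))
  expect_identical(
    bones_induced(c("SHOULDER_R", "ELBOW_R", "WRIST_R")),
    c("SHOULDER_R-ELBOW_R", "ELBOW_R-WRIST_R")
  )
  expect_length(bones_induced(joint_names()), 21L)
  expect_error(bones_induced("ELBOW_X"), "unknown joint")
})

test_that("bones_induced is monotone under joint-set inclusion", {
  set.seed(41)
  for (i in 1:50) {
    j1 <- sample(joint_names(), sample(3:12, 1))
    j2 <- unique(c(j1, sample(joint_names(), sample(1:8, 1))))
    expect_true(all(bones_induced(j1) %in% bones_induced(j2)))
  }
})

test_that("bone_id canonicalizes endpoint order and rejects non-edges", {
  expect_identical(bone_id("ELBOW_R", "SHOULDER_R"), "SHOULDER_R-ELBOW_R")
  expect_identical(bone_id("SHOULDER_R", "ELBOW_R"), "SHOULDER_R-ELBOW_R")
  expect_error(bone_id("HEAD", "FOOT_L"), "not a bone")
})

test_that("skeleton_frame validates joints, coordinates and timestamp", {
  pos <- standing_positions()
  expect_s3_class(skeleton_frame(pos), "skeleton_frame")
  bad <- pos
  bad[1, 1] <- Inf
  expect_error(skeleton_frame(bad), "finite")
  expect_error(skeleton_frame(pos[-1, ]), "missing joint")
  expect_error(skeleton_frame(pos, timestamp = -1), "non-negative")
  # declared-subset validation admits partial frames
  sub <- pos[c("HIP_CENTER", "KNEE_L", "HIP_L"), ]
  expect_s3_class(
    skeleton_frame(sub, joints = rownames(sub)), "skeleton_frame"
  )
})

test_that("skeleton_sequence enforces increasing timestamps and fps", {
  f1 <- skeleton_frame(standing_positions(), 0)
  f2 <- skeleton_frame(standing_positions(), 0.5)
  expect_error(skeleton_sequence(list(f2, f1), fps = 2), "increasing")
  expect_error(skeleton_sequence(list(f1, f2), fps = 0), "positive")
  expect_warning(skeleton_sequence(list(f1, f2), fps = 30), "inconsistent")
  s <- skeleton_sequence(list(f1, f2), fps = 2, label = "Stand")
  expect_identical(sequence_duration(s), 0.5)
})

test_that("mirror_frame is an involution that preserves distances", {
  set.seed(42)
  for (i in 1:20) {
    f <- rand_frame()
    m <- mirror_frame(f)
    mm <- mirror_frame(m)
    expect_equal(mm$positions[joint_names(), ], f$positions[joint_names(), ],
      tolerance = 1e-12
    )
    # distances are preserved up to the left/right relabeling
    d0 <- as.matrix(stats::dist(f$positions))
    d1 <- as.matrix(stats::dist(m$positions))
    jm <- mirror_joint(joint_names())
    expect_equal(
      unname(d1[jm, jm]), unname(d0[joint_names(), joint_names()]),
      tolerance = 1e-9
    )
  }
})

test_that("mirror_frame reflects about the hip-center midline", {
  pos <- standing_positions()
  mid <- pos["HIP_CENTER", "x"]
  pos["WRIST_R", ] <- c(mid + 0.3, 0.9, 2.4)
  f <- mirror_frame(skeleton_frame(pos))
  expect_equal(unname(f$positions["WRIST_L", "x"]), mid - 0.3)
  # a perfectly symmetric frame is a fixed point
  sym <- skeleton_frame(standing_positions())
  ms <- mirror_frame(sym)
  expect_equal(ms$positions[joint_names(), ], sym$positions[joint_names(), ],
    tolerance = 1e-12
  )
})

test_that("sequence round trips are bit-exact in both dialects", {
  body <- generate_participant(seed = 5)
  seq <- generate_sequence(
    activity_scripts()[["Walk [D]"]], body, 15,
    noise_params(seed = 9)
  )
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_sequence(seq, path, fmt)
    back <- read_sequence(path, fmt)
    expect_identical(back$fps, seq$fps)
    expect_identical(back$label, seq$label)
    for (i in seq_along(seq$frames)) {
      expect_identical(back$frames[[i]]$timestamp, seq$frames[[i]]$timestamp)
      expect_identical(
        back$frames[[i]]$positions, seq$frames[[i]]$positions
      )
    }
  }
  # csv and json writes of the same sequence re-read equal
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_sequence(seq, p1)
  write_sequence(seq, p2)
  a <- read_sequence(p1)
  b <- read_sequence(p2)
  expect_identical(
    lapply(a$frames, `[[`, "positions"),
    lapply(b$frames, `[[`, "positions")
  )
})

test_that("empty sequences round trip as header-only files", {
  s <- skeleton_sequence(list(), fps = 15, label = "empty")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequence(s, path)
  lines <- readLines(path)
  expect_true(all(grepl("^#", lines)))
  back <- read_sequence(path)
  expect_length(back$frames, 0L)
  expect_identical(back$fps, 15)
})

test_that("a handcrafted two-frame CSV parses with stated coordinates", {
  path <- withr::local_tempfile(fileext = ".csv")
  joints <- c("HIP_CENTER", "KNEE_L")
  writeLines(c(
    "#fps=2",
    "#coords=meters",
    "0,0,HIP_CENTER,0.1,0.9,2.5",
    "0,0,KNEE_L,-0.1,0.45,2.5",
    "1,0.5,HIP_CENTER,0.1,0.91,2.5",
    "1,0.5,KNEE_L,-0.1,0.46,2.5"
  ), path)
  s <- read_sequence(path, joints = joints)
  expect_length(s$frames, 2L)
  expect_identical(s$fps, 2)
  expect_equal(
    unname(s$frames[[1]]$positions["HIP_CENTER", ]), c(0.1, 0.9, 2.5)
  )
  expect_equal(unname(s$frames[[2]]$positions["KNEE_L", ]), c(-0.1, 0.46, 2.5))
})

test_that("CSV parse errors are distinct and name the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "#fps=2", "#coords=meters",
    "0,0,ELBOW_X,0,0,0"
  ), path)
  expect_error(read_sequence(path), "unknown joint name \"ELBOW_X\" at line 3")

  writeLines(c("#fps=2", "0,0,HIP_CENTER,1,2"), path)
  expect_error(
    read_sequence(path, joints = "HIP_CENTER"), "malformed row at line 2"
  )

  writeLines(c(
    "#fps=2",
    "0,0.5,HIP_CENTER,0,0,0",
    "1,0.5,HIP_CENTER,0,0,0"
  ), path)
  expect_error(
    read_sequence(path, joints = "HIP_CENTER"), "non-increasing"
  )

  writeLines(c("0,0,HIP_CENTER,0,0,0"), path)
  expect_error(read_sequence(path, joints = "HIP_CENTER"), "missing #fps")
})
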