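test_that("canonical femoral landmarks give axis-aligned frame", {
  fr <- build_femoral_frame(canonical_femur_landmarks("right"))
  expect_equal(fr$si, c(0, 0, 1))
  expect_equal(fr$ml, c(1, 0, 0))
  expect_equal(fr$ap, c(0, 1, 0))
  expect_equal(fr$origin, c(0, 0, 0))
})

test_that("frame construction is equivariant under rigid transforms", {
  for (seed in 1:20) {
    tr <- random_rigid(seed)
    for (lms in list(random_femur_landmarks(seed + 40),
                     random_tibia_landmarks(seed + 80))) {
      fr <- build_frame(lms)
      fr2 <- build_frame(transform_landmarks(tr, lms))
      for (ax in c("ap", "ml", "si"))
        expect_equal(fr2[[ax]], as.numeric(tr$rotation %*% fr[[ax]]),
                     tolerance = 1e-9)
      expect_equal(fr2$origin, as.numeric(apply_transform(tr, fr$origin)),
                   tolerance = 1e-9)
    }
  }
})

test_that("frames are orthonormal with correct anatomical signs on random landmarks", {
  for (seed in 1:100) {
    side <- if (seed %% 2 == 0) "right" else "left"
    fem <- build_femoral_frame(random_femur_landmarks(seed, side))
    tib <- build_tibial_frame(random_tibia_landmarks(seed, side))
    expect_frame_valid(fem)
    expect_frame_valid(tib)
    # SI primary axis is exactly the landmark-defined direction
    lms <- random_femur_landmarks(seed, side)
    mech <- lms$points["hip_centre", ] - lms$points["knee_centre", ]
    expect_equal(fem$si, as.numeric(mech / sqrt(sum(mech^2))), tolerance = 1e-12)
    # ml points laterally: toward the lateral epicondyle
    tea <- lms$points["lateral_epicondyle", ] - lms$points["medial_sulcus", ]
    expect_gt(sum(fem$ml * tea), 0)
    # tibial ap points anteriorly: toward the tubercle
    tlm <- random_tibia_landmarks(seed, side)
    ap_raw <- tlm$points["tubercle_medial_third", ] - tlm$points["pcl_insertion", ]
    expect_gt(sum(tib$ap * ap_raw), 0)
  }
})

test_that("tibial frame agrees with an independent Gram-Schmidt oracle", {
  lms <- canonical_tibia_landmarks("right")
  fr <- build_tibial_frame(lms)
  # oracle: orthonormalise [si_raw, ap_raw] with pracma, tertiary by cross
  si_raw <- midpoint(lms$points["tubercle_medial_third", ],
                     lms$points["pcl_insertion", ]) -
    midpoint(lms$points["medial_malleolus", ], lms$points["lateral_malleolus", ])
  ap_raw <- lms$points["tubercle_medial_third", ] - lms$points["pcl_insertion", ]
  gs <- pracma::gramSchmidt(cbind(si_raw, ap_raw, c(1, 0, 0)))$Q
  expect_equal(fr$si, as.numeric(gs[, 1]), tolerance = 1e-12)
  expect_equal(fr$ap, as.numeric(gs[, 2]), tolerance = 1e-12)
  expect_lt(abs(sum(fr$ap * fr$si)), 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))
})

test_that("tibial AP axis is orthogonal to SI by construction", {
  for (seed in 1:25) {
    fr <- build_tibial_frame(random_tibia_landmarks(seed))
    expect_lt(abs(sum(fr$ap * fr$si)), 1e-12)
  }
})

test_that("sagittal mirroring with side flip reflects every frame axis", {
  # reflect landmarks across x = 0 and flip the side tag: each axis must map
  # through the same reflection (the side-aware cross products absorb the
  # handedness change, so no axis picks up a spurious sign). For canonical
  # landmarks this is the clinical statement "ml reflects, si and ap stay".
  reflect <- function(v) c(-v[1], v[2], v[3])
  for (seed in 1:10) {
    for (cfg in list(list(random_femur_landmarks, build_femoral_frame, "femur"),
                     list(random_tibia_landmarks, build_tibial_frame, "tibia"))) {
      lms <- cfg[[1]](seed, "right")
      fr <- cfg[[2]](lms)
      pts_m <- lms$points
      pts_m[, 1] <- -pts_m[, 1]
      fr_m <- cfg[[2]](landmark_set(pts_m, cfg[[3]], "left"))
      expect_equal(fr_m$ml, reflect(fr$ml), tolerance = 1e-9)
      expect_equal(fr_m$si, reflect(fr$si), tolerance = 1e-9)
      expect_equal(fr_m$ap, reflect(fr$ap), tolerance = 1e-9)
    }
  }
  # canonical case: si and ap are unchanged, ml flips
  fr_r <- build_femoral_frame(canonical_femur_landmarks("right"))
  pts <- canonical_femur_landmarks("right")$points
  pts[, 1] <- -pts[, 1]
  fr_l <- build_femoral_frame(landmark_set(pts, "femur", "left"))
  expect_equal(fr_l$si, fr_r$si)
  expect_equal(fr_l$ap, fr_r$ap)
  expect_equal(fr_l$ml, -fr_r$ml)
})

test_that("degenerate landmark configurations raise errors", {
  bad <- canonical_femur_landmarks()$points
  bad["medial_sulcus", ] <- c(0, 0, -50)       # TEA parallel to mechanical axis
  bad["lateral_epicondyle", ] <- c(0, 0, 50)
  expect_error(build_femoral_frame(landmark_set(bad, "femur", "right")),
               "parallel")
  badt <- canonical_tibia_landmarks()$points
  badt["pcl_insertion", ] <- badt["tubercle_medial_third", ]
  expect_error(build_tibial_frame(landmark_set(badt, "tibia", "right")),
               "coincide")
  expect_error(landmark_set(canonical_femur_landmarks()$points[-1, ],
                            "femur", "right"), "missing")
})
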