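test_that("implant pose recovery from fiducials", {
  implant <- default_femoral_implant()
  ident <- implant_pose_from_fiducials(implant, implant$fiducials)
  expect_lt(ident$fit_rms, 1e-12)
  expect_lt(max(abs(ident$transform$rotation - diag(3))), 1e-12)

  for (seed in 1:5) {
    truth <- random_rigid(seed)
    obs <- apply_transform(truth, implant$fiducials)
    pose <- implant_pose_from_fiducials(implant, obs)
    expect_lt(max(abs(pose$transform$rotation - truth$rotation)), 1e-9)
    expect_lt(max(abs(pose$transform$translation - truth$translation)), 1e-9)
  }

  expect_error(implant_pose_from_fiducials(implant,
                                           implant$fiducials[1:2, ]), ">= 3")
  unnamed <- implant$fiducials
  rownames(unnamed) <- paste0("x", seq_len(nrow(unnamed)))
  expect_error(implant_pose_from_fiducials(implant, unnamed), ">= 3")
})

test_that("implant pose tolerates fiducial picking noise", {
  implant <- default_tibial_implant()
  truth <- random_rigid(99, max_angle = 20, max_translation = 30)
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    obs <- apply_transform(truth, implant$fiducials) +
      matrix(rnorm(length(implant$fiducials), 0, 0.2), ncol = 3)
    pose <- implant_pose_from_fiducials(implant, obs)
    worst <- max(worst, rotation_angle_between(pose$transform$rotation,
                                               truth$rotation))
  }
  expect_lte(worst, 0.5)
})

test_that("single-axis rotations decompose to the matching angle", {
  frame <- build_femoral_frame(canonical_femur_landmarks("right"))
  implant <- default_femoral_implant()
  aligned <- identity_transform()
  expect_equal(unname(alignment_angles(aligned, frame, implant)), c(0, 0, 0))

  for (mag in c(1, 5, 10, 20)) {
    fe <- alignment_angles(rotation_about(frame$ml, mag), frame, implant)
    expect_equal(unname(fe), c(mag, 0, 0), tolerance = 1e-9)
    # varus for a right knee: rotation about +ap gives positive VV
    vv <- alignment_angles(rotation_about(frame$ap, mag), frame, implant)
    expect_equal(unname(vv), c(0, mag, 0), tolerance = 1e-9)
    ie <- alignment_angles(rotation_about(frame$si, mag), frame, implant)
    expect_equal(unname(ie[3]), mag, tolerance = 1e-9)
  }
})

test_that("combined rotations match a brute-force decomposition within cross-talk bounds", {
  frame <- build_femoral_frame(canonical_femur_landmarks("right"))
  implant <- default_femoral_implant()
  pose <- compose_transforms(rotation_about(frame$ml, 3),
                             rotation_about(frame$si, 2))
  ang <- alignment_angles(pose, frame, implant)
  # oracle: search the (fe, ie) pair whose composed rotation reproduces the pose
  obj <- function(p) {
    R <- compose_transforms(rotation_about(frame$ml, p[1]),
                            rotation_about(frame$si, p[2]))$rotation
    sum((R - pose$rotation)^2)
  }
  best <- optim(c(0, 0), obj, method = "BFGS")$par
  expect_equal(unname(ang["FE"]), best[1], tolerance = 0.05)
  expect_equal(unname(ang["IE"]), best[2], tolerance = 0.05)
  expect_lt(abs(ang["VV"]), 0.05)
})

test_that("placement translations read off the anatomic components", {
  frame <- build_femoral_frame(canonical_femur_landmarks("right"))
  implant <- default_femoral_implant()
  expect_equal(unname(placement_translations(identity_transform(), frame, implant)),
               c(0, 0, 0))
  tr <- rigid_transform(diag(3), frame$ap * 4)
  expect_equal(unname(placement_translations(tr, frame, implant)),
               c(4, 0, 0), tolerance = 1e-12)
})

test_that("resection thickness matches analytic sphere geometry", {
  frame <- build_femoral_frame(canonical_femur_landmarks("right"))
  # synthetic condyle: sphere radius 20 centred at (-22, -5, 10), entirely
  # within the medial half-space
  sph <- kneepose:::uv_sphere(c(-22, -5, 10), 20, 40, 80)
  lowest <- min(sph$vertices[, 3])
  cut <- plane(c(-22, -5, lowest + 9), c(0, 0, -1))
  t_mm <- resection_thickness(sph, frame, cut, "distal_medial")
  expect_equal(t_mm, 9.0, tolerance = 1e-6)
  through <- plane(c(-22, -5, lowest), c(0, 0, -1))
  expect_equal(resection_thickness(sph, frame, through, "distal_medial"), 0,
               tolerance = 1e-9)
  expect_error(resection_thickness(sph, frame, cut, "distal_lateral"),
               "no vertices")
})

test_that("resection thickness is stable under tessellation refinement", {
  frame <- build_femoral_frame(canonical_femur_landmarks("right"))
  cut <- plane(c(-22, -5, -1), c(0, 0, -1))
  vals <- vapply(c(20, 40, 80), function(n) {
    sph <- kneepose:::uv_sphere(c(-22, -5, 10), 20, n, 2 * n)
    resection_thickness(sph, frame, cut, "distal_medial")
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 0.05)
})

test_that("zero-noise identity scan reproduces ground truth to 1e-6", {
  sim <- simulate_tka_case(small_spec(1, noise_sd = 0, fiducial_noise_sd = 0,
                                      ct_offset = identity_transform()))
  rep <- analyze_case(sim$case, sim$implants)
  expect_equal(rep$femoral$angles, sim$truth$angles$femoral, tolerance = 1e-6)
  expect_equal(rep$tibial$angles, sim$truth$angles$tibial, tolerance = 1e-6)
  res <- c(rep$femoral$resections, rep$tibial$resections)
  expect_equal(res, sim$truth$resections[names(res)], tolerance = 1e-6)
  expect_equal(rep$femoral$translations, sim$truth$translations$femoral,
               tolerance = 1e-6)
})

test_that("analysis is deterministic and scene-equivariant", {
  sim <- simulate_tka_case(small_spec(3))
  rep1 <- analyze_case(sim$case, sim$implants)
  rep2 <- analyze_case(sim$case, sim$implants)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  # rigidly move the whole post-operative scene: report must not change
  tr <- random_rigid(77, max_angle = 30, max_translation = 40)
  case2 <- sim$case
  case2$postop_femur <- transform_mesh(tr, sim$case$postop_femur)
  case2$postop_tibia <- transform_mesh(tr, sim$case$postop_tibia)
  case2$femoral_fiducials <- apply_transform(tr, sim$case$femoral_fiducials)
  case2$tibial_fiducials <- apply_transform(tr, sim$case$tibial_fiducials)
  rep3 <- analyze_case(case2, sim$implants)
  expect_equal(rep3$femoral$angles, rep1$femoral$angles, tolerance = 1e-6)
  expect_equal(rep3$tibial$angles, rep1$tibial$angles, tolerance = 1e-6)
  expect_equal(rep3$femoral$resections, rep1$femoral$resections, tolerance = 1e-6)
  expect_equal(rep3$tibial$resections, rep1$tibial$resections, tolerance = 1e-6)
  expect_equal(rep3$femoral$translations, rep1$femoral$translations,
               tolerance = 1e-6)
})

test_that("stage failures propagate with the stage name", {
  sim <- simulate_tka_case(small_spec(2))
  case <- sim$case
  rownames(case$femoral_fiducials) <-
    paste0("bogus", seq_len(nrow(case$femoral_fiducials)))
  expect_error(analyze_case(case, sim$implants), "implant_pose_femoral")
})
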