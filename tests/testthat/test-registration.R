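test_that("kabsch solves trivial and constructed alignments exactly", {
  src <- random_points(1, 10)
  ident <- kabsch(src, src)
  expect_lt(ident$rms_residual, 1e-12)
  expect_lt(max(abs(ident$transform$rotation - diag(3))), 1e-12)

  shifted <- kabsch(src, sweep(src, 2, c(1, 2, 3), "+"))
  expect_equal(shifted$transform$translation, c(1, 2, 3), tolerance = 1e-12)
  expect_lt(shifted$rms_residual, 1e-12)

  truth <- rotation_about(c(0, 0, 1), 30, c(5, 0, 0))
  fit <- kabsch(src, apply_transform(truth, src))
  expect_lt(max(abs(fit$transform$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - truth$translation)), 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
})

test_that("kabsch rejects degenerate configurations", {
  expect_error(kabsch(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(0, 0, 0), c(1, 0, 0))),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(random_points(1, 4), random_points(2, 5)), "same number")
})

test_that("kabsch result is a proper rotation even for reflective data", {
  src <- random_points(3, 6)
  dst <- src
  dst[, 1] <- -dst[, 1]            # mirrored target tempts a reflection
  fit <- kabsch(src, dst)
  expect_gt(det(fit$transform$rotation), 0)
})

test_that("kabsch beats 10,000 random rigid transforms on small instances", {
  sq_resid <- function(tr, src, dst) sum((apply_transform(tr, src) - dst)^2)
  for (inst in 1:3) {
    n <- c(4, 5, 6)[inst]
    src <- random_points(inst * 11, n, scale = 20)
    dst <- apply_transform(random_rigid(inst * 13), src) +
      matrix(rnorm(n * 3, 0, 1), n, 3)
    best <- kabsch(src, dst)
    best_val <- sq_resid(best$transform, src, dst)
    set.seed(inst)
    vals <- replicate(10000, {
      axis <- rnorm(3)
      cand <- rotation_about(axis, runif(1, -180, 180), runif(3, -30, 30))
      sq_resid(cand, src, dst)
    })
    expect_true(all(vals >= best_val - 1e-9))
  }
})

test_that("kabsch residual is equivariant under joint rigid motion", {
  src <- random_points(21, 8)
  dst <- apply_transform(random_rigid(22), src) + matrix(rnorm(24, 0, 0.5), 8, 3)
  base <- kabsch(src, dst)$rms_residual
  for (seed in 1:10) {
    tr <- random_rigid(seed + 300)
    moved <- kabsch(apply_transform(tr, src), apply_transform(tr, dst))$rms_residual
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("icp converges immediately on exact data at truth", {
  mesh <- generate_phantom(small_spec(4))$femur
  # a subsampled scan of the model surface, already aligned: zero residual
  sub <- mesh$vertices[seq(1, nrow(mesh$vertices), by = 3), ]
  fit <- icp(sub, mesh$vertices, identity_transform())
  expect_lt(fit$rms_residual, 1e-9)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 2L)
})

test_that("icp recovers ground truth from offsets up to 10 degrees / 5 mm", {
  sim <- simulate_tka_case(phantom_spec(seed = 2, noise_sd = 0,
                                        fiducial_noise_sd = 0))
  truth <- sim$truth$ct_offset
  set.seed(42)
  for (k in 1:4) {
    axis <- rnorm(3)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    mag <- c(5, 10)[1 + k %% 2]
    init <- compose_transforms(truth, rotation_about(axis, mag, dir * mag / 2))
    fit <- icp(sim$case$preop_femur, sim$case$postop_femur, init)
    expect_lt(rotation_angle_between(fit$transform$rotation, truth$rotation), 0.01)
    expect_lt(max(abs(fit$transform$translation - truth$translation)), 0.01)
  }
})

test_that("icp accepted rms history is monotone non-increasing", {
  sim <- simulate_tka_case(phantom_spec(seed = 5))
  init <- implant_seeded_init(sim$case$femur_landmarks, sim$implants$femoral,
                              implant_pose_from_fiducials(sim$implants$femoral,
                                                          sim$case$femoral_fiducials))
  fit <- icp(sim$case$preop_femur, sim$case$postop_femur, init)
  expect_true(all(diff(fit$rms_history) <= 0))
  expect_lte(fit$rms_residual, fit$rms_history[1])
})

test_that("icp rejects an empty destination and bad parameters", {
  src <- random_points(1, 50, scale = 5)
  expect_error(icp(src, matrix(numeric(), 0, 3)), "empty")
  expect_error(icp_params(trim_fraction = 0.6), "trim_fraction")
  expect_error(icp_params(tolerance = 0), "tolerance")
  expect_error(icp_params(max_iterations = 0), "max_iterations")
})

test_that("landmark_qc flags only displacements beyond the threshold", {
  a <- canonical_femur_landmarks()
  expect_identical(landmark_qc(a, a), character(0))

  shifted <- a$points
  shifted["hip_centre", ] <- shifted["hip_centre", ] + c(5, 0, 0)
  expect_identical(landmark_qc(a, landmark_set(shifted, "femur", "right"), 4.0),
                   "hip_centre")

  near <- a$points
  near["knee_centre", ] <- near["knee_centre", ] + c(0, 3.9, 0)
  expect_identical(landmark_qc(a, landmark_set(near, "femur", "right"), 4.0),
                   character(0))

  b <- a$points[c("hip_centre", "knee_centre", "medial_sulcus"), ]
  expect_error(landmark_qc(a$points, b), "lateral_epicondyle")
})
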