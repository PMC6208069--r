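# Shared test helpers: seeded random rigid transforms, canonical landmark
# sets, and rotation-distance utilities.

rotation_angle_between <- function(R1, R2) {
  M <- R1 %*% t(R2)
  acos(min(1, max(-1, (sum(diag(M)) - 1) / 2))) * 180 / pi
}

random_rigid <- function(seed, max_angle = 180, max_translation = 50) {
  set.seed(seed)
  axis <- rnorm(3)
  angle <- runif(1, -max_angle, max_angle)
  transl <- runif(3, -max_translation, max_translation)
  rotation_about(axis, angle, transl)
}

random_points <- function(seed, n, scale = 50) {
  set.seed(seed)
  matrix(runif(n * 3, -scale, scale), n, 3)
}

canonical_femur_landmarks <- function(side = "right") {
  landmark_set(rbind(knee_centre = c(0, 0, 0),
                     hip_centre = c(0, 0, 400),
                     medial_sulcus = c(-40, 0, 0),
                     lateral_epicondyle = c(40, 0, 0)),
               bone = "femur", side = side)
}

canonical_tibia_landmarks <- function(side = "right") {
  landmark_set(rbind(plateau_centre = c(0, 0, 0),
                     medial_malleolus = c(-25, 0, -350),
                     lateral_malleolus = c(25, 0, -350),
                     tubercle_medial_third = c(0, 30, 2),
                     pcl_insertion = c(0, -30, -2)),
               bone = "tibia", side = side)
}

random_femur_landmarks <- function(seed, side = "right") {
  set.seed(seed)
  jitter <- function(p, s = 8) p + rnorm(3, 0, s)
  landmark_set(rbind(knee_centre = jitter(c(0, 0, 0)),
                     hip_centre = jitter(c(0, 0, 400)),
                     medial_sulcus = jitter(c(-40, -5, 5)),
                     lateral_epicondyle = jitter(c(40, -5, 5))),
               bone = "femur", side = side)
}

random_tibia_landmarks <- function(seed, side = "right") {
  set.seed(seed)
  jitter <- function(p, s = 6) p + rnorm(3, 0, s)
  landmark_set(rbind(plateau_centre = jitter(c(0, 0, 0)),
                     medial_malleolus = jitter(c(-25, 0, -350)),
                     lateral_malleolus = jitter(c(25, 0, -350)),
                     tubercle_medial_third = jitter(c(-2, 25, 0)),
                     pcl_insertion = jitter(c(0, -18, -2))),
               bone = "tibia", side = side)
}

expect_frame_valid <- function(frame) {
  A <- cbind(frame$ap, frame$ml, frame$si)
  expect_lt(max(abs(crossprod(A) - diag(3))), 1e-9)
}

# fast phantom for tests that only need pipeline plumbing, not accuracy
small_spec <- function(seed = 1, ...) {
  phantom_spec(seed = seed, resolution = 0.8, ...)
}
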