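# Parametric synthetic knee phantoms. Bones are built from analytic
# primitives (shaft cylinders, condylar spheres, a plateau ellipsoid) so
# that landmarks, implant poses and resection depths are all known in closed
# form and every downstream measurement can be checked against ground truth.

# golden-angle stagger: offsets successive rings so the tessellation has no
# exact rotational or translational self-alias (segmented bone never does)
GOLDEN <- pi * (3 - sqrt(5))

uv_sphere <- function(center, radius, n_lat, n_lon, scale = c(1, 1, 1)) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2L)[-c(1L, n_lat + 2L)]
  lon0 <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  g <- expand.grid(lon = lon0, lat = lat)
  g$lon <- g$lon + GOLDEN * (match(g$lat, lat) - 1L)
  ring <- cbind(cos(g$lat) * cos(g$lon), cos(g$lat) * sin(g$lon), sin(g$lat))
  verts <- rbind(ring, c(0, 0, -1), c(0, 0, 1))
  verts <- sweep(verts * radius, 2L, scale, `*`)
  verts <- sweep(verts, 2L, center, `+`)
  south <- nrow(verts) - 1L; north <- nrow(verts)
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  for (i in seq_len(n_lat - 1L)) {
    j <- seq_len(n_lon)
    faces[[length(faces) + 1L]] <- cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j))
    faces[[length(faces) + 1L]] <- cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))
  }
  j <- seq_len(n_lon)
  faces[[length(faces) + 1L]] <- cbind(south, idx(1L, j + 1L), idx(1L, j))
  faces[[length(faces) + 1L]] <- cbind(north, idx(n_lat, j), idx(n_lat, j + 1L))
  triangle_mesh(verts, do.call(rbind, faces))
}

# bone shaft: elliptical cross-section (long bones are not circular) with a
# linear taper, a metaphyseal flare toward the joint end (z1), and a gentle
# spiral ridge (linea-aspera analogue). The relief matters: featureless
# quadric surfaces leave axial rotation and longitudinal slide nearly
# unconstrained for surface registration, which real bone never does.
shaft_mesh <- function(rx, ry, z0, z1, n_seg, ring_spacing = 10,
                       taper = 0.15, flare = 0.5, flare_scale = 40,
                       ridge_amp = 0.18, ridge_twist = 0.012) {
  n_rings <- max(2L, ceiling(abs(z1 - z0) / ring_spacing) + 1L)
  zs <- seq(z0, z1, length.out = n_rings)
  ang0 <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  ang <- rep(ang0, n_rings) + GOLDEN * rep(seq_len(n_rings) - 1L, each = n_seg)
  z <- rep(zs, each = n_seg)
  scale <- 1 + taper * (z - z0) / (z1 - z0) +
    flare * exp(-abs(z - z1) / flare_scale)
  ridge <- 1 + ridge_amp * cos(ang - ridge_twist * z)
  verts <- cbind(rx * scale * ridge * cos(ang), ry * scale * ridge * sin(ang),
                 z)
  idx <- function(i, j) (i - 1L) * n_seg + ((j - 1L) %% n_seg) + 1L
  faces <- list()
  for (i in seq_len(n_rings - 1L)) {
    j <- seq_len(n_seg)
    faces[[length(faces) + 1L]] <- cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j))
    faces[[length(faces) + 1L]] <- cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))
  }
  triangle_mesh(verts, do.call(rbind, faces))
}

merge_meshes <- function(...) {
  parts <- list(...)
  verts <- do.call(rbind, lapply(parts, function(m) m$vertices))
  offs <- cumsum(c(0L, vapply(parts, function(m) nrow(m$vertices), integer(1))))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, parts,
                              offs[seq_along(parts)]))
  triangle_mesh(verts, faces)
}

#' Synthetic knee phantom specification
#'
#' Defaults describe an adult-scale right knee: a 400 mm femur (14 mm shaft)
#' with 25 mm condylar spheres spaced 44 mm apart, and a 350 mm tibia with a
#' 60 x 44 mm plateau ellipsoid. The scan-emulation defaults mirror a
#' modern ~1 mm-slice CT workflow: 0.3 mm isotropic vertex noise (the
#' segmentation uncertainty scale), 0.2 mm fiducial-picking noise, a CT
#' table offset of 10 degrees and 20 mm, and a 3 mm peri-implant flare band
#' in which post-operative bone is discarded.
#'
#' @param seed integer; drives every random draw (noise and offset
#'   direction).
#' @param side `"right"` or `"left"`.
#' @param noise_sd isotropic Gaussian vertex noise SD applied to the
#'   post-operative surfaces, mm.
#' @param fiducial_noise_sd Gaussian noise SD on observed implant fiducials,
#'   mm.
#' @param ct_offset_angle_deg,ct_offset_mm magnitude of the rigid offset
#'   between the pre-op and post-op CT frames (direction drawn from `seed`).
#' @param ct_offset optionally a fixed `rigid_transform` overriding the two
#'   magnitudes.
#' @param flare_band_mm width of the peri-implant band removed from the
#'   post-op surfaces, mm.
#' @param femoral_pose,tibial_pose true implant poses in the pre-operative
#'   bone frame (`rigid_transform`s); defaults place each component near
#'   neutral with a few degrees of deliberate malalignment.
#' @param femur_length,femur_shaft_radius,condyle_radius_medial,
#'   condyle_radius_lateral,condyle_spacing,condyle_ap_offset,
#'   condyle_si_offset femoral dimensions, mm; the medial condyle is larger
#'   than the lateral one, as in the native knee. Shaft cross-sections are
#'   elliptical (ML radius as given, AP radius 80% of it) with a 15% linear
#'   taper, so the bone has no rotational or translational symmetry.
#' @param tibia_length,tibia_shaft_radius tibial shaft dimensions, mm.
#' @param plateau_semi_ml,plateau_semi_ap,plateau_semi_si plateau ellipsoid
#'   semi-axes, mm.
#' @param femoral_distal_cut,femoral_posterior_cut,tibial_plateau_cut
#'   implant-local resection plane offsets, mm (see
#'   [default_femoral_implant()]).
#' @param resolution mesh density multiplier (1 = default tessellation).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, side = "right", noise_sd = 0.3,
                         fiducial_noise_sd = 0.2,
                         ct_offset_angle_deg = 10, ct_offset_mm = 20,
                         ct_offset = NULL, flare_band_mm = 3,
                         femoral_pose = NULL, tibial_pose = NULL,
                         femur_length = 400, femur_shaft_radius = 14,
                         condyle_radius_medial = 26, condyle_radius_lateral = 24,
                         condyle_spacing = 44,
                         condyle_ap_offset = -5, condyle_si_offset = 10,
                         tibia_length = 350, tibia_shaft_radius = 12,
                         plateau_semi_ml = 30, plateau_semi_ap = 22,
                         plateau_semi_si = 10,
                         femoral_distal_cut = 6, femoral_posterior_cut = 20,
                         tibial_plateau_cut = 10, resolution = 1) {
  dims <- c(femur_length, femur_shaft_radius, condyle_radius_medial,
            condyle_radius_lateral, condyle_spacing,
            tibia_length, tibia_shaft_radius, plateau_semi_ml, plateau_semi_ap,
            plateau_semi_si, flare_band_mm, resolution)
  if (any(dims <= 0)) stop("all phantom dimensions must be positive")
  if (noise_sd < 0 || fiducial_noise_sd < 0) stop("noise SDs must be >= 0")
  side <- match.arg(side, c("right", "left"))
  if (is.null(femoral_pose))
    femoral_pose <- compose_transforms(
      rotation_about(c(1, 0, 0), 2, c(0.5, -1.0, -0.5)),
      compose_transforms(rotation_about(c(0, 1, 0), -1),
                         rotation_about(c(0, 0, 1), 1)))
  if (is.null(tibial_pose))
    tibial_pose <- compose_transforms(
      rotation_about(c(1, 0, 0), 3, c(-0.5, 0.5, -1.0)),
      rotation_about(c(0, 0, 1), -2))
  structure(list(seed = as.integer(seed), side = side, noise_sd = noise_sd,
                 fiducial_noise_sd = fiducial_noise_sd,
                 ct_offset_angle_deg = ct_offset_angle_deg,
                 ct_offset_mm = ct_offset_mm, ct_offset = ct_offset,
                 flare_band_mm = flare_band_mm,
                 femoral_pose = femoral_pose, tibial_pose = tibial_pose,
                 femur_length = femur_length,
                 femur_shaft_radius = femur_shaft_radius,
                 condyle_radius_medial = condyle_radius_medial,
                 condyle_radius_lateral = condyle_radius_lateral,
                 condyle_spacing = condyle_spacing,
                 condyle_ap_offset = condyle_ap_offset,
                 condyle_si_offset = condyle_si_offset,
                 tibia_length = tibia_length,
                 tibia_shaft_radius = tibia_shaft_radius,
                 plateau_semi_ml = plateau_semi_ml,
                 plateau_semi_ap = plateau_semi_ap,
                 plateau_semi_si = plateau_semi_si,
                 femoral_distal_cut = femoral_distal_cut,
                 femoral_posterior_cut = femoral_posterior_cut,
                 tibial_plateau_cut = tibial_plateau_cut,
                 resolution = resolution),
            class = "phantom_spec")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Generate the pre-operative phantom
#'
#' Builds the pre-operative femur and tibia meshes (in the pre-operative
#' frame, anatomic axes: +x lateral for a right knee, +y anterior,
#' +z superior, femoral origin at the knee centre, tibial origin at the
#' plateau centre) and their analytically placed landmark sets. Fully
#' deterministic for a given spec.
#'
#' @param spec a `phantom_spec`.
#' @return an object of class `knee_phantom`: `femur`, `tibia`
#'   (`triangle_mesh`es), `femur_landmarks`, `tibia_landmarks`
#'   (`landmark_set`s), declared vertex `counts`, and the `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  s <- if (spec$side == "right") 1 else -1
  n_seg <- max(8L, round(24 * spec$resolution))
  n_lat <- max(6L, round(13 * spec$resolution))
  ring <- 10 / spec$resolution

  cx <- spec$condyle_spacing / 2
  cc_med <- c(-s * cx, spec$condyle_ap_offset, spec$condyle_si_offset)
  cc_lat <- c(s * cx, spec$condyle_ap_offset, spec$condyle_si_offset)
  femur <- merge_meshes(
    shaft_mesh(spec$femur_shaft_radius, 0.8 * spec$femur_shaft_radius,
               spec$femur_length, spec$condyle_si_offset + 5, n_seg, ring),
    uv_sphere(cc_med, spec$condyle_radius_medial, n_lat, n_seg),
    uv_sphere(cc_lat, spec$condyle_radius_lateral, n_lat, n_seg))
  femur_landmarks <- landmark_set(rbind(
    knee_centre = c(0, 0, 0),
    hip_centre = c(0, 0, spec$femur_length),
    medial_sulcus = cc_med - c(s * spec$condyle_radius_medial, 0, 0),
    lateral_epicondyle = cc_lat + c(s * spec$condyle_radius_lateral, 0, 0)),
    bone = "femur", side = spec$side)

  tibia <- merge_meshes(
    shaft_mesh(spec$tibia_shaft_radius, 0.8 * spec$tibia_shaft_radius,
               -spec$tibia_length, -spec$plateau_semi_si - 5, n_seg, ring),
    # plateau sits slightly posterior of the shaft axis, as in the native tibia
    uv_sphere(c(0, -3, -spec$plateau_semi_si), 1, n_lat, n_seg,
              scale = c(spec$plateau_semi_ml, spec$plateau_semi_ap,
                        spec$plateau_semi_si)))
  tibia_landmarks <- landmark_set(rbind(
    plateau_centre = c(0, 0, 0),
    medial_malleolus = c(-s * 25, 0, -spec$tibia_length),
    lateral_malleolus = c(s * 25, 0, -spec$tibia_length),
    tubercle_medial_third = c(-s * 2, 20, 0),
    pcl_insertion = c(0, -16, 0)),
    bone = "tibia", side = spec$side)

  if (nrow(femur$vertices) < 100L || nrow(tibia$vertices) < 100L)
    stop("mesh resolution too coarse to place landmarks (< 100 vertices)")
  structure(list(femur = femur, tibia = tibia,
                 femur_landmarks = femur_landmarks,
                 tibia_landmarks = tibia_landmarks,
                 counts = c(femur = nrow(femur$vertices),
                            tibia = nrow(tibia$vertices)),
                 spec = spec),
            class = "knee_phantom")
}

# keep vertices on the kept-bone side of every plane and outside the flare
# band; drop unreferenced vertices and dangling faces
crop_mesh <- function(mesh, planes, flare_band) {
  d <- vapply(planes, function(p) signed_plane_distance(p, mesh$vertices),
              numeric(nrow(mesh$vertices)))
  keep <- apply(as.matrix(d), 1L, max) <= -flare_band
  if (!any(keep)) stop("resection planes removed the whole bone")
  remap <- cumsum(keep)
  faces <- mesh$faces[rowSums(matrix(keep[mesh$faces], ncol = 3L)) == 3L, ,
                      drop = FALSE]
  triangle_mesh(mesh$vertices[keep, , drop = FALSE],
                matrix(remap[faces], ncol = 3L))
}

#' Implant the phantom and emulate the post-operative scan
#'
#' Cuts each pre-operative bone at its posed resection planes (removed-bone
#' side deleted), removes a peri-implant flare band, maps everything into
#' the post-operative CT frame by the (seeded) CT offset, adds Gaussian
#' vertex and fiducial noise, and returns both the analysis-ready case and
#' the ground truth.
#'
#' @param phantom a `knee_phantom` from [generate_phantom()].
#' @param implants list with `femoral` and `tibial` `implant_definition`s;
#'   defaults are built from the spec's cut offsets.
#' @return list with `case` (a `tka_case`), `truth` (a `ground_truth`), and
#'   `implants`.
#' @export
implant_and_scan <- function(phantom, implants = NULL) {
  if (!inherits(phantom, "knee_phantom")) stop("phantom must be a knee_phantom")
  spec <- phantom$spec
  if (is.null(implants))
    implants <- list(
      femoral = default_femoral_implant(spec$femoral_distal_cut,
                                        spec$femoral_posterior_cut,
                                        side = spec$side),
      tibial = default_tibial_implant(spec$tibial_plateau_cut,
                                      side = spec$side))

  with_seed(spec$seed, {
    ct_offset <- spec$ct_offset
    if (is.null(ct_offset)) {
      axis <- rnorm(3); tdir <- rnorm(3)
      ct_offset <- rotation_about(axis, spec$ct_offset_angle_deg,
                                  unitv(tdir) * spec$ct_offset_mm)
    }

    planes_f <- lapply(implants$femoral$planes,
                       function(p) transform_plane(spec$femoral_pose, p))
    planes_t <- lapply(implants$tibial$planes,
                       function(p) transform_plane(spec$tibial_pose, p))
    cut_f <- crop_mesh(phantom$femur, planes_f, spec$flare_band_mm)
    cut_t <- crop_mesh(phantom$tibia, planes_t, spec$flare_band_mm)

    post_f <- transform_mesh(ct_offset, cut_f)
    post_t <- transform_mesh(ct_offset, cut_t)
    if (spec$noise_sd > 0) {
      post_f$vertices <- post_f$vertices +
        matrix(rnorm(length(post_f$vertices), 0, spec$noise_sd),
               ncol = 3L)
      post_t$vertices <- post_t$vertices +
        matrix(rnorm(length(post_t$vertices), 0, spec$noise_sd),
               ncol = 3L)
    }

    pose_f_ct <- compose_transforms(ct_offset, spec$femoral_pose)
    pose_t_ct <- compose_transforms(ct_offset, spec$tibial_pose)
    fid_f <- apply_transform(pose_f_ct, implants$femoral$fiducials)
    fid_t <- apply_transform(pose_t_ct, implants$tibial$fiducials)
    if (spec$fiducial_noise_sd > 0) {
      fid_f <- fid_f + matrix(rnorm(length(fid_f), 0, spec$fiducial_noise_sd),
                              ncol = 3L)
      fid_t <- fid_t + matrix(rnorm(length(fid_t), 0, spec$fiducial_noise_sd),
                              ncol = 3L)
    }

    lms_f_ct <- transform_landmarks(ct_offset, phantom$femur_landmarks)
    lms_t_ct <- transform_landmarks(ct_offset, phantom$tibia_landmarks)
    frame_f <- build_femoral_frame(lms_f_ct)
    frame_t <- build_tibial_frame(lms_t_ct)
    mesh_f_ct <- transform_mesh(ct_offset, phantom$femur)
    mesh_t_ct <- transform_mesh(ct_offset, phantom$tibia)

    truth <- structure(list(
      ct_offset = ct_offset,
      landmarks = list(femur = lms_f_ct, tibia = lms_t_ct),
      frames = list(femur = frame_f, tibia = frame_t),
      poses = list(femoral = pose_f_ct, tibial = pose_t_ct),
      angles = list(
        femoral = alignment_angles(pose_f_ct, frame_f, implants$femoral),
        tibial = alignment_angles(pose_t_ct, frame_t, implants$tibial)),
      translations = list(
        femoral = placement_translations(pose_f_ct, frame_f, implants$femoral),
        tibial = placement_translations(pose_t_ct, frame_t, implants$tibial)),
      resections = c(
        resections_for_component(implants$femoral, pose_f_ct, frame_f, mesh_f_ct),
        resections_for_component(implants$tibial, pose_t_ct, frame_t, mesh_t_ct))),
      class = "ground_truth")

    case <- tka_case(phantom$femur, phantom$tibia,
                     phantom$femur_landmarks, phantom$tibia_landmarks,
                     post_f, post_t, fid_f, fid_t)
    list(case = case, truth = truth, implants = implants)
  })
}

#' Generate a complete synthetic case in one call
#'
#' @param spec a `phantom_spec` (or arguments forwarded to [phantom_spec()]).
#' @param ... arguments forwarded to [phantom_spec()] when `spec` is missing.
#' @return as [implant_and_scan()], plus the `phantom`.
#' @export
simulate_tka_case <- function(spec = phantom_spec(...), ...) {
  phantom <- generate_phantom(spec)
  out <- implant_and_scan(phantom)
  out$phantom <- phantom
  out
}
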