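# Component pose estimation and decomposition into clinical alignment
# angles, placement translations, and bony resection thicknesses.

RESECTION_REGIONS <- c("distal_medial", "distal_lateral", "posterior_medial",
                       "posterior_lateral", "plateau_medial", "plateau_lateral")

ANGLE_CONVENTION <- paste(
  "projection angles; flexion, varus, internal rotation positive;",
  "anterior, lateral, superior translations positive; side-aware")

#' Implant pose from observed fiducials
#'
#' Paired-point (Kabsch) registration of the implant-local fiducials onto
#' the fiducial positions observed in the post-operative CT (e.g. picked on
#' the segmented prosthesis surface).
#'
#' @param implant an `implant_definition`.
#' @param observed_fiducials named n x 3 matrix of observed positions in the
#'   CT frame, mm; at least 3 names must match the implant's fiducials.
#' @return an object of class `component_pose`: `transform` (implant-local
#'   to CT) and `fit_rms` (mm).
#' @export
implant_pose_from_fiducials <- function(implant, observed_fiducials) {
  if (!inherits(implant, "implant_definition"))
    stop("implant must be an implant_definition")
  obs <- as_points(observed_fiducials)
  if (is.null(rownames(obs))) stop("observed fiducials must be named")
  common <- intersect(rownames(implant$fiducials), rownames(obs))
  if (length(common) < 3L)
    stop(sprintf("only %d fiducial name(s) match the implant definition; >= 3 required",
                 length(common)))
  fit <- kabsch(implant$fiducials[common, , drop = FALSE],
                obs[common, , drop = FALSE])
  structure(list(transform = fit$transform, fit_rms = fit$rms_residual,
                 n_fiducials = length(common)),
            class = "component_pose")
}

#' @export
print.component_pose <- function(x, ...) {
  cat(sprintf("Component pose from %d fiducials, fit rms %.4f mm\n",
              x$n_fiducials, x$fit_rms))
  print(x$transform)
  invisible(x)
}

project_angle <- function(u, v, what) {
  # signed angle of the 2D vector (u, v) away from the v axis, degrees
  if (sqrt(u^2 + v^2) < 1e-9)
    stop(sprintf("degenerate projection: component axis is orthogonal to the %s plane", what))
  atan2(u, v) * 180 / pi
}

#' Component alignment angles
#'
#' Expresses the posed component axes in the anatomic frame and reports the
#' three clinical projection angles, in degrees:
#' * FE (flexion/extension): component SI axis projected onto the sagittal
#'   (SI-AP) plane, angle from the anatomic SI axis; flexion (anterior tilt)
#'   positive.
#' * VV (varus/valgus): component SI axis projected onto the coronal (SI-ML)
#'   plane; varus positive, side-aware.
#' * IE (internal/external): component ML axis projected onto the axial
#'   (ML-AP) plane, angle from the anatomic ML axis; internal rotation
#'   positive, side-aware.
#'
#' These are projection angles, not a sequential Euler decomposition; for a
#' rotation about a single anatomic axis the matching angle equals the
#' rotation magnitude exactly and the other two are zero.
#'
#' @param pose a `component_pose` (or `rigid_transform`), implant-local to CT.
#' @param frame the bone's `anatomic_frame` in the CT frame.
#' @param implant the `implant_definition` supplying local axes.
#' @return named numeric vector `c(FE, VV, IE)`, degrees, each in
#'   (-180, 180].
#' @export
alignment_angles <- function(pose, frame, implant) {
  tr <- if (inherits(pose, "component_pose")) pose$transform else pose
  if (!inherits(tr, "rigid_transform")) stop("pose must carry a rigid_transform")
  R <- tr$rotation
  s <- side_sign(frame$side)
  A <- cbind(frame$ap, frame$ml, frame$si)       # CT -> anatomic components
  c_si <- as.numeric(crossprod(A, R %*% implant$axes$si))   # (ap, ml, si)
  c_ml <- as.numeric(crossprod(A, R %*% implant$axes$ml))
  # signs: a positive right-hand rotation about the frame's ml / ap / si
  # axis reads as positive FE / VV / IE (VV and IE side-aware)
  fe <- project_angle(-c_si[1L], c_si[3L], "sagittal")
  vv <- s * project_angle(c_si[2L], c_si[3L], "coronal")
  ie <- s * project_angle(c_ml[1L], c_ml[2L], "axial")
  c(FE = fe, VV = vv, IE = ie)
}

#' Component placement translations
#'
#' Vector from the anatomic frame origin to the posed implant-local origin,
#' expressed along the anatomic axes. Anterior, lateral, superior positive.
#'
#' @inheritParams alignment_angles
#' @return named numeric vector `c(AP, ML, SI)`, mm.
#' @export
placement_translations <- function(pose, frame, implant) {
  tr <- if (inherits(pose, "component_pose")) pose$transform else pose
  if (!inherits(tr, "rigid_transform")) stop("pose must carry a rigid_transform")
  origin_ct <- apply_transform(tr, c(0, 0, 0))
  out <- as.numeric(frame_coordinates(frame, origin_ct))
  c(AP = out[1L], ML = out[2L], SI = out[3L])
}

#' Bony resection thickness
#'
#' Thickness of bone removed at a named region, measured perpendicular to
#' the resection plane from the pre-operative bone's extreme point in that
#' region. The mesh is split into medial and lateral halves by the sagittal
#' plane through the frame origin; distal regions use the lowest-SI vertex
#' of the half, posterior regions the lowest-AP vertex, plateau regions the
#' highest-SI vertex. Positive values mean the reference point lies on the
#' removed-bone side of the plane.
#'
#' @param preop_mesh the pre-operative `triangle_mesh` already registered
#'   into the post-op CT frame.
#' @param frame the bone's `anatomic_frame` in the CT frame.
#' @param plane_in_ct the resection `plane` in the CT frame, normal toward
#'   the removed bone.
#' @param region one of `"distal_medial"`, `"distal_lateral"`,
#'   `"posterior_medial"`, `"posterior_lateral"`, `"plateau_medial"`,
#'   `"plateau_lateral"`.
#' @return resection thickness, mm (signed).
#' @export
resection_thickness <- function(preop_mesh, frame, plane_in_ct, region) {
  region <- match.arg(region, RESECTION_REGIONS)
  verts <- if (inherits(preop_mesh, "triangle_mesh")) preop_mesh$vertices
           else as_points(preop_mesh)
  fc <- frame_coordinates(frame, verts)
  half <- if (grepl("_medial$", region)) fc[, "ml"] < 0 else fc[, "ml"] > 0
  if (!any(half))
    stop(sprintf("no vertices in the %s half for region %s",
                 if (grepl("_medial$", region)) "medial" else "lateral", region))
  idx <- which(half)
  ref <- switch(sub("_(medial|lateral)$", "", region),
                distal = idx[which.min(fc[idx, "si"])],
                posterior = idx[which.min(fc[idx, "ap"])],
                plateau = idx[which.max(fc[idx, "si"])])
  signed_plane_distance(plane_in_ct, verts[ref, , drop = FALSE])
}

resections_for_component <- function(implant, pose, frame, mesh_ct) {
  tr <- if (inherits(pose, "component_pose")) pose$transform else pose
  if (implant$component == "femoral") {
    vals <- vapply(FEMORAL_PLANES, function(nm) {
      resection_thickness(mesh_ct, frame,
                          transform_plane(tr, implant$planes[[nm]]), nm)
    }, numeric(1))
  } else {
    pl <- transform_plane(tr, implant$planes$plateau)
    vals <- c(plateau_medial = resection_thickness(mesh_ct, frame, pl, "plateau_medial"),
              plateau_lateral = resection_thickness(mesh_ct, frame, pl, "plateau_lateral"))
  }
  vals
}

#' Bundle the inputs of one post-operative case
#'
#' @param preop_femur,preop_tibia pre-operative `triangle_mesh`es.
#' @param femur_landmarks,tibia_landmarks pre-operative `landmark_set`s (in
#'   the pre-op frame, alongside the meshes).
#' @param postop_femur,postop_tibia post-operative flare-cropped surfaces
#'   (`triangle_mesh` or point matrix) in the CT frame.
#' @param femoral_fiducials,tibial_fiducials named n x 3 matrices of implant
#'   fiducials observed in the CT frame.
#' @return an object of class `tka_case`.
#' @export
tka_case <- function(preop_femur, preop_tibia, femur_landmarks, tibia_landmarks,
                     postop_femur, postop_tibia,
                     femoral_fiducials, tibial_fiducials) {
  stopifnot(inherits(preop_femur, "triangle_mesh"),
            inherits(preop_tibia, "triangle_mesh"),
            inherits(femur_landmarks, "landmark_set"),
            inherits(tibia_landmarks, "landmark_set"))
  if (femur_landmarks$side != tibia_landmarks$side)
    stop("femoral and tibial landmark sets disagree on side")
  structure(list(preop_femur = preop_femur, preop_tibia = preop_tibia,
                 femur_landmarks = femur_landmarks,
                 tibia_landmarks = tibia_landmarks,
                 postop_femur = postop_femur, postop_tibia = postop_tibia,
                 femoral_fiducials = as_points(femoral_fiducials),
                 tibial_fiducials = as_points(tibial_fiducials)),
            class = "tka_case")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Analyse a post-operative TKA case
#'
#' Full pipeline: trimmed-ICP registration of each pre-operative bone into
#' the post-operative CT frame, propagation of the pre-operative landmarks,
#' construction of the anatomic frames, paired-point implant pose
#' estimation, and decomposition into alignment angles, placement
#' translations and the six resection thicknesses.
#'
#' @param case a `tka_case`.
#' @param implants list with `femoral` and `tibial` `implant_definition`s.
#' @param params an `icp_params` shared by both bone registrations.
#' @param init optional list with `femur` / `tibia` initial
#'   `rigid_transform`s for ICP; by default each bone is pre-aligned with
#'   the deterministic [moment_init()] (centroid + principal axes), the
#'   computational stand-in for the manual placement step of the clinical
#'   workflow.
#' @return an object of class `tka_report`.
#' @export
analyze_case <- function(case, implants = list(femoral = default_femoral_implant(),
                                               tibial = default_tibial_implant()),
                         params = icp_params(), init = list()) {
  if (!inherits(case, "tka_case")) stop("case must be a tka_case")
  pose_f <- stage("implant_pose_femoral",
                  implant_pose_from_fiducials(implants$femoral, case$femoral_fiducials))
  pose_t <- stage("implant_pose_tibial",
                  implant_pose_from_fiducials(implants$tibial, case$tibial_fiducials))
  init_f <- if (!is.null(init$femur)) init$femur
            else stage("init_femur",
                       implant_seeded_init(case$femur_landmarks, implants$femoral, pose_f))
  init_t <- if (!is.null(init$tibia)) init$tibia
            else stage("init_tibia",
                       implant_seeded_init(case$tibia_landmarks, implants$tibial, pose_t))

  reg_f <- stage("icp_femur", icp(case$preop_femur, case$postop_femur, init_f, params))
  reg_t <- stage("icp_tibia", icp(case$preop_tibia, case$postop_tibia, init_t, params))
  lms_f <- stage("landmark_propagation",
                 transform_landmarks(reg_f$transform, case$femur_landmarks))
  lms_t <- stage("landmark_propagation",
                 transform_landmarks(reg_t$transform, case$tibia_landmarks))
  frame_f <- stage("femoral_frame", build_femoral_frame(lms_f))
  frame_t <- stage("tibial_frame", build_tibial_frame(lms_t))
  mesh_f_ct <- transform_mesh(reg_f$transform, case$preop_femur)
  mesh_t_ct <- transform_mesh(reg_t$transform, case$preop_tibia)

  comp <- function(implant, pose, frame, mesh_ct, reg) {
    list(angles = stage("alignment_angles", alignment_angles(pose, frame, implant)),
         translations = stage("placement_translations",
                              placement_translations(pose, frame, implant)),
         resections = stage("resections",
                            resections_for_component(implant, pose, frame, mesh_ct)),
         fit_rms = pose$fit_rms, icp_rms = reg$rms_residual,
         icp_iterations = reg$n_iterations, icp_converged = reg$converged)
  }
  structure(list(
    femoral = comp(implants$femoral, pose_f, frame_f, mesh_f_ct, reg_f),
    tibial = comp(implants$tibial, pose_t, frame_t, mesh_t_ct, reg_t),
    frames = list(femur = frame_f, tibia = frame_t),
    registrations = list(femur = reg_f, tibia = reg_t),
    poses = list(femoral = pose_f, tibial = pose_t),
    side = case$femur_landmarks$side,
    convention = ANGLE_CONVENTION,
    version = as.character(utils::packageVersion("kneepose"))),
    class = "tka_report")
}

#' @export
print.tka_report <- function(x, digits = 2, ...) {
  cat(sprintf("TKA component position report (%s side)\n", x$side))
  cat(sprintf("  convention: %s\n\n", x$convention))
  for (comp in c("femoral", "tibial")) {
    y <- x[[comp]]
    cat(sprintf("%s component:\n",
                paste0(toupper(substring(comp, 1, 1)), substring(comp, 2))))
    cat(sprintf("  alignment (deg): FE %+.*f  VV %+.*f  IE %+.*f\n",
                digits, y$angles["FE"], digits, y$angles["VV"],
                digits, y$angles["IE"]))
    cat(sprintf("  placement (mm):  AP %+.*f  ML %+.*f  SI %+.*f\n",
                digits, y$translations["AP"], digits, y$translations["ML"],
                digits, y$translations["SI"]))
    cat("  resections (mm): ",
        paste(sprintf("%s %.2f", names(y$resections), y$resections),
              collapse = ", "), "\n")
    cat(sprintf("  fiducial fit rms %.3f mm; ICP rms %.3f mm (%d iter)\n\n",
                y$fit_rms, y$icp_rms, y$icp_iterations))
  }
  invisible(x)
}

#' @export
summary.tka_report <- function(object, ...) {
  df <- as.data.frame(object)
  cat("TKA component position summary\n")
  print(df, row.names = FALSE)
  invisible(df)
}

#' Flatten a report to a one-row-per-component data frame
#' @param x a `tka_report`.
#' @param ... unused.
#' @return data.frame with angles, translations, resections and fit metrics.
#' @export
as.data.frame.tka_report <- function(x, ...) {
  row <- function(comp) {
    y <- x[[comp]]
    res <- setNames(rep(NA_real_, length(RESECTION_REGIONS)), RESECTION_REGIONS)
    res[names(y$resections)] <- y$resections
    data.frame(component = comp, side = x$side,
               FE = y$angles[["FE"]], VV = y$angles[["VV"]], IE = y$angles[["IE"]],
               AP = y$translations[["AP"]], ML = y$translations[["ML"]],
               SI = y$translations[["SI"]], t(res),
               fit_rms = y$fit_rms, icp_rms = y$icp_rms)
  }
  rbind(row("femoral"), row("tibial"))
}
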