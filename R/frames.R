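# Patient-specific anatomic coordinate frames built from bony landmarks.
#
# Axis conventions (documented, side-aware):
#   si: inferior -> superior (the mechanical axis direction, kept exact)
#   ml: medial   -> lateral
#   ap: posterior -> anterior
# Gram-Schmidt order is fixed: the primary (SI) axis is exact, the secondary
# landmark axis is projected orthogonal to it, the tertiary axis is a cross
# product with a side-aware sign so that ml always points laterally and ap
# anteriorly, for either knee.

new_anatomic_frame <- function(origin, ap, ml, si, bone, side) {
  stopifnot(abs(sum(ap * ml)) < 1e-9, abs(sum(ap * si)) < 1e-9,
            abs(sum(ml * si)) < 1e-9)
  structure(list(origin = as.numeric(origin), ap = as.numeric(ap),
                 ml = as.numeric(ml), si = as.numeric(si),
                 bone = bone, side = side),
            class = "anatomic_frame")
}

#' @export
print.anatomic_frame <- function(x, ...) {
  cat(sprintf("Anatomic frame: %s, %s side\n", x$bone, x$side))
  m <- rbind(origin = x$origin, ap = x$ap, ml = x$ml, si = x$si)
  colnames(m) <- c("x", "y", "z")
  print(round(m, 4))
  invisible(x)
}

side_sign <- function(side) if (side == "right") 1 else -1

#' Femoral anatomic frame from landmarks
#'
#' The superior-inferior axis is the femoral mechanical axis (knee centre to
#' hip centre, kept exact). The medio-lateral axis is the transepicondylar
#' axis (medial sulcus to lateral epicondyle) projected orthogonal to the
#' mechanical axis and sign-corrected to point laterally. The
#' antero-posterior axis completes the frame, pointing anteriorly. Origin:
#' the knee centre.
#'
#' @param landmarks a femoral `landmark_set`.
#' @return an `anatomic_frame`.
#' @export
build_femoral_frame <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set") || landmarks$bone != "femur")
    stop("landmarks must be a femoral landmark_set")
  knee <- lm_point(landmarks, "knee_centre")
  hip <- lm_point(landmarks, "hip_centre")
  si <- unitv(hip - knee, "mechanical axis")
  tea <- lm_point(landmarks, "lateral_epicondyle") - lm_point(landmarks, "medial_sulcus")
  if (vnorm(cross3(si, tea)) < 1e-6)
    stop("degenerate landmarks: transepicondylar axis is parallel to the mechanical axis")
  ml <- unitv(tea - sum(tea * si) * si, "projected TEA")
  ap <- side_sign(landmarks$side) * cross3(si, ml)
  new_anatomic_frame(knee, ap, ml, si, "femur", landmarks$side)
}

#' Tibial anatomic frame from landmarks
#'
#' The tibial mechanical (SI) axis runs from the midpoint of the malleoli to
#' the midpoint of the medial third of the tubercle and the PCL insertion
#' (kept exact). The AP axis is the tubercle-to-PCL line projected
#' orthogonal to the mechanical axis, pointing anteriorly; the ML axis
#' completes the frame, pointing laterally. Origin: the tibial plateau
#' centre.
#'
#' @param landmarks a tibial `landmark_set`.
#' @return an `anatomic_frame`.
#' @export
build_tibial_frame <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set") || landmarks$bone != "tibia")
    stop("landmarks must be a tibial landmark_set")
  ankle <- midpoint(lm_point(landmarks, "medial_malleolus"),
                    lm_point(landmarks, "lateral_malleolus"))
  tub <- lm_point(landmarks, "tubercle_medial_third")
  pcl <- lm_point(landmarks, "pcl_insertion")
  proximal <- midpoint(tub, pcl)
  si <- unitv(proximal - ankle, "tibial mechanical axis")
  ap_raw <- tub - pcl
  if (vnorm(ap_raw) < 1e-9)
    stop("degenerate landmarks: tubercle and PCL insertion coincide")
  if (vnorm(cross3(si, ap_raw)) < 1e-6)
    stop("degenerate landmarks: tibial AP axis is parallel to the mechanical axis")
  ap <- unitv(ap_raw - sum(ap_raw * si) * si, "projected tibial AP axis")
  ml <- side_sign(landmarks$side) * cross3(ap, si)
  new_anatomic_frame(lm_point(landmarks, "plateau_centre"), ap, ml, si,
                     "tibia", landmarks$side)
}

#' Build the anatomic frame appropriate to a landmark set's bone
#' @param landmarks a `landmark_set`.
#' @return an `anatomic_frame`.
#' @export
build_frame <- function(landmarks) {
  if (landmarks$bone == "femur") build_femoral_frame(landmarks)
  else build_tibial_frame(landmarks)
}

#' Express points in an anatomic frame
#'
#' @param frame an `anatomic_frame`.
#' @param points points in the CT frame, mm.
#' @return n x 3 matrix of (ap, ml, si) coordinates relative to the frame
#'   origin, mm.
#' @export
frame_coordinates <- function(frame, points) {
  p <- as_points(points)
  rel <- sweep(p, 2L, frame$origin)
  out <- cbind(ap = as.numeric(rel %*% frame$ap),
               ml = as.numeric(rel %*% frame$ml),
               si = as.numeric(rel %*% frame$si))
  rownames(out) <- rownames(p)
  out
}
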