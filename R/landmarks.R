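FEMUR_LANDMARKS <- c("hip_centre", "knee_centre", "medial_sulcus",
                     "lateral_epicondyle")
TIBIA_LANDMARKS <- c("medial_malleolus", "lateral_malleolus",
                     "tubercle_medial_third", "pcl_insertion",
                     "plateau_centre")

#' Named anatomical landmark set
#'
#' The controlled vocabulary is fixed: femoral sets need `hip_centre`,
#' `knee_centre`, `medial_sulcus`, `lateral_epicondyle`; tibial sets need
#' `medial_malleolus`, `lateral_malleolus`, `tubercle_medial_third`,
#' `pcl_insertion`, `plateau_centre`. Extra named points are allowed.
#'
#' @param points named list of length-3 points, or a matrix with row names.
#' @param bone `"femur"` or `"tibia"`.
#' @param side `"left"` or `"right"`.
#' @return an object of class `landmark_set` (points stored as a named
#'   n x 3 matrix, mm).
#' @export
landmark_set <- function(points, bone = c("femur", "tibia"),
                         side = c("right", "left")) {
  bone <- match.arg(bone)
  side <- match.arg(side)
  if (is.list(points)) {
    nms <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nms
  }
  points <- as_points(points)
  if (is.null(rownames(points)) || any(rownames(points) == ""))
    stop("every landmark must be named")
  required <- if (bone == "femur") FEMUR_LANDMARKS else TIBIA_LANDMARKS
  missing <- setdiff(required, rownames(points))
  if (length(missing) > 0L)
    stop(sprintf("%s landmark set is missing: %s", bone,
                 paste(missing, collapse = ", ")))
  structure(list(points = points, bone = bone, side = side),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: %s, %s side, %d points\n",
              x$bone, x$side, nrow(x$points)))
  print(round(x$points, 3))
  invisible(x)
}

lm_point <- function(lms, name) {
  if (!name %in% rownames(lms$points))
    stop(sprintf("landmark '%s' not present", name))
  as.numeric(lms$points[name, ])
}

#' Transform a landmark set
#' @param transform a `rigid_transform`.
#' @param lms a `landmark_set`.
#' @return the transformed `landmark_set`.
#' @export
transform_landmarks <- function(transform, lms) {
  landmark_set(apply_transform(transform, lms$points), lms$bone, lms$side)
}

#' Read / write landmark JSON
#'
#' Landmarks are exchanged as
#' `{"bone": ..., "side": ..., "landmarks": {"name": [x, y, z], ...}}`
#' with coordinates in millimetres.
#'
#' @param path JSON file path.
#' @return `read_landmarks`: a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$landmarks)) stop(sprintf("no 'landmarks' field in %s", path))
  pts <- doc$landmarks
  if (is.list(pts)) {
    nms <- names(pts)
    pts <- do.call(rbind, lapply(pts, as.numeric))
    rownames(pts) <- nms
  }
  landmark_set(pts, doc$bone, doc$side)
}

#' @rdname read_landmarks
#' @param lms a `landmark_set`.
#' @return `write_landmarks`: `path`, invisibly.
#' @export
write_landmarks <- function(lms, path) {
  pts <- lapply(seq_len(nrow(lms$points)), function(i) as.numeric(lms$points[i, ]))
  names(pts) <- rownames(lms$points)
  jsonlite::write_json(list(bone = lms$bone, side = lms$side, landmarks = pts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Landmark quality-control check
#'
#' Flags landmarks whose positions differ between two observers by more than
#' a threshold (default 4 mm), the trigger for independent review in the
#' pre-operative landmarking workflow.
#'
#' @param landmarks_a,landmarks_b `landmark_set`s (or named point matrices)
#'   sharing the same name vocabulary.
#' @param threshold_mm flag landmarks whose Euclidean separation exceeds
#'   this, mm.
#' @return character vector of flagged landmark names (possibly empty).
#' @export
landmark_qc <- function(landmarks_a, landmarks_b, threshold_mm = 4.0) {
  pa <- if (inherits(landmarks_a, "landmark_set")) landmarks_a$points else as_points(landmarks_a)
  pb <- if (inherits(landmarks_b, "landmark_set")) landmarks_b$points else as_points(landmarks_b)
  if (!setequal(rownames(pa), rownames(pb))) {
    sdiff <- c(setdiff(rownames(pa), rownames(pb)),
               setdiff(rownames(pb), rownames(pa)))
    stop(sprintf("landmark name sets differ: %s", paste(sdiff, collapse = ", ")))
  }
  pb <- pb[rownames(pa), , drop = FALSE]
  d <- sqrt(rowSums((pa - pb)^2))
  names(d)[d > threshold_mm]
}
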