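# Implant component definitions. Commercial TKA component geometry is
# proprietary, so components are described by a parametric definition file:
# named registration fiducials, orthonormal local axes, and named resection
# planes, all in implant-local millimetre coordinates. Real CAD-derived
# fiducials and planes can be supplied through the same format.

FEMORAL_PLANES <- c("distal_medial", "distal_lateral",
                    "posterior_medial", "posterior_lateral")
TIBIAL_PLANES <- c("plateau")

#' Implant component definition
#'
#' @param name component name.
#' @param component `"femoral"` or `"tibial"`.
#' @param fiducials named n x 3 matrix (or named list of length-3 points) of
#'   at least 3 non-collinear registration fiducials, implant-local mm.
#' @param axes list with unit vectors `ap`, `ml`, `si` (orthonormal,
#'   implant-local).
#' @param planes named list of [plane()]s, implant-local; femoral components
#'   need `distal_medial`, `distal_lateral`, `posterior_medial`,
#'   `posterior_lateral`; tibial components need `plateau`. Normals must
#'   point toward the bone that was removed.
#' @return an object of class `implant_definition`.
#' @export
implant_definition <- function(name, component = c("femoral", "tibial"),
                               fiducials, axes, planes) {
  component <- match.arg(component)
  if (is.list(fiducials) && !is.matrix(fiducials)) {
    nms <- names(fiducials)
    fiducials <- do.call(rbind, lapply(fiducials, as.numeric))
    rownames(fiducials) <- nms
  }
  fiducials <- as_points(fiducials)
  if (is.null(rownames(fiducials)) || any(rownames(fiducials) == ""))
    stop("implant fiducials must be named")
  if (nrow(fiducials) < 3L) stop("at least 3 fiducials are required")
  sv <- svd(sweep(fiducials, 2L, colMeans(fiducials)), nu = 0, nv = 0)$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1)) stop("implant fiducials are collinear")
  axes <- lapply(axes[c("ap", "ml", "si")], as.numeric)
  A <- cbind(axes$ap, axes$ml, axes$si)
  if (max(abs(crossprod(A) - diag(3))) > 1e-9)
    stop("implant local axes must be orthonormal")
  required <- if (component == "femoral") FEMORAL_PLANES else TIBIAL_PLANES
  planes <- lapply(planes, function(p) if (inherits(p, "plane")) p else plane(p$point, p$normal))
  missing <- setdiff(required, names(planes))
  if (length(missing) > 0L)
    stop(sprintf("%s implant definition is missing plane(s): %s", component,
                 paste(missing, collapse = ", ")))
  structure(list(name = name, component = component, fiducials = fiducials,
                 axes = axes, planes = planes),
            class = "implant_definition")
}

#' @export
print.implant_definition <- function(x, ...) {
  cat(sprintf("Implant definition '%s' (%s): %d fiducials, %d resection plane(s)\n",
              x$name, x$component, nrow(x$fiducials), length(x$planes)))
  invisible(x)
}

#' Read / write implant definition JSON
#'
#' Format:
#' `{"name", "component", "fiducials": {"name": [x,y,z]}, "axes": {"ap","ml","si"},
#'   "planes": {"name": {"point": [..], "normal": [..]}}}`.
#'
#' @param path JSON file path.
#' @return `read_implant_definition`: an `implant_definition`.
#' @export
read_implant_definition <- function(path) {
  if (!file.exists(path)) stop(sprintf("implant definition not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  planes <- lapply(doc$planes, function(p) plane(p$point, p$normal))
  implant_definition(doc$name, doc$component, doc$fiducials, doc$axes, planes)
}

#' @rdname read_implant_definition
#' @param implant an `implant_definition`.
#' @return `write_implant_definition`: `path`, invisibly.
#' @export
write_implant_definition <- function(implant, path) {
  fids <- lapply(seq_len(nrow(implant$fiducials)),
                 function(i) as.numeric(implant$fiducials[i, ]))
  names(fids) <- rownames(implant$fiducials)
  doc <- list(name = implant$name, component = implant$component,
              fiducials = fids, axes = implant$axes,
              planes = lapply(implant$planes,
                              function(p) list(point = p$point, normal = p$normal)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generic femoral / tibial component definitions
#'
#' Parametric stand-ins for proprietary CAD: a cruciate-retaining-style
#' femoral component with 9 mm distal and 10 mm posterior cut offsets, and a
#' tibial tray with a single plateau cut 10 mm below the implant-local
#' origin. Fiducials are six well-spread points on each component. Local
#' axes coincide with the anatomic axes at neutral placement.
#'
#' @param distal_cut_mm femoral distal cut plane height (implant-local SI),
#'   mm below origin.
#' @param posterior_cut_mm femoral posterior cut plane (implant-local AP),
#'   mm posterior of origin.
#' @param side `"right"` or `"left"`; left components are the mirror image
#'   (implant-local x is medial-to-lateral of the target knee, so the ml
#'   axis of a left component is `(-1, 0, 0)`).
#' @return an `implant_definition`.
#' @export
default_femoral_implant <- function(distal_cut_mm = 6, posterior_cut_mm = 20,
                                    side = c("right", "left")) {
  side <- match.arg(side)
  s <- if (side == "right") 1 else -1
  # registration points span the whole component (condyles, anterior flange,
  # intercondylar box): the spread sets the angular precision of the
  # paired-point fit under picking noise
  fids <- rbind(med_distal = c(-s * 30, 5, -5), lat_distal = c(s * 30, 5, -5),
                med_post = c(-s * 26, -24, 14), lat_post = c(s * 26, -24, 14),
                med_ant = c(-s * 24, 24, 2), lat_ant = c(s * 24, 24, 2),
                flange_sup = c(0, 24, 32), flange_mid = c(0, 30, 12),
                box_post = c(0, -16, 26), notch = c(0, 4, -4),
                med_mid = c(-s * 32, -8, 6), lat_mid = c(s * 32, -8, 6))
  axes <- list(ap = c(0, 1, 0), ml = c(s, 0, 0), si = c(0, 0, 1))
  planes <- list(
    distal_medial = plane(c(-s * 22, 0, -distal_cut_mm), c(0, 0, -1)),
    distal_lateral = plane(c(s * 22, 0, -distal_cut_mm), c(0, 0, -1)),
    posterior_medial = plane(c(-s * 22, -posterior_cut_mm, 10), c(0, -1, 0)),
    posterior_lateral = plane(c(s * 22, -posterior_cut_mm, 10), c(0, -1, 0)))
  implant_definition(paste0("generic-femoral-", side), "femoral", fids, axes,
                     planes)
}

#' @rdname default_femoral_implant
#' @param plateau_cut_mm tibial plateau cut depth below the implant-local
#'   origin, mm.
#' @export
default_tibial_implant <- function(plateau_cut_mm = 10,
                                   side = c("right", "left")) {
  side <- match.arg(side)
  s <- if (side == "right") 1 else -1
  fids <- rbind(med_edge = c(-s * 30, 4, -2), lat_edge = c(s * 30, 4, -2),
                ant_edge = c(0, 22, -2),
                post_med = c(-s * 20, -16, -2), post_lat = c(s * 20, -16, -2),
                stem_tip = c(0, 0, -55), stem_mid = c(0, 0, -35),
                keel_ant = c(0, 12, -25), keel_post = c(0, -12, -25),
                med_rim = c(-s * 28, -10, -8), lat_rim = c(s * 28, -10, -8),
                ant_rim = c(0, 20, -10))
  axes <- list(ap = c(0, 1, 0), ml = c(s, 0, 0), si = c(0, 0, 1))
  planes <- list(plateau = plane(c(0, 0, -plateau_cut_mm), c(0, 0, 1)))
  implant_definition(paste0("generic-tibial-", side), "tibial", fids, axes,
                     planes)
}
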