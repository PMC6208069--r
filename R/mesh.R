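#' Triangle surface mesh
#'
#' Bone and implant surfaces are triangle meshes in millimetres: an n x 3
#' vertex matrix and an m x 3 integer face matrix (1-based vertex indices).
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates, mm.
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, n_vertices]")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
            faces[, 1L] == faces[, 3L]))
      stop("a face repeats a vertex index")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces (mm)\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#' @param transform a `rigid_transform`.
#' @param mesh a `triangle_mesh`.
#' @return the transformed `triangle_mesh`.
#' @export
transform_mesh <- function(transform, mesh) {
  triangle_mesh(apply_transform(transform, mesh$vertices), mesh$faces)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  e1 <- vertices[faces[, 2L], , drop = FALSE] - a
  e2 <- vertices[faces[, 3L], , drop = FALSE] - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Merge vertices closer than `tol` (mm) by snapping to a tol-grid, and drop
# degenerate (zero-area) faces with a warning. STL stores each facet's
# corners independently, so merging is what makes vertex queries meaningful.
weld_mesh <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1L] / tol), round(vertices[, 2L] / tol),
               round(vertices[, 3L] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3L)
  degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  if (nrow(faces) > 0L)
    degen[!degen] <- face_areas(vertices, faces[!degen, , drop = FALSE]) <= 0
  if (any(degen)) {
    warning(sprintf("dropped %d degenerate (zero-area) face(s)", sum(degen)))
    faces <- faces[!degen, , drop = FALSE]
  }
  triangle_mesh(vertices, faces)
}

#' Read an STL surface mesh
#'
#' Reads binary or ASCII stereolithography files (auto-detected). STL carries
#' no units; coordinates are taken as millimetres. Duplicate vertices within
#' 1e-6 mm are merged and zero-area facets dropped (with a warning), since
#' STL stores facets independently.
#'
#' @param path path to an `.stl` file.
#' @return a `triangle_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop(sprintf("STL file not found: %s", path))
  size <- file.info(path)$size
  if (size < 15) stop(sprintf("STL parse error at byte 0: file too short (%d bytes)", size))
  con <- file(path, "rb")
  on.exit(close(con))
  head84 <- readBin(con, "raw", n = min(84, size))
  is_binary <- FALSE
  if (size >= 84) {
    nf <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (nf >= 0 && size == 84 + 50 * as.double(nf)) is_binary <- TRUE
  }
  if (is_binary) {
    nf <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (nf == 0L) stop("STL parse error at byte 80: facet count is zero")
    rec <- matrix(readBin(con, "raw", n = 50 * nf), nrow = 50L)
    flt <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                   size = 4, n = 12L * nf, endian = "little")
    flt <- matrix(flt, nrow = 12L)             # normal + 3 vertices per facet
    verts <- matrix(as.vector(flt[4:12, , drop = FALSE]), ncol = 3L, byrow = TRUE)
    if (!all(is.finite(verts)))
      stop("STL parse error: non-finite vertex coordinate in facet data")
  } else {
    txt <- readLines(path, warn = FALSE)
    if (length(txt) == 0L || !grepl("^\\s*solid", txt[1L]))
      stop("STL parse error at byte 0: neither a valid binary STL (size mismatch with facet count at byte 80) nor an ASCII 'solid'")
    vlines <- grep("^\\s*vertex\\s", txt)
    if (length(vlines) == 0L) stop("STL parse error: ASCII file contains no vertex records")
    if (length(vlines) %% 3L != 0L)
      stop(sprintf("STL parse error: %d vertex lines, not a multiple of 3", length(vlines)))
    nums <- lapply(strsplit(trimws(txt[vlines]), "\\s+"), function(f) {
      v <- suppressWarnings(as.numeric(f[-1L]))
      if (length(v) != 3L || anyNA(v))
        stop(sprintf("STL parse error: malformed vertex line '%s'", paste(f, collapse = " ")))
      v
    })
    verts <- do.call(rbind, nums)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  weld_mesh(verts, faces)
}

#' Write an STL surface mesh
#'
#' @param mesh a `triangle_mesh` with at least one face.
#' @param path output path.
#' @param dialect `"binary"` (80-byte header, uint32 facet count, 50-byte
#'   facet records) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  nf <- nrow(mesh$faces)
  if (nf == 0L) stop("refusing to write an STL with zero facets")
  v1 <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (dialect == "ascii") {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1L], m[, 2L], m[, 3L])
    lines <- c("solid kneepose",
               as.vector(rbind(paste("facet normal", fmt(nrm)),
                               "  outer loop",
                               paste("    vertex", fmt(v1)),
                               paste("    vertex", fmt(v2)),
                               paste("    vertex", fmt(v3)),
                               "  endloop",
                               "endfacet")),
               "endsolid kneepose")
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    flt <- t(cbind(nrm, v1, v2, v3))           # 12 floats per facet, column-wise
    fbytes <- matrix(writeBin(as.vector(flt), raw(), size = 4, endian = "little"),
                     nrow = 48L)
    rec <- rbind(fbytes, matrix(as.raw(0L), 2L, nf))
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}
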