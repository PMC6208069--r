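# Rigid registration: closed-form paired-point (Kabsch) and trimmed
# iterative closest point surface registration.

new_registration_fit <- function(transform, rms, iters, converged,
                                 rms_history = numeric()) {
  structure(list(transform = transform, rms_residual = rms,
                 n_iterations = iters, converged = converged,
                 rms_history = rms_history),
            class = "registration_fit")
}

#' @export
print.registration_fit <- function(x, ...) {
  cat("Rigid registration fit\n")
  cat(sprintf("  rms residual: %.6f mm\n", x$rms_residual))
  cat(sprintf("  iterations:   %d (%s)\n", x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

#' Paired-point rigid registration (Kabsch algorithm)
#'
#' Closed-form SVD solution for the proper rigid transform minimising
#' `sum |R s_i + t - d_i|^2` over paired points in the same order. If the
#' SVD yields a reflection the sign of the last singular vector is flipped
#' (standard correction), so the result is always a proper rotation.
#'
#' @param src_points,dst_points n x 3 matrices of paired points (n >= 3,
#'   non-collinear), mm.
#' @return a `registration_fit`: the optimal `rigid_transform`, post-fit RMS
#'   residual (mm), `n_iterations = 0`, `converged = TRUE`.
#' @export
kabsch <- function(src_points, dst_points) {
  src <- as_points(src_points)
  dst <- as_points(dst_points)
  if (nrow(src) != nrow(dst))
    stop("src and dst must contain the same number of points")
  if (nrow(src) < 3L)
    stop("degenerate geometry: at least 3 point pairs are required")
  cs <- colMeans(src); cd <- colMeans(dst)
  S <- sweep(src, 2L, cs); D <- sweep(dst, 2L, cd)
  # collinearity check: rank of centred source < 2
  sv_src <- svd(S, nu = 0, nv = 0)$d
  if (sv_src[2L] < 1e-9 * max(sv_src[1L], 1))
    stop("degenerate geometry: source points are collinear")
  H <- crossprod(S, D)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cd - as.numeric(R %*% cs)
  tr <- rigid_transform(R, t)
  resid <- apply_transform(tr, src) - dst
  rms <- sqrt(mean(rowSums(resid^2)))
  new_registration_fit(tr, rms, 0L, TRUE)
}

#' Trimmed ICP parameters
#'
#' Defaults are chosen for the partial-overlap setting where the
#' post-operative surface is missing resected bone and a peri-implant flare
#' band: the worst 25% of correspondences are trimmed each iteration (the
#' trim must exceed the non-overlap fraction, which is 15-20% for a
#' flare-cropped TKA surface, or the unmatched pre-operative bone biases
#' the fit) and pairs farther than 10 mm are gated out.
#'
#' @param max_iterations maximum ICP iterations.
#' @param tolerance convergence threshold on the change in RMS between
#'   iterations, mm.
#' @param trim_fraction fraction of the worst (largest-distance)
#'   correspondences discarded each iteration, in `[0, 0.5)`.
#' @param max_correspondence_distance correspondences farther than this are
#'   ignored, mm.
#' @param subsample_n optionally register using a random subsample of this
#'   many source points (default `NULL`: use all points, deterministic).
#' @param seed integer seed for the subsample draw; ignored when
#'   `subsample_n` is `NULL`.
#' @return an object of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, tolerance = 1e-6,
                       trim_fraction = 0.25, max_correspondence_distance = 10,
                       subsample_n = NULL, seed = 1L) {
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  if (max_correspondence_distance <= 0)
    stop("max_correspondence_distance must be > 0")
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, trim_fraction = trim_fraction,
                 max_correspondence_distance = max_correspondence_distance,
                 subsample_n = subsample_n, seed = as.integer(seed)),
            class = "icp_params")
}

#' Moment-based rigid pre-alignment
#'
#' Deterministic initializer standing in for the manual bone placement of
#' the clinical workflow: aligns the centroids and principal axes of the two
#' point clouds. Principal-axis sign ambiguity (four proper-rotation
#' candidates) is resolved by a short trimmed-ICP burn-in from each
#' candidate, keeping the one with the lowest residual. Suited to long-bone
#' surfaces, whose first principal axis (the shaft) is stable even under
#' the partial cropping of post-operative segmentation.
#'
#' @param src,dst `triangle_mesh`es or n x 3 point matrices, mm.
#' @param params an `icp_params` used for the scoring registrations.
#' @param n_score source points used when scoring candidates (deterministic
#'   stride subsample; full resolution is only needed for the final
#'   refinement, not for basin selection).
#' @return a `rigid_transform` suitable as `init_transform` for [icp()].
#' @export
moment_init <- function(src, dst, params = icp_params(), n_score = 600L) {
  src_pts <- if (inherits(src, "triangle_mesh")) src$vertices else as_points(src)
  dst_pts <- if (inherits(dst, "triangle_mesh")) dst$vertices else as_points(dst)
  cs <- colMeans(src_pts); cd <- colMeans(dst_pts)
  Vs <- svd(sweep(src_pts, 2L, cs), nu = 0)$v
  Vd <- svd(sweep(dst_pts, 2L, cd), nu = 0)$v
  sub <- src_pts[unique(round(seq(1L, nrow(src_pts),
                                  length.out = min(n_score, nrow(src_pts))))), ,
                 drop = FALSE]
  cands <- list(identity_transform())
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    D <- diag(c(s1, s2, 1))
    R <- Vd %*% D %*% t(Vs)
    if (det(R) < 0) R <- Vd %*% diag(c(s1, s2, -1)) %*% t(Vs)
    cands[[length(cands) + 1L]] <- rigid_transform(R, cd - as.numeric(R %*% cs))
  }
  best <- NULL; best_rms <- Inf
  for (cand in cands) {
    fit <- tryCatch(icp(sub, dst_pts, cand, params), error = function(e) NULL)
    if (!is.null(fit) && fit$rms_residual < best_rms) {
      best_rms <- fit$rms_residual
      best <- fit$transform
    }
  }
  if (is.null(best)) stop("moment initialization failed: no candidate produced overlap")
  best
}

#' Implant-seeded rigid pre-alignment for bone ICP
#'
#' Landmark-based Kabsch pre-alignment: the implant pose recovered from its
#' fiducials predicts, to within the component's few degrees of
#' malalignment and millimetres of placement offset, where the bone's
#' anatomic frame lies in the post-operative CT. Registering the
#' pre-operative anatomic frame onto the posed implant frame therefore
#' starts the bone ICP well inside its convergence basin — the
#' computational counterpart of the manual placement step in the clinical
#' workflow.
#'
#' @param landmarks the bone's pre-operative `landmark_set` (pre-op frame).
#' @param implant the component's `implant_definition`.
#' @param pose the `component_pose` (implant-local to CT) from
#'   [implant_pose_from_fiducials()].
#' @return a `rigid_transform` mapping the pre-operative frame into the CT
#'   frame, for use as `init_transform` in [icp()].
#' @export
implant_seeded_init <- function(landmarks, implant, pose) {
  frame <- build_frame(landmarks)
  tr <- if (inherits(pose, "component_pose")) pose$transform else pose
  arm <- 100  # mm; virtual axis-tip points for the paired-point fit
  src <- rbind(frame$origin,
               frame$origin + arm * frame$ap,
               frame$origin + arm * frame$ml,
               frame$origin + arm * frame$si)
  o_ct <- as.numeric(apply_transform(tr, c(0, 0, 0)))
  R <- tr$rotation
  dst <- rbind(o_ct,
               o_ct + arm * as.numeric(R %*% implant$axes$ap),
               o_ct + arm * as.numeric(R %*% implant$axes$ml),
               o_ct + arm * as.numeric(R %*% implant$axes$si))
  kabsch(src, dst)$transform
}

#' Trimmed iterative closest point registration
#'
#' Aligns source points (typically the pre-operative bone mesh) to a
#' destination point set (the flare-cropped post-operative surface).
#' Each iteration: nearest-neighbour correspondences (exhaustive search,
#' lowest-index tie-break), trimming to the best `1 - trim_fraction` of
#' correspondences (the trimmed-ICP objective), an annealed distance gate
#' (pairs up to three times the current trimmed RMS are admitted while far
#' from alignment, tightening to `max_correspondence_distance`), then a
#' Kabsch update on the kept pairs. Iteration stops when the trimmed RMS
#' changes by less than `tolerance`, stops improving for ten consecutive
#' iterations, or `max_iterations` is reached; the best pose seen is
#' returned, and the recorded RMS history is the improving envelope
#' (non-increasing).
#'
#' ICP is local: it must be seeded either by `init_transform` or by a
#' landmark-based Kabsch pre-alignment such as [implant_seeded_init()] or
#' [moment_init()]. Recovery is validated for initial offsets of at least
#' 10 degrees / 5 mm on knee-scale surfaces.
#'
#' @param src a `triangle_mesh` or n x 3 point matrix (moving), mm.
#' @param dst a `triangle_mesh` or n x 3 point matrix (fixed), mm.
#' @param init_transform initial `rigid_transform` (default identity).
#' @param params an `icp_params`.
#' @return a `registration_fit` with the source-to-destination transform,
#'   final trimmed RMS (mm), iteration count, convergence flag, and the
#'   per-iteration RMS history.
#' @export
icp <- function(src, dst, init_transform = identity_transform(),
                params = icp_params()) {
  if (!inherits(params, "icp_params")) stop("params must be icp_params()")
  if (!inherits(init_transform, "rigid_transform"))
    stop("init_transform must be a rigid_transform")
  src_pts <- if (inherits(src, "triangle_mesh")) src$vertices else as_points(src)
  dst_pts <- if (inherits(dst, "triangle_mesh")) dst$vertices else as_points(dst)
  if (nrow(dst_pts) == 0L) stop("destination point set is empty")
  if (!is.null(params$subsample_n) && params$subsample_n < nrow(src_pts)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(params$seed)
    keep <- sort(sample.int(nrow(src_pts), params$subsample_n))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    src_pts <- src_pts[keep, , drop = FALSE]
  }

  transform <- init_transform
  best_transform <- init_transform
  best_rms <- Inf
  rms_history <- numeric()
  prev_rms <- Inf
  converged <- FALSE
  iters <- 0L
  patience <- 10L        # stop after this many iterations without improvement
  stall <- 0L
  for (it in seq_len(params$max_iterations)) {
    moved <- apply_transform(transform, src_pts)
    nn <- .closest_point(moved, dst_pts)
    # trimmed-ICP objective: rms over the best (1 - trim_fraction) of the
    # correspondences — a fixed fraction, so the value is comparable across
    # iterations and initializations
    n_keep <- max(3L, floor(length(nn$distance) * (1 - params$trim_fraction)))
    ord <- order(nn$distance, seq_along(nn$distance))
    keep <- sort(ord[seq_len(n_keep)])
    rms <- sqrt(mean(nn$distance[keep]^2))
    # annealed distance gate: admit pairs up to 3x the current trimmed rms
    # while far from alignment, tightening to the configured gate (a fixed
    # tight gate stalls under gross initial offsets)
    gate <- max(params$max_correspondence_distance, 3 * rms)
    keep <- keep[nn$distance[keep] <= gate]
    if (length(keep) < 3L)
      stop("no overlap: fewer than 3 correspondences within max_correspondence_distance")
    iters <- it
    if (rms < best_rms - 1e-15) {
      # accepted step: the recorded rms sequence is the improving envelope
      best_rms <- rms
      best_transform <- transform
      rms_history <- c(rms_history, rms)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (abs(prev_rms - rms) < params$tolerance) {
      converged <- TRUE
      break
    }
    if (stall >= patience) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    fit <- kabsch(src_pts[keep, , drop = FALSE],
                  dst_pts[nn$index[keep], , drop = FALSE])
    transform <- fit$transform
  }
  new_registration_fit(best_transform, best_rms, iters, converged, rms_history)
}
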