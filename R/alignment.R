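# Rigid alignment of a subject bone to its pre-oriented template: sagittal
# mirroring for right-side bones, a PCA-based initialization with exhaustive
# sign disambiguation, and point-to-surface iterative closest point.

#' Mirror a mesh across the sagittal plane
#'
#' Reflects vertices across x = 0 and reverses the face winding so outward
#' normals are preserved. Used to turn right-side bones into left-side
#' anatomy before template alignment; the subsequent rigid registration
#' absorbs the arbitrary choice of mirror plane.
#'
#' @param mesh a [triangle_mesh()].
#' @return the mirrored mesh.
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  triangle_mesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE],
                name = mesh$name, validate = FALSE)
}

# Principal axes of a point cloud: columns ordered by decreasing spread,
# forced to det +1.
principal_axes <- function(points) {
  ctr <- colMeans(points)
  cc <- crossprod(sweep(points, 2, ctr)) / nrow(points)
  eg <- eigen(cc, symmetric = TRUE)
  ev <- eg$vectors
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  list(center = ctr, axes = ev, sdev = sqrt(pmax(0, eg$values)))
}

#' Provisional alignment by principal axes
#'
#' Translates the subject centroid onto the template centroid and rotates the
#' subject's principal axes (of area-weighted surface samples) onto the
#' template's. The four proper sign assignments of the principal axes are
#' evaluated exhaustively and the one with the lowest RMS nearest-neighbour
#' distance on a 500-point subsample wins. Nearly-isotropic shapes (two
#' spread ratios above 0.98) fall back to a centroid-only translation with
#' `confident = FALSE`.
#'
#' @param subject subject `triangle_mesh` (already mirrored if right-sided).
#' @param template a `bone_template` from [select_template()], or a
#'   `triangle_mesh`.
#' @param n_samples surface samples used for the PCA (default 2000).
#' @param seed RNG seed for the sampling.
#' @return a list with `transform` ([rigid_transform()]), `confident`, and
#'   `rms` of the winning candidate.
#' @export
initial_alignment <- function(subject, template, n_samples = 2000, seed = 0) {
  tmesh <- if (inherits(template, "bone_template")) template$mesh else template
  with_seed(seed, {
    sub_pts <- sample_mesh_surface(subject, n_samples)
    tpl_pts <- sample_mesh_surface(tmesh, n_samples)
    eval_idx <- sample.int(n_samples, min(500L, n_samples))
  })
  ps <- principal_axes(sub_pts)
  pt <- principal_axes(tpl_pts)

  ratios <- c(ps$sdev[2] / ps$sdev[1], ps$sdev[3] / ps$sdev[2])
  if (any(!is.finite(ratios)) || all(ratios > 0.98)) {
    tr <- rigid_transform(diag(3), pt$center - ps$center)
    return(list(transform = tr, confident = FALSE, rms = NA_real_))
  }

  # Candidate poses: every sign assignment of the principal axes, and — for
  # axis pairs whose spreads are within 10% of each other, where the eigen
  # decomposition may order or mix them arbitrarily — every permutation that
  # exchanges only such near-degenerate axes.
  perms <- list(c(1L, 2L, 3L))
  close_pair <- function(i, j) {
    min(ps$sdev[i], ps$sdev[j]) / max(ps$sdev[i], ps$sdev[j]) > 0.9
  }
  if (close_pair(1, 2)) perms <- c(perms, list(c(2L, 1L, 3L)))
  if (close_pair(2, 3)) perms <- c(perms, list(c(1L, 3L, 2L)))
  if (close_pair(1, 3)) perms <- c(perms, list(c(3L, 2L, 1L)))
  if (close_pair(1, 2) && close_pair(2, 3)) {
    perms <- c(perms, list(c(2L, 3L, 1L), c(3L, 1L, 2L)))
  }
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
                c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(-1, -1, -1))

  best <- NULL
  ev_pts <- sub_pts[eval_idx, , drop = FALSE]
  for (perm in perms) {
    base <- ps$axes[, perm, drop = FALSE]
    for (s in signs) {
      rot <- pt$axes %*% diag(s) %*% t(base)
      if (det(rot) < 0) next # keep proper rotations only
      tr <- rigid_transform(rot, pt$center - as.numeric(rot %*% ps$center))
      # near-symmetric bones make wrong candidates almost as close as the
      # right one at the coarse stage; a short ICP burst on the subsample
      # separates the basins decisively before the RMS comparison
      tr <- refine_rigid(ev_pts, tmesh, tr, iterations = 20)
      moved <- apply_transform(tr, ev_pts)
      d <- cpp_closest_on_mesh(moved, tmesh$vertices, tmesh$faces)$dist
      rms <- sqrt(mean(d^2))
      if (is.null(best) || rms < best$rms) {
        best <- list(transform = tr, confident = TRUE, rms = rms)
      }
    }
  }
  best
}

# fixed-budget rigid refinement of a point set onto a mesh
refine_rigid <- function(X, tmesh, transform, iterations = 10) {
  eng <- icp_engine(X, tmesh, transform$rotation, transform$translation,
                    max_iterations = iterations, tolerance = 1e-6)
  rigid_transform(eng$rot, eng$tra)
}

#' Rigid iterative-closest-point alignment to a template
#'
#' Point-to-surface ICP: area-weighted surface samples of the subject are
#' matched to their closest points on the template surface, and the rigid
#' (rotation + translation, no scale) least-squares pose is re-estimated until
#' the RMS residual improves by less than `tolerance` or `max_iterations` is
#' reached. The residual is non-increasing across iterations by construction
#' (fixed sample set, alternating minimization). Deterministic given `seed`.
#'
#' @param subject subject `triangle_mesh` (already mirrored if right-sided).
#' @param template a `bone_template` or `triangle_mesh`.
#' @param initial a [rigid_transform()] starting pose (usually from
#'   [initial_alignment()]); identity if omitted.
#' @param max_iterations iteration budget (default 100).
#' @param tolerance RMS improvement threshold in mm (default 1e-4).
#' @param sample_count subject surface samples (default 2000, minimum 100).
#' @param seed RNG seed for the sampling.
#' @return a list with `transform`, `rms_residual` (mm), `iterations_used`,
#'   `converged`, and `residual_history`.
#' @export
icp_align <- function(subject, template, initial = NULL,
                      max_iterations = 100, tolerance = 1e-4,
                      sample_count = 2000, seed = 0) {
  if (sample_count < 100) stop("sample_count must be at least 100", call. = FALSE)
  tmesh <- if (inherits(template, "bone_template")) template$mesh else template
  if (is.null(initial)) initial <- rigid_transform()
  X <- with_seed(seed, sample_mesh_surface(subject, sample_count))
  mirrored <- initial$mirrored
  if (mirrored) X[, 1] <- -X[, 1] # work in the mirrored frame

  eng <- icp_engine(X, tmesh, initial$rotation, initial$translation,
                    max_iterations = max_iterations, tolerance = tolerance)
  list(
    transform = rigid_transform(eng$rot, eng$tra, mirrored = mirrored),
    rms_residual = eng$history[length(eng$history)],
    iterations_used = eng$iterations,
    converged = eng$converged,
    residual_history = eng$history
  )
}

# Core point-to-surface rigid registration loop. Each iteration evaluates a
# Kabsch (point-to-point) update and a linearized point-to-plane update and
# keeps whichever lowers the RMS point-to-surface residual more: the Kabsch
# optimum bounds the new residual by the current one, so the recorded
# residuals are monotonically non-increasing, while the point-to-plane step
# gives fast convergence near the optimum.
icp_engine <- function(X, tmesh, rot, tra, max_iterations, tolerance) {
  fn <- face_unit_normals(tmesh)
  history <- numeric()
  converged <- FALSE
  iters <- 0L

  query <- function(R, t) {
    moved <- X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE)
    cl <- cpp_closest_on_mesh(moved, tmesh$vertices, tmesh$faces)
    rms <- sqrt(mean(cl$dist^2))
    if (!is.finite(rms)) stop("non-finite ICP residual", call. = FALSE)
    list(moved = moved, cl = cl, rms = rms)
  }

  cur <- query(rot, tra)
  while (iters < max_iterations) {
    iters <- iters + 1L
    history <- c(history, cur$rms)

    # candidate 1 — Kabsch onto the closest points
    Y <- cur$cl$points
    mx <- colMeans(X)
    my <- colMeans(Y)
    H <- crossprod(sweep(X, 2, mx), sweep(Y, 2, my))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot1 <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tra1 <- my - as.numeric(rot1 %*% mx)
    cand1 <- query(rot1, tra1)

    # candidate 2 — linearized point-to-plane update
    n <- fn[cur$cl$face, , drop = FALSE]
    r <- rowSums((cur$moved - cur$cl$points) * n)
    cxn <- cbind(cur$moved[, 2] * n[, 3] - cur$moved[, 3] * n[, 2],
                 cur$moved[, 3] * n[, 1] - cur$moved[, 1] * n[, 3],
                 cur$moved[, 1] * n[, 2] - cur$moved[, 2] * n[, 1])
    A <- cbind(cxn, n)
    delta <- tryCatch(solve(crossprod(A), -crossprod(A, r)),
                      error = function(e) NULL)
    best <- cand1
    best_pose <- list(rot = rot1, tra = tra1)
    if (!is.null(delta)) {
      w <- delta[1:3]
      W <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3,
                  byrow = TRUE)
      inc <- orthonormalize_axes(diag(3) + W)
      rot2 <- inc %*% rot
      tra2 <- as.numeric(inc %*% tra) + delta[4:6]
      cand2 <- query(rot2, tra2)
      if (cand2$rms < best$rms) {
        best <- cand2
        best_pose <- list(rot = rot2, tra = tra2)
      }
    }
    improvement <- cur$rms - best$rms
    rot <- best_pose$rot
    tra <- best_pose$tra
    cur <- best
    if (improvement < tolerance) {
      converged <- TRUE
      history <- c(history, cur$rms)
      break
    }
  }
  if (iters == 0L || !converged) history <- c(history, cur$rms)
  list(rot = rot, tra = tra, history = history, iterations = iters,
       converged = converged)
}

#' Map an ACS between original and template-aligned space
#'
#' Axes are rotated and the origin rigidly mapped; the result is
#' re-orthonormalized to 1e-12 and right-handedness is preserved. For
#' mirrored transforms (right-side bones) the axes pass through the sagittal
#' reflection and the ML axis sign is then flipped so the reported frame stays
#' right-handed — the usual side-specific axis-sense convention.
#'
#' @param acs an [acs()] object.
#' @param transform the [rigid_transform()] from the bone's alignment.
#' @param direction `"to_aligned"` (original -> aligned) or `"to_original"`.
#' @return the mapped `acs` with its `space` field updated.
#' @export
map_acs_between_spaces <- function(acs, transform,
                                   direction = c("to_aligned", "to_original")) {
  direction <- match.arg(direction)
  M <- if (transform$mirrored) mirror_matrix else diag(3)
  R <- transform$rotation
  if (direction == "to_aligned") {
    if (acs$space != "original") {
      stop("ACS is already in '", acs$space, "' space", call. = FALSE)
    }
    origin <- apply_transform(transform, acs$origin)
    A <- R %*% M %*% cbind(acs$ML, acs$AP, acs$SI)
    if (transform$mirrored) A[, 1] <- -A[, 1]
    space <- "aligned"
  } else {
    if (acs$space != "aligned") {
      stop("ACS is already in '", acs$space, "' space", call. = FALSE)
    }
    origin <- apply_transform_inverse(transform, acs$origin)
    B <- cbind(acs$ML, acs$AP, acs$SI)
    if (transform$mirrored) B[, 1] <- -B[, 1]
    A <- M %*% t(R) %*% B
    space <- "original"
  }
  A <- orthonormalize_axes(A)
  acs(origin = as.numeric(origin), ML = A[, 1], AP = A[, 2], SI = A[, 3],
      space = space, bone_id = acs$bone_id, acs_variant = acs$acs_variant)
}

# Project a near-orthonormal right-handed 3x3 axis matrix onto the closest
# rotation (polar decomposition via SVD).
orthonormalize_axes <- function(A) {
  sv <- svd(A)
  Q <- sv$u %*% t(sv$v)
  if (det(Q) < 0) stop("axis set is left-handed; cannot orthonormalize",
                       call. = FALSE)
  Q
}
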