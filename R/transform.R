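# Rigid transforms mapping a bone's original ("scanner") space into the
# template-aligned space. A transform optionally records that a sagittal
# mirror (x -> -x) was applied before the rigid part, for right-side bones.

#' Construct a rigid transform
#'
#' Maps original-space points `p` to aligned-space points `R (M p) + t`, where
#' `M` is the sagittal mirror `diag(-1, 1, 1)` when `mirrored = TRUE` and the
#' identity otherwise.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation numeric 3-vector, millimetres.
#' @param mirrored was a sagittal mirror applied before the rigid part?
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            mirrored = FALSE) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as_point3(translation, "translation")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9) stop("rotation is not orthonormal (error ", format(err), ")",
                       call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (det +1); use `mirrored` for reflections",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation,
                 mirrored = isTRUE(mirrored)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(max(-1, min(1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform: rotation %.2f deg, |t| = %.2f mm%s>\n",
              ang, vnorm(x$translation), if (x$mirrored) ", mirrored" else ""))
  invisible(x)
}

mirror_matrix <- diag(c(-1, 1, 1))

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points an n x 3 matrix or a single 3-vector.
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else as.matrix(points)
  if (transform$mirrored) p[, 1] <- -p[, 1]
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (single) as.numeric(out) else out
}

# Inverse mapping of points from aligned space back to original space.
apply_transform_inverse <- function(transform, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else as.matrix(points)
  out <- (p - matrix(transform$translation, nrow(p), 3, byrow = TRUE)) %*%
    transform$rotation
  if (transform$mirrored) out[, 1] <- -out[, 1]
  if (single) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` applies `a` first, then `b`. Composition with a
#' mirrored transform is only supported when the later transform is proper.
#'
#' @param b,a `rigid_transform` objects.
#' @export
compose_transforms <- function(b, a) {
  if (b$mirrored) stop("cannot compose with a mirrored outer transform",
                       call. = FALSE)
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation,
                  mirrored = a$mirrored)
}

#' Invert a rigid transform
#'
#' Only proper (non-mirrored) transforms can be represented inverted; for
#' mirrored transforms use [apply_transform_inverse()] point mapping.
#'
#' @param transform a `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  if (transform$mirrored) {
    stop("mirrored transforms have no rigid_transform inverse; use apply_transform_inverse",
         call. = FALSE)
  }
  rigid_transform(t(transform$rotation),
                  as.numeric(-t(transform$rotation) %*% transform$translation))
}

# Apply a transform to a whole mesh (winding unchanged: rotation is proper,
# and the mirrored case flips winding which mirror_mesh() already corrected).
transform_mesh <- function(mesh, transform) {
  v <- apply_transform(transform, mesh$vertices)
  f <- mesh$faces
  if (transform$mirrored) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  triangle_mesh(v, f, name = mesh$name, validate = FALSE)
}
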