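# TriangleMesh container: the universal geometry carrier of the package.
# Vertices are an n x 3 numeric matrix in millimetres; faces an m x 3 integer
# matrix of 1-based vertex indices with consistent outward winding.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix with 3 columns (millimetres).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param name free-text label carried through the pipeline.
#' @param validate check mesh invariants (at least 4 vertices and faces,
#'   in-range indices, no degenerate faces, positive surface area).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, name = "", validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  m <- structure(list(vertices = vertices, faces = faces, name = as.character(name)),
                 class = "triangle_mesh")
  if (validate) validate_mesh(m)
  m
}

#' Validate triangle-mesh invariants
#'
#' @param mesh a `triangle_mesh`.
#' @return the mesh, invisibly; errors describe the violated invariant.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (any(!is.finite(v))) stop("mesh has non-finite vertex coordinates", call. = FALSE)
  if (nrow(v) < 4L) stop("mesh must have at least 4 vertices", call. = FALSE)
  if (nrow(f) < 4L) stop("mesh must have at least 4 faces", call. = FALSE)
  if (any(f < 1L) || any(f > nrow(v))) {
    stop("face indices out of range", call. = FALSE)
  }
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(degen)) {
    stop(sprintf("%d degenerate face(s) with repeated vertex indices", sum(degen)),
         call. = FALSE)
  }
  if (mesh_area(mesh) <= 0) stop("mesh surface area must be positive", call. = FALSE)
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces, area %.2f mm^2>\n",
              x$name, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `triangle_mesh`.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Area-weighted surface centroid of a mesh (mm)
#' @param mesh a `triangle_mesh`.
#' @export
mesh_centroid <- function(mesh) {
  w <- face_areas(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  tc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  as.numeric(colSums(tc * w) / sum(w))
}

#' Signed volume enclosed by a mesh (mm^3)
#'
#' Positive for a closed mesh with outward-facing winding; used to check that
#' mirroring preserves orientation.
#'
#' @param mesh a `triangle_mesh`.
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Area-weighted random surface samples
#'
#' Draws faces with probability proportional to area, then uniform barycentric
#' positions within each face. Uses the current RNG stream; wrap in a seeded
#' context for reproducibility.
#'
#' @param mesh a `triangle_mesh`.
#' @param n number of samples.
#' @return an `n` x 3 matrix of points on the surface.
#' @export
sample_mesh_surface <- function(mesh, n) {
  stopifnot(n >= 1)
  w <- face_areas(mesh)
  cw <- cumsum(w) / sum(w)
  fi <- findInterval(stats::runif(n), cw) + 1L
  fi[fi > length(w)] <- length(w)
  v <- mesh$vertices
  f <- mesh$faces
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  a <- 1 - r1
  b <- r1 * (1 - r2)
  cc <- r1 * r2
  a * v[f[fi, 1], , drop = FALSE] +
    b * v[f[fi, 2], , drop = FALSE] +
    cc * v[f[fi, 3], , drop = FALSE]
}

# Unit outward normals per face.
face_unit_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

# Area-weighted vertex normals (unnormalized face normals accumulated).
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  vn <- matrix(0, nrow(v), 3)
  idx <- c(f[, 1], f[, 2], f[, 3])
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  vn[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(vn^2))
  len[len < 1e-300] <- 1
  vn / len
}

# Merge duplicate vertices within `tol` (grid rounding); reindexes faces and
# drops faces that become degenerate.
merge_duplicate_vertices <- function(vertices, faces, tol = 1e-9) {
  key <- apply(round(vertices / tol) * tol, 1, paste, collapse = ",")
  first <- !duplicated(key)
  new_v <- vertices[first, , drop = FALSE]
  new_index <- match(key, key[first])
  new_f <- matrix(new_index[faces], ncol = 3)
  degen <- new_f[, 1] == new_f[, 2] | new_f[, 2] == new_f[, 3] | new_f[, 1] == new_f[, 3]
  list(vertices = new_v, faces = new_f[!degen, , drop = FALSE])
}

# Extent of a point set along one coordinate axis.
axis_extent <- function(points, axis_index) {
  diff(range(points[, axis_index]))
}
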