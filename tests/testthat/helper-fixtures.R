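# Shared fixtures: a regular tetrahedron, a cached synthetic template
# directory (generated once per test run), and small binary-format writers
# used to exercise the binary mesh dialects.

tetra_vertices <- matrix(c(
  0, 0, 0,
  1, 0, 0,
  0, 1, 0,
  0, 0, 1
), ncol = 3, byrow = TRUE)

# outward winding
tetra_faces <- matrix(c(
  1, 3, 2,
  1, 2, 4,
  1, 4, 3,
  2, 3, 4
), ncol = 3, byrow = TRUE)

tetra_mesh <- function() triangle_mesh(tetra_vertices, tetra_faces, name = "tetra")

.fixture_cache <- new.env(parent = emptyenv())

# synthetic template directory, generated once and reused by every test
template_fixture <- function() {
  if (is.null(.fixture_cache$templates)) {
    dir <- file.path(tempdir(), "footacs-templates")
    if (!dir.exists(dir)) generate_template_set(dir)
    .fixture_cache$templates <- load_template_set(dir)
  }
  .fixture_cache$templates
}

# Triangulated sphere for analytic checks. The grid is chosen so that the
# six axis directions are exact vertices: rays along the coordinate axes hit
# the analytic points to machine precision.
sphere_mesh <- function(r = 1, ctr = c(0, 0, 0)) {
  sph <- footacs:::uv_sphere(25L, 36L)
  triangle_mesh(sweep(sph$dirs * r, 2, ctr, "+"), sph$faces, name = "sphere")
}

# order-insensitive vertex comparison (writers may reorder on merge)
sort_rows <- function(m) {
  m <- round(unname(as.matrix(m)), 9)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

max_axis_error_deg <- function(acs_a, acs_b) {
  max(vapply(c("ML", "AP", "SI"), function(a) {
    angle_between_deg(acs_a[[a]], acs_b[[a]])
  }, 0))
}

# ground-truth axes mapped through a pose, as an acs in original space
posed_truth <- function(record) record$true_acs

write_binary_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    n <- footacs:::cross3(p2 - p1, p3 - p1)
    n <- n / max(1e-30, sqrt(sum(n^2)))
    writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
}

write_binary_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  header <- paste0(c(
    "ply", "format binary_little_endian 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header", ""), collapse = "\n")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
  }
}
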