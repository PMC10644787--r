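test_that("ASCII stl with one tetrahedron parses to 4 vertices and 4 faces", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, path)
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), 4L)
  expect_equal(nrow(back$faces), 4L)
  expect_equal(sort_rows(back$vertices), sort_rows(m$vertices), tolerance = 1e-12)
})

test_that("binary and ASCII stl dialects give identical geometry", {
  m <- tetra_mesh()
  pa <- withr::local_tempfile(fileext = ".stl")
  pb <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, pa)
  write_binary_stl(m, pb)
  a <- read_mesh(pa)
  b <- read_mesh(pb)
  expect_equal(sort_rows(a$vertices), sort_rows(b$vertices), tolerance = 1e-6)
  expect_equal(nrow(a$faces), nrow(b$faces))
})

test_that("binary little-endian ply matches its ASCII twin", {
  p <- synthetic_bone_params("cuboid", mesh_resolution = 1, seed = 3)
  m <- generate_bone(p)$mesh
  pa <- withr::local_tempfile(fileext = ".ply")
  pb <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, pa)
  write_binary_ply(m, pb)
  a <- read_mesh(pa)
  b <- read_mesh(pb)
  expect_equal(a$faces, b$faces)
  expect_equal(a$vertices, b$vertices, tolerance = 1e-6)
})

test_that("keyword-format shell mesh parses nodes, triangles and quads", {
  path <- withr::local_tempfile(fileext = ".k")
  writeLines(c(
    "*KEYWORD",
    "$ comment line",
    "*NODE",
    " 1, 0.0, 0.0, 0.0",
    " 2, 1.0, 0.0, 0.0",
    " 3, 0.0, 1.0, 0.0",
    " 4, 0.0, 0.0, 1.0",
    "*ELEMENT_SHELL",
    " 1, 1, 1, 3, 2, 2",
    " 2, 1, 1, 2, 4, 4",
    " 3, 1, 1, 4, 3, 3",
    " 4, 1, 2, 3, 4, 4",
    "*END"), path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
  expect_equal(sort_rows(m$vertices), sort_rows(tetra_vertices))

  # a quad shell (4th node distinct) splits along the 1-3 diagonal
  path2 <- withr::local_tempfile(fileext = ".k")
  writeLines(c(
    "*NODE",
    "1 0 0 0", "2 1 0 0", "3 1 1 0", "4 0 1 0", "5 0.5 0.5 1",
    "*ELEMENT_SHELL",
    "1 1 1 2 3 4",
    "2 1 1 2 5 5",
    "3 1 2 3 5 5",
    "4 1 3 4 5 5",
    "5 1 4 1 5 5"), path2)
  m2 <- read_mesh(path2)
  expect_equal(nrow(m2$faces), 6L) # 1 quad -> 2 triangles, plus 4 triangles
})

test_that("legacy and XML vtk polydata read back the same mesh", {
  m <- tetra_mesh()
  pa <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(m, pa)
  a <- read_mesh(pa)
  expect_equal(sort_rows(a$vertices), sort_rows(m$vertices), tolerance = 1e-12)

  pb <- withr::local_tempfile(fileext = ".vtp")
  v <- m$vertices
  f <- m$faces - 1L
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1">',
    '<PolyData>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfPolys="%d">', nrow(v), nrow(f)),
    '<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste(apply(v, 1, paste, collapse = " "), collapse = "\n"),
    '</DataArray></Points>',
    '<Polys><DataArray type="Int64" Name="connectivity" format="ascii">',
    paste(apply(f, 1, paste, collapse = " "), collapse = " "),
    '</DataArray><DataArray type="Int64" Name="offsets" format="ascii">',
    paste(seq_len(nrow(f)) * 3L, collapse = " "),
    '</DataArray></Polys>',
    '</Piece></PolyData></VTKFile>'), pb)
  b <- read_mesh(pb)
  expect_equal(sort_rows(b$vertices), sort_rows(m$vertices), tolerance = 1e-12)
  expect_equal(nrow(b$faces), 4L)
})

test_that("every write format round-trips fuzzed synthetic meshes within 1e-6 mm", {
  set.seed(99)
  for (i in 1:20) {
    bone <- sample(footacs:::BONES, 1)
    p <- synthetic_bone_params(bone, footacs:::variants_for_bone(bone)[1],
                               mesh_resolution = 1, seed = i)
    m <- generate_bone(p, pose = "random")$mesh
    for (fmt in c("stl", "ply", "vtk")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_mesh(m, path)
      back <- read_mesh(path)
      expect_equal(nrow(back$vertices), nrow(m$vertices))
      expect_lt(max(abs(sort_rows(back$vertices) - sort_rows(m$vertices))), 1e-6)
      expect_equal(mesh_area(back), mesh_area(m), tolerance = 1e-9)
    }
  }
})

test_that("unsupported or malformed mesh files are rejected, not partially read", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines("v 0 0 0", path)
  expect_error(read_mesh(path), "unsupported")

  empty <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "endsolid x"), empty)
  expect_error(read_mesh(empty), "vertices|geometry")

  degen <- withr::local_tempfile(fileext = ".k")
  writeLines(c("*NODE", "1 0 0 0", "2 1 0 0", "3 0 1 0",
               "*ELEMENT_SHELL", "1 1 1 2 3 3"), degen)
  expect_error(read_mesh(degen)) # fewer than 4 faces/vertices
})

test_that("particle files parse literally, tolerate blank lines, and round-trip", {
  path <- withr::local_tempfile(fileext = ".particles")
  writeLines(c("0 0 0", "1 2 3"), path)
  ps <- read_particles(path)
  expect_equal(nrow(ps$points), 2L)
  expect_equal(unname(ps$points[2, ]), c(1, 2, 3))

  path2 <- withr::local_tempfile(fileext = ".particles")
  writeLines(c("0 0 0", "1 2 3", ""), path2)
  expect_equal(read_particles(path2)$points, ps$points)

  pts <- matrix(rnorm(128 * 3), ncol = 3)
  path3 <- withr::local_tempfile(fileext = ".particles")
  write_particles(pts, path3)
  expect_equal(unname(read_particles(path3)$points), pts, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".particles")
  writeLines(c("0 0 0", "1 2"), bad)
  expect_error(read_particles(bad), "line 2")
})

test_that("ACS table rows carry both spaces at full precision", {
  identity_acs <- acs(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                      space = "aligned", bone_id = "talus",
                      acs_variant = "tibiotalar")
  orig <- identity_acs
  orig$space <- "original"
  path <- withr::local_tempfile(fileext = ".csv")
  write_acs_table(list(list(bone = "talus", acs_original = orig,
                            acs_aligned = identity_acs)), path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$ML_x, c(1, 1))
  expect_equal(tab$SI_z, c(1, 1))
  expect_equal(tab$origin_x, c(0, 0))

  # empty record list: header only
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_acs_table(list(), path2)
  expect_equal(nrow(utils::read.csv(path2)), 0L)
  expect_equal(length(readLines(path2)), 1L)

  # two bones -> 4 data rows
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_acs_table(list(
    list(bone = "a", acs_original = orig, acs_aligned = identity_acs),
    list(bone = "b", acs_original = orig, acs_aligned = identity_acs)), path3)
  expect_equal(nrow(utils::read.csv(path3)), 4L)

  # full precision survives a write/read cycle
  third <- acs(c(1 / 3, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               space = "aligned")
  path4 <- withr::local_tempfile(fileext = ".csv")
  write_acs_table(list(list(bone = "x", acs_aligned = third)), path4)
  expect_equal(utils::read.csv(path4)$origin_x, 1 / 3, tolerance = 1e-15)
})
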