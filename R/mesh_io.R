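# Readers and writers for the surface-mesh and point-set formats the toolbox
# touches: STL (ASCII + binary), PLY (ASCII + binary little-endian), VTK
# (legacy POLYDATA and XML PolyData/UnstructuredGrid, triangles only),
# LS-DYNA-style keyword shell meshes (.k), ShapeWorks-style .particles text
# files, and the CSV table of assigned coordinate systems.
#
# Coordinates are treated as millimetres throughout; no unit conversion.

SUPPORTED_READ_FORMATS <- c("stl", "ply", "vtk", "vtp", "vtu", "k")
SUPPORTED_WRITE_FORMATS <- c("stl", "ply", "vtk")

#' Read a triangle surface mesh
#'
#' Dispatches on the file extension (or `format_hint`). Duplicate vertices
#' within 1e-9 mm are merged, so STL soups come back as indexed meshes.
#'
#' @param path file path.
#' @param format_hint optional format name (`stl`, `ply`, `vtk`, `k`)
#'   overriding the extension.
#' @return a validated [triangle_mesh()].
#' @export
read_mesh <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- tolower(format_hint %||% tools::file_ext(path))
  if (!fmt %in% SUPPORTED_READ_FORMATS) {
    stop("unsupported mesh format '", fmt, "' for ", path,
         " (supported: ", paste(SUPPORTED_READ_FORMATS, collapse = ", "), ")",
         call. = FALSE)
  }
  raw <- switch(fmt,
    stl = read_stl(path),
    ply = read_ply(path),
    vtk = read_vtk(path),
    vtp = read_vtk_xml(path),
    vtu = read_vtk_xml(path),
    k = read_keyword_mesh(path)
  )
  if (nrow(raw$vertices) == 0 || nrow(raw$faces) == 0) {
    stop("no geometry found in ", path, call. = FALSE)
  }
  merged <- merge_duplicate_vertices(raw$vertices, raw$faces, tol = 1e-9)
  mesh <- tryCatch(
    triangle_mesh(merged$vertices, merged$faces,
                  name = tools::file_path_sans_ext(basename(path))),
    error = function(e) {
      stop("invalid geometry in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  mesh
}

#' Write a triangle surface mesh
#'
#' ASCII dialects are written for every format; geometry round-trips within
#' 1e-6 mm.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `stl`, `ply` or `vtk` (default: from the extension).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  validate_mesh(mesh)
  fmt <- tolower(format %||% tools::file_ext(path))
  if (!fmt %in% SUPPORTED_WRITE_FORMATS) {
    stop("unsupported write format '", fmt, "' (supported: ",
         paste(SUPPORTED_WRITE_FORMATS, collapse = ", "), ")", call. = FALSE)
  }
  switch(fmt,
    stl = write_stl(mesh, path),
    ply = write_ply(mesh, path),
    vtk = write_vtk(mesh, path)
  )
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

# --- STL ---------------------------------------------------------------

is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.double(ntri)
  # An ASCII file starting with "solid" can still be binary; trust the size.
  if (identical(expected, as.double(size))) return(TRUE)
  head_txt <- rawToChar(header[header != as.raw(0)])
  !grepl("^\\s*solid", head_txt)
}

read_stl <- function(path) {
  if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices found in ASCII stl ", path, call. = FALSE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v))) stop("malformed vertex line in ", path, call. = FALSE)
    v
  })
  verts <- do.call(rbind, nums)
  if (nrow(verts) %% 3 != 0) {
    stop("ASCII stl ", path, " has a vertex count not divisible by 3",
         call. = FALSE)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri < 1) {
    stop("binary stl ", path, " has no triangles (offset 80)", call. = FALSE)
  }
  rec <- readBin(con, "raw", 50 * ntri)
  if (length(rec) < 50 * ntri) {
    stop("binary stl ", path, " truncated at byte ",
         84 + length(rec), call. = FALSE)
  }
  m <- matrix(rec, nrow = 50)
  tri_raw <- as.raw(m[1:48, ])
  vals <- readBin(tri_raw, "numeric", n = 12 * ntri, size = 4,
                  endian = "little")
  vm <- matrix(vals, ncol = 12, byrow = TRUE) # normal + 3 vertices
  verts <- rbind(
    vm[, 4:6, drop = FALSE], vm[, 7:9, drop = FALSE], vm[, 10:12, drop = FALSE]
  )
  # interleave back to per-face order
  idx <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
  verts <- verts[idx, , drop = FALSE]
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  blocks <- sprintf(
    "facet normal %s %s %s\nouter loop\nvertex %s %s %s\nvertex %s %s %s\nvertex %s %s %s\nendloop\nendfacet",
    fmt_num(n[, 1]), fmt_num(n[, 2]), fmt_num(n[, 3]),
    fmt_num(p1[, 1]), fmt_num(p1[, 2]), fmt_num(p1[, 3]),
    fmt_num(p2[, 1]), fmt_num(p2[, 2]), fmt_num(p2[, 3]),
    fmt_num(p3[, 1]), fmt_num(p3[, 2]), fmt_num(p3[, 3]))
  writeLines(blocks, con)
  writeLines(sprintf("endsolid %s", mesh$name), con)
}

# --- PLY ---------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- read_line_binary(con)
    if (is.null(line)) stop("unexpected end of ply header in ", path, call. = FALSE)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 500) stop("ply header too long in ", path, call. = FALSE)
  }
  if (!grepl("^ply", header[1])) stop(path, " is not a ply file", call. = FALSE)
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]

  # parse element declarations in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("ply file ", path, " lacks vertex or face elements", call. = FALSE)
  }

  if (fmt == "ascii") {
    read_ply_ascii_body(con, elements, path)
  } else if (fmt %in% c("binary_little_endian", "binary_big_endian")) {
    read_ply_binary_body(con, elements, path,
                         endian = if (fmt == "binary_little_endian") "little" else "big")
  } else {
    stop("unsupported ply format '", fmt, "' in ", path, call. = FALSE)
  }
}

read_line_binary <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b)) return(if (length(out)) rawToChar(out) else NULL)
    if (b == as.raw(10)) return(rawToChar(out[out != as.raw(13)]))
    out <- c(out, b)
  }
}

read_ply_ascii_body <- function(con, elements, path) {
  txt <- readLines(con, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 0
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    rows <- txt[pos + seq_len(el$count)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      xi <- match(c("x", "y", "z"), pn)
      if (any(is.na(xi))) stop("ply vertex element lacks x/y/z in ", path, call. = FALSE)
      vals <- lapply(strsplit(trimws(rows), "\\s+"), function(tok) {
        as.numeric(tok[xi])
      })
      verts <- do.call(rbind, vals)
    } else if (el$name == "face") {
      fl <- lapply(strsplit(trimws(rows), "\\s+"), function(tok) {
        n <- as.integer(tok[1])
        idx <- as.integer(tok[1 + seq_len(n)]) + 1L
        if (n == 3) return(matrix(idx, 1))
        if (n == 4) return(rbind(idx[c(1, 2, 3)], idx[c(1, 3, 4)]))
        stop("ply face with ", n, " vertices unsupported in ", path, call. = FALSE)
      })
      faces <- do.call(rbind, fl)
    }
  }
  if (any(is.na(verts))) stop("malformed vertex data in ", path, call. = FALSE)
  list(vertices = verts, faces = faces)
}

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = "integer", size = 1, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4, signed = TRUE),
    float = , float32 = list(what = "numeric", size = 4, signed = TRUE),
    double = , float64 = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported ply type '", type, "'", call. = FALSE)
  )
}

read_ply_binary_body <- function(con, elements, path, endian) {
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    scalar <- all(!vapply(el$props, `[[`, TRUE, "list"))
    if (el$name == "vertex" && scalar) {
      infos <- lapply(el$props, function(p) ply_type_info(p$type))
      sizes <- vapply(infos, `[[`, 0, "size")
      same <- length(unique(vapply(infos, `[[`, "", "what"))) == 1 &&
        length(unique(sizes)) == 1
      pn <- vapply(el$props, `[[`, "", "name")
      xi <- match(c("x", "y", "z"), pn)
      if (any(is.na(xi))) stop("ply vertex element lacks x/y/z in ", path, call. = FALSE)
      if (same) {
        info <- infos[[1]]
        vals <- readBin(con, info$what, n = el$count * length(infos),
                        size = info$size, signed = info$signed, endian = endian)
        m <- matrix(vals, ncol = length(infos), byrow = TRUE)
        verts <- m[, xi, drop = FALSE]
      } else {
        verts <- matrix(NA_real_, el$count, 3)
        for (r in seq_len(el$count)) {
          row <- numeric(length(infos))
          for (j in seq_along(infos)) {
            row[j] <- readBin(con, infos[[j]]$what, 1, size = infos[[j]]$size,
                              signed = infos[[j]]$signed, endian = endian)
          }
          verts[r, ] <- row[xi]
        }
      }
    } else if (el$name == "face") {
      lp <- el$props[[1]]
      if (!lp$list) stop("ply face element must be a list property in ", path, call. = FALSE)
      cinfo <- ply_type_info(lp$count_type)
      iinfo <- ply_type_info(lp$type)
      fl <- vector("list", el$count)
      for (r in seq_len(el$count)) {
        n <- readBin(con, cinfo$what, 1, size = cinfo$size,
                     signed = cinfo$signed, endian = endian)
        idx <- readBin(con, iinfo$what, n, size = iinfo$size,
                       signed = iinfo$signed, endian = endian) + 1L
        fl[[r]] <- if (n == 3) matrix(idx, 1)
                   else if (n == 4) rbind(idx[c(1, 2, 3)], idx[c(1, 3, 4)])
                   else stop("ply face with ", n, " vertices unsupported in ",
                             path, call. = FALSE)
      }
      faces <- do.call(rbind, fl)
    } else {
      # skip unknown scalar elements
      infos <- lapply(el$props, function(p) {
        if (p$list) stop("unsupported list property in element '", el$name,
                         "' of ", path, call. = FALSE)
        ply_type_info(p$type)
      })
      nb <- sum(vapply(infos, `[[`, 0, "size")) * el$count
      readBin(con, "raw", nb)
    }
  }
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    "ply",
    "format ascii 1.0",
    sprintf("comment %s", mesh$name),
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%s %s %s", fmt_num(v[, 1]), fmt_num(v[, 2]),
                     fmt_num(v[, 3])), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

# --- VTK ---------------------------------------------------------------

read_vtk <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^\\s*<", first)) return(read_vtk_xml(path))
  read_vtk_legacy(path)
}

read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1])) {
    stop(path, " is not a legacy vtk file", call. = FALSE)
  }
  if (toupper(trimws(lines[3])) != "ASCII") {
    stop("only ASCII legacy vtk supported: ", path, call. = FALSE)
  }
  pts_i <- grep("^POINTS", lines)[1]
  if (is.na(pts_i)) stop("no POINTS section in ", path, call. = FALSE)
  npts <- as.integer(strsplit(trimws(lines[pts_i]), "\\s+")[[1]][2])
  # coordinates may wrap across lines
  coord_tok <- character()
  i <- pts_i + 1
  while (length(coord_tok) < 3 * npts && i <= length(lines)) {
    coord_tok <- c(coord_tok, strsplit(trimws(lines[i]), "\\s+")[[1]])
    i <- i + 1
  }
  verts <- matrix(as.numeric(coord_tok[seq_len(3 * npts)]), ncol = 3,
                  byrow = TRUE)

  poly_i <- grep("^(POLYGONS|CELLS)", lines)[1]
  if (is.na(poly_i)) stop("no POLYGONS/CELLS section in ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[poly_i]), "\\s+")[[1]]
  ncell <- as.integer(hdr[2])
  cell_tok <- character()
  i <- poly_i + 1
  while (i <= length(lines) && length(cell_tok) < as.integer(hdr[3])) {
    tl <- trimws(lines[i])
    if (grepl("^[A-Z]", tl)) break
    cell_tok <- c(cell_tok, strsplit(tl, "\\s+")[[1]])
    i <- i + 1
  }
  cell_vals <- as.integer(cell_tok)
  faces <- list()
  p <- 1
  for (cidx in seq_len(ncell)) {
    n <- cell_vals[p]
    idx <- cell_vals[p + seq_len(n)] + 1L
    p <- p + n + 1
    faces[[cidx]] <- if (n == 3) matrix(idx, 1)
                     else if (n == 4) rbind(idx[c(1, 2, 3)], idx[c(1, 3, 4)])
                     else stop("vtk cell with ", n,
                               " points unsupported in ", path, call. = FALSE)
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

read_vtk_xml <- function(path) {
  doc <- xml2::read_xml(path)
  root_name <- xml2::xml_name(doc)
  type <- xml2::xml_attr(doc, "type")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(root_name) || is.na(type) ||
      !type %in% c("PolyData", "UnstructuredGrid") ||
      inherits(piece, "xml_missing")) {
    stop("unsupported vtk xml structure in ", path,
         " (need ascii PolyData or UnstructuredGrid)", call. = FALSE)
  }
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  if (!identical(xml2::xml_attr(pts, "format"), "ascii")) {
    stop("only ascii-format vtk xml supported: ", path, call. = FALSE)
  }
  verts <- matrix(as.numeric(strsplit(trimws(xml2::xml_text(pts)),
                                      "\\s+")[[1]]), ncol = 3, byrow = TRUE)
  cont <- if (type == "PolyData") "Polys" else "Cells"
  conn <- xml2::xml_find_first(
    piece, sprintf(".//%s/DataArray[@Name='connectivity']", cont))
  offs <- xml2::xml_find_first(
    piece, sprintf(".//%s/DataArray[@Name='offsets']", cont))
  if (inherits(conn, "xml_missing") || inherits(offs, "xml_missing")) {
    stop("vtk xml file ", path, " lacks connectivity/offsets", call. = FALSE)
  }
  cv <- as.integer(strsplit(trimws(xml2::xml_text(conn)), "\\s+")[[1]]) + 1L
  ov <- as.integer(strsplit(trimws(xml2::xml_text(offs)), "\\s+")[[1]])
  starts <- c(0L, ov[-length(ov)])
  sizes <- ov - starts
  if (any(sizes != 3L)) {
    stop("vtk xml file ", path, " contains non-triangle cells", call. = FALSE)
  }
  faces <- matrix(cv, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    "# vtk DataFile Version 3.0",
    mesh$name,
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d double", nrow(v))
  ), con)
  writeLines(sprintf("%s %s %s", fmt_num(v[, 1]), fmt_num(v[, 2]),
                     fmt_num(v[, 3])), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

# --- keyword (.k) shell meshes -----------------------------------------

# Minimal keyword dialect: *NODE and *ELEMENT_SHELL cards, comma- or
# whitespace-separated; quads split along the 1-3 diagonal; '$' comment lines
# ignored; any other card skipped until the next '*'.
read_keyword_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*\\$", lines)]
  card <- ""
  node_id <- integer()
  node_xyz <- list()
  shells <- list()
  for (ln in lines) {
    tl <- trimws(ln)
    if (!nzchar(tl)) next
    if (startsWith(tl, "*")) {
      card <- toupper(tl)
      next
    }
    tok <- strsplit(tl, "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (startsWith(card, "*NODE")) {
      if (length(tok) < 4) stop("malformed *NODE line in ", path, ": ", tl,
                                call. = FALSE)
      node_id <- c(node_id, as.integer(tok[1]))
      node_xyz[[length(node_xyz) + 1]] <- as.numeric(tok[2:4])
    } else if (startsWith(card, "*ELEMENT_SHELL")) {
      if (length(tok) < 5) stop("malformed *ELEMENT_SHELL line in ", path,
                                ": ", tl, call. = FALSE)
      shells[[length(shells) + 1]] <- as.integer(tok[3:min(6, length(tok))])
    }
  }
  if (!length(node_id)) stop("no *NODE card found in ", path, call. = FALSE)
  if (!length(shells)) stop("no *ELEMENT_SHELL card found in ", path, call. = FALSE)
  verts <- do.call(rbind, node_xyz)
  faces <- list()
  for (s in shells) {
    idx <- match(s, node_id)
    if (any(is.na(idx[1:3]))) {
      stop("shell references unknown node in ", path, call. = FALSE)
    }
    quad <- length(s) >= 4 && !is.na(s[4]) && s[4] != 0L && s[4] != s[3]
    if (quad) {
      i4 <- match(s[4], node_id)
      faces[[length(faces) + 1]] <- rbind(idx[c(1, 2, 3)], c(idx[1], idx[3], i4))
    } else {
      faces[[length(faces) + 1]] <- matrix(idx[1:3], 1)
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

# --- particles ---------------------------------------------------------

#' Read a correspondence-particle file
#'
#' Plain text, one whitespace-separated `x y z` triple per line; blank lines
#' ignored. Particle order is meaningful: index k marks the same relative
#' anatomical location on every shape of a population.
#'
#' @param path file path.
#' @return a `particle_set`: list with `points` (n x 3 matrix) and
#'   `source_path`.
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  rows <- lapply(seq_along(lineno), function(i) {
    tok <- strsplit(trimws(lines[lineno[i]]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) != 3 || any(is.na(v))) {
      stop("malformed particle line ", lineno[i], " in ", path, call. = FALSE)
    }
    v
  })
  if (!length(rows)) stop("no particles in ", path, call. = FALSE)
  particle_set(do.call(rbind, rows), source_path = path)
}

#' Construct a particle set
#' @param points n x 3 matrix of particle coordinates (mm), in correspondence
#'   order.
#' @param source_path provenance label.
#' @export
particle_set <- function(points, source_path = "") {
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(points) < 1 || any(!is.finite(points))) {
    stop("particle set must contain at least one finite point", call. = FALSE)
  }
  structure(list(points = points, source_path = source_path),
            class = "particle_set")
}

#' Write a correspondence-particle file
#' @param particles a `particle_set` or n x 3 matrix.
#' @param path output path.
#' @export
write_particles <- function(particles, path) {
  pts <- if (inherits(particles, "particle_set")) particles$points
         else matrix(as.numeric(particles), ncol = 3)
  writeLines(sprintf("%s %s %s", fmt_num(pts[, 1]), fmt_num(pts[, 2]),
                     fmt_num(pts[, 3])), path)
  invisible(path)
}

# --- ACS table ---------------------------------------------------------

acs_table_columns <- c(
  "bone", "acs_variant", "space",
  "origin_x", "origin_y", "origin_z",
  "ML_x", "ML_y", "ML_z", "AP_x", "AP_y", "AP_z", "SI_x", "SI_y", "SI_z")

#' Write the spreadsheet of assigned coordinate systems
#'
#' One row per bone per space (original and template-aligned), carrying the
#' origin and the three unit axes at full float precision.
#'
#' @param records list of records, each a list with `bone`, and `acs_original`
#'   / `acs_aligned` [acs()] objects (either may be absent).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_acs_table <- function(records, path) {
  rows <- list()
  for (rec in records) {
    for (space in c("original", "aligned")) {
      a <- rec[[paste0("acs_", space)]]
      if (is.null(a)) next
      rows[[length(rows) + 1]] <- c(
        rec$bone, a$acs_variant %||% "default", space,
        fmt_num(a$origin), fmt_num(a$ML), fmt_num(a$AP), fmt_num(a$SI))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(acs_table_columns, collapse = ","), con)
  for (r in rows) writeLines(paste(r, collapse = ","), con)
  invisible(path)
}
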