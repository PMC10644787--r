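# Synthetic bone-like meshes with known ground-truth anatomical axes.
#
# Shapes are star-shaped radial surfaces: a superellipsoid base (elongated
# along the bone's primary anatomical axis) plus a few off-axis Gaussian
# bumps that break every mirror symmetry, so the anatomical frame is
# unambiguous for alignment. The canonical frame IS the ground truth:
# medial +x, anterior +y, superior +z, identity axes at the radial center.

# UV-sphere triangulation of the unit sphere: n_lat interior latitude rings,
# n_lon longitudes, two poles. Outward winding.
uv_sphere <- function(n_lat, n_lon) {
  theta <- pi * seq_len(n_lat) / (n_lat + 1)
  phi <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  ring <- function(th) cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                             rep(cos(th), n_lon))
  dirs <- rbind(c(0, 0, 1), do.call(rbind, lapply(theta, ring)), c(0, 0, -1))
  vid <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  north <- 1L
  south <- nrow(dirs)
  faces <- list()
  jj <- seq_len(n_lon)
  faces[[1]] <- cbind(north, vid(1L, jj), vid(1L, jj + 1L))
  for (i in seq_len(n_lat - 1L)) {
    u <- vid(i, jj); u1 <- vid(i, jj + 1L)
    l <- vid(i + 1L, jj); l1 <- vid(i + 1L, jj + 1L)
    faces[[length(faces) + 1]] <- cbind(u, l, l1)
    faces[[length(faces) + 1]] <- cbind(u, l1, u1)
  }
  faces[[length(faces) + 1]] <- cbind(south, vid(n_lat, jj + 1L), vid(n_lat, jj))
  list(dirs = dirs, faces = do.call(rbind, faces))
}

# radial distance of the parametric bone surface along unit directions
radial_radius <- function(params, dirs) {
  sa <- params$semi_axes
  p <- params$exponent
  base <- (abs(dirs[, 1] / sa[["ML"]])^p +
           abs(dirs[, 2] / sa[["AP"]])^p +
           abs(dirs[, 3] / sa[["SI"]])^p)^(-1 / p)
  r <- base
  for (bp in params$bumps) {
    d <- unitize(bp$dir)
    ang <- acos(pmax(-1, pmin(1, dirs %*% d)))
    r <- r + bp$amp * exp(-ang^2 / (2 * bp$width^2))
  }
  as.numeric(r)
}

#' Default synthetic-shape parameters for a bone / ACS-variant pair
#'
#' Semi-axes (mm) approximate adult bone dimensions, with the elongation
#' along each pair's primary anatomical axis; two Gaussian bumps (amplitudes
#' scaled to the smallest semi-axis) break all mirror symmetries.
#'
#' @param bone_id,acs_variant bone / variant pair.
#' @param noise_sd vertex noise SD in mm (default 0).
#' @param mesh_resolution resolution level; the surface grid is
#'   `6 x resolution` latitude rings by `12 x resolution` longitudes
#'   (default 3, about 1300 faces).
#' @param seed generator seed.
#' @return a `synthetic_bone_params` list.
#' @export
synthetic_bone_params <- function(bone_id, acs_variant = "default",
                                  noise_sd = 0, mesh_resolution = 3,
                                  seed = 0) {
  spec <- get_bone_spec(bone_id, acs_variant)
  sa <- switch(spec$template_id,
    "calcaneus/subtalar_calcaneus" = c(ML = 22, AP = 40, SI = 23),
    "calcaneus/calcaneocuboid" = c(ML = 21, AP = 41, SI = 22),
    "talus/talonavicular" = c(ML = 24, AP = 30, SI = 18),
    "talus/subtalar_talus" = c(ML = 23, AP = 29, SI = 17),
    "talus/tibiotalar" = c(ML = 30, AP = 24, SI = 18),
    "navicular/default" = c(ML = 22, AP = 12, SI = 14),
    "cuboid/default" = c(ML = 15, AP = 22, SI = 14),
    "medial_cuneiform/default" = c(ML = 10, AP = 15, SI = 12),
    "intermediate_cuneiform/default" = c(ML = 8, AP = 13, SI = 11),
    "lateral_cuneiform/default" = c(ML = 9, AP = 14, SI = 11),
    "metatarsal1/default" = c(ML = 10, AP = 30, SI = 11),
    "metatarsal2/default" = c(ML = 7, AP = 32, SI = 9),
    "metatarsal3/default" = c(ML = 7, AP = 30, SI = 9),
    "metatarsal4/default" = c(ML = 7, AP = 29, SI = 9),
    "metatarsal5/default" = c(ML = 8, AP = 28, SI = 9),
    "tibia/default" = c(ML = 15, AP = 13, SI = 42),
    "fibula/default" = c(ML = 8, AP = 10, SI = 42),
    stop("no shape parameters for ", spec$template_id, call. = FALSE)
  )
  # Three Gaussian bumps with distinct directions, amplitudes and widths.
  # No bump maps near another under any 180-degree axis flip, so every
  # proper sign assignment of the principal axes except the true one leaves
  # a clear registration residual; amplitudes stay small relative to the
  # semi-axes so the region centroids (hence the constructed axes) move
  # little.
  # Bumps sit near the equator of the superior axis: the extreme slabs that
  # anchor the axes (thin caps for 10-region bones) must keep near-centred
  # centroids, or the constructed frame would tilt away from the canonical
  # ground truth.
  amp <- min(sa)
  bumps <- list(
    list(dir = unitize(c(0.70, 0.71, 0.10)), amp = 0.14 * amp, width = 0.45),
    list(dir = unitize(c(-0.12, 0.42, -0.90)), amp = 0.07 * amp, width = 0.40),
    list(dir = unitize(c(-0.85, 0.25, 0.47)), amp = 0.05 * amp, width = 0.40)
  )
  # blockier bones get a higher superellipsoid exponent: their flat ends
  # keep the thin extreme slabs (1/10 of the extent for the calcaneus) well
  # populated, as the tuberosities and facets of the real bones do
  exponent <- if (bone_id == "calcaneus") 4 else
    if (bone_id %in% c("navicular", "cuboid")) 3 else 2.5
  structure(list(
    bone_id = bone_id, acs_variant = acs_variant,
    semi_axes = sa, exponent = exponent, bumps = bumps,
    noise_sd = noise_sd, mesh_resolution = as.integer(mesh_resolution),
    seed = as.integer(seed)
  ), class = "synthetic_bone_params")
}

canonical_bone_mesh <- function(params) {
  res <- params$mesh_resolution
  sph <- uv_sphere(6L * res, 12L * res)
  r <- radial_radius(params, sph$dirs)
  triangle_mesh(sph$dirs * r, sph$faces,
                name = paste(params$bone_id, params$acs_variant, sep = "_"))
}

#' Generate a synthetic bone with known ground-truth axes
#'
#' Builds the parametric surface in the canonical (template) frame, mirrors
#' it for right-side bones, applies the pose, then adds i.i.d. normal vertex
#' noise of `params$noise_sd`. The ground-truth ACS — identity axes at the
#' radial center — is carried along with the pose. Deterministic given
#' `params$seed`.
#'
#' @param params a [synthetic_bone_params()].
#' @param pose a [rigid_transform()], `"identity"`, or `"random"` (seeded
#'   uniform rotation with a translation up to 50 mm).
#' @param side `"left"` or `"right"`.
#' @return a `synthetic_bone` record: `mesh` (posed), `true_acs` (original
#'   space), `pose`, `side`, `params`.
#' @export
generate_bone <- function(params, pose = "identity", side = "left") {
  canon <- canonical_bone_mesh(params)
  if (identical(side, "right")) canon <- mirror_mesh(canon)

  if (identical(pose, "identity")) {
    pose <- rigid_transform()
  } else if (identical(pose, "random")) {
    pose <- with_seed(derive_seed(params$seed, 11), {
      rigid_transform(random_rotation(), stats::runif(3, -50, 50))
    })
  }
  stopifnot(inherits(pose, "rigid_transform"), !pose$mirrored)

  mesh <- transform_mesh(canon, pose)
  if (params$noise_sd > 0) {
    mesh$vertices <- mesh$vertices + with_seed(
      derive_seed(params$seed, 12),
      matrix(stats::rnorm(length(mesh$vertices), sd = params$noise_sd),
             ncol = 3))
  }

  axes <- pose$rotation # identity canonical axes mapped through the pose
  true_acs <- acs(origin = apply_transform(pose, c(0, 0, 0)),
                  ML = axes[, 1], AP = axes[, 2], SI = axes[, 3],
                  space = "original", bone_id = params$bone_id,
                  acs_variant = params$acs_variant)
  structure(list(mesh = mesh, true_acs = true_acs, pose = pose, side = side,
                 params = params),
            class = "synthetic_bone")
}

# crop a template mesh to the given fraction of its extent along an axis,
# keeping the low-coordinate (distal) end; emulates a limited field of view
crop_mesh_along_axis <- function(mesh, axis_index, keep_fraction) {
  coord <- mesh$vertices[, axis_index]
  cutoff <- min(coord) + keep_fraction * diff(range(coord))
  keep_vert <- coord <= cutoff
  keep_face <- keep_vert[mesh$faces[, 1]] & keep_vert[mesh$faces[, 2]] &
    keep_vert[mesh$faces[, 3]]
  sub <- mesh$faces[keep_face, , drop = FALSE]
  used <- sort(unique(as.vector(sub)))
  remap <- match(sub, used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap, ncol = 3),
                name = paste0(mesh$name, "_partial"))
}

#' Write a synthetic template directory
#'
#' One canonical-pose, noise-free template per bone / ACS-variant pair, in
#' the layout [load_template_set()] expects. Joint-specific variants carry
#' their own template geometry (each pre-oriented in its own joint frame);
#' tibias, fibulas and metatarsals also get a partial-length template (the
#' distal half of the full one).
#'
#' @param dir output directory (created if needed).
#' @param bone_ids bones to cover (default: all 14).
#' @param mesh_resolution resolution level passed to the shape generator.
#' @param seed generator seed (templates are deterministic; the seed only
#'   namespaces the template ids).
#' @return `dir`, invisibly.
#' @export
generate_template_set <- function(dir, bone_ids = BONES, mesh_resolution = 3,
                                  seed = 0) {
  for (b in bone_ids) {
    for (v in variants_for_bone(b)) {
      spec <- get_bone_spec(b, v)
      params <- synthetic_bone_params(b, v, noise_sd = 0,
                                      mesh_resolution = mesh_resolution,
                                      seed = seed)
      mesh <- canonical_bone_mesh(params)
      out <- file.path(dir, b, v)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_mesh(mesh, file.path(out, "full.ply"))
      ai <- axis_to_index(spec$primary_region_axis)
      if (b %in% PARTIAL_BONES) {
        partial <- crop_mesh_along_axis(mesh, ai, 0.5)
        write_mesh(partial, file.path(out, "partial.ply"))
      }
      jsonlite::write_json(
        list(template_id = sprintf("synthetic-%s-%s-seed%d", b, v, seed),
             extent_along_primary = axis_extent(mesh$vertices, ai)),
        file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' Emulate a second segmentation of the same bone
#'
#' Remeshes the surface to about `remesh_factor` times the original face
#' count (radial recasting from the bone center onto the existing surface)
#' and adds surface-normal noise of `noise_sd`. The ground-truth ACS is
#' unchanged: the twin represents the same bone segmented again.
#'
#' @param record a `synthetic_bone` from [generate_bone()].
#' @param noise_sd surface-normal noise SD in mm.
#' @param remesh_factor target face count as a fraction of the original.
#' @param seed RNG seed for the noise.
#' @return a new `synthetic_bone` record.
#' @export
perturb_segmentation <- function(record, noise_sd = 0.2, remesh_factor = 1,
                                 seed = 0) {
  stopifnot(inherits(record, "synthetic_bone"))
  old_faces <- nrow(record$mesh$faces)
  target <- max(144, round(remesh_factor * old_faces))
  n_lat <- max(4L, as.integer(round(sqrt(target / 4))))
  n_lon <- 2L * n_lat
  sph <- uv_sphere(n_lat, n_lon)
  dirs <- sph$dirs
  faces <- sph$faces
  if (identical(record$side, "right")) {
    dirs[, 1] <- -dirs[, 1]
    faces <- faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  # cast rays from the posed bone center along the posed directions
  center <- apply_transform(record$pose, c(0, 0, 0))
  dirs_world <- dirs %*% t(record$pose$rotation)
  hit <- cpp_ray_mesh(matrix(center, nrow(dirs), 3, byrow = TRUE), dirs_world,
                      record$mesh$vertices, record$mesh$faces, 1e-9)
  if (any(is.na(hit$t))) {
    stop("remesh ray missed the surface; record mesh is not star-shaped",
         call. = FALSE)
  }
  mesh <- triangle_mesh(hit$points, faces, name = record$mesh$name)
  if (noise_sd > 0) {
    vn <- vertex_normals(mesh)
    mesh$vertices <- mesh$vertices + with_seed(
      seed, stats::rnorm(nrow(vn), sd = noise_sd)) * vn
  }
  out <- record
  out$mesh <- mesh
  out
}

# particles at fixed parametric surface locations (Fibonacci directions in
# the canonical frame): index k is the same relative location on every shape
particles_for_params <- function(params, pose = rigid_transform(),
                                 n_particles = 128) {
  dirs <- fibonacci_directions(n_particles)
  r <- radial_radius(params, dirs)
  particle_set(apply_transform(pose, dirs * r),
               source_path = sprintf("synthetic:%s/%s", params$bone_id,
                                     params$acs_variant))
}

offset_bumps <- function(params, offsets) {
  for (i in seq_along(params$bumps)) {
    params$bumps[[i]]$amp <- max(0, params$bumps[[i]]$amp + offsets[i])
  }
  params
}

#' Generate a synthetic population with group and overall mean shapes
#'
#' Group mean shapes differ from the overall mean by seeded bump-amplitude
#' offsets of magnitude `group_effect_scale` (mm); individuals jitter around
#' their group mean (1.5% semi-axis scatter, 0.3 mm bump scatter, random
#' pose). Correspondence particles sit at fixed parametric surface locations,
#' identical across all shapes, so index k is in true correspondence.
#'
#' @param bone_id,acs_variant bone / variant pair.
#' @param n_groups number of population groups.
#' @param n_per_group individuals per group (at least 2).
#' @param group_effect_scale SD of the group bump-amplitude offsets, mm; 0
#'   makes every group mean identical to the overall mean.
#' @param seed generator seed.
#' @param n_particles correspondence particles per shape (default 128).
#' @param mesh_resolution resolution level.
#' @return list with `overall` (record + particles) and `groups` (each:
#'   `label`, `mean` record, `mean_particles`, `individuals` list of records).
#' @export
generate_population <- function(bone_id, acs_variant = "default",
                                n_groups = 3, n_per_group = 8,
                                group_effect_scale = 0.5, seed = 0,
                                n_particles = 128, mesh_resolution = 3) {
  stopifnot(n_per_group >= 2)
  base <- synthetic_bone_params(bone_id, acs_variant, noise_sd = 0,
                                mesh_resolution = mesh_resolution, seed = seed)
  overall <- generate_bone(base, pose = "identity")
  overall_particles <- particles_for_params(base, n_particles = n_particles)

  groups <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    gseed <- derive_seed(seed, 100 + g)
    offs <- with_seed(gseed, stats::rnorm(length(base$bumps))) *
      group_effect_scale
    gparams <- offset_bumps(base, offs)
    gparams$seed <- gseed
    gmean <- generate_bone(gparams, pose = "identity")
    individuals <- vector("list", n_per_group)
    for (k in seq_len(n_per_group)) {
      iseed <- derive_seed(seed, 1000 + g * 100 + k)
      ip <- gparams
      ip$seed <- iseed
      jit <- with_seed(iseed, list(sa = stats::rnorm(3, sd = 0.015),
                                   amp = stats::rnorm(length(ip$bumps), sd = 0.3)))
      ip$semi_axes <- ip$semi_axes * (1 + pmax(-0.1, pmin(0.1, jit$sa)))
      ip <- offset_bumps(ip, jit$amp)
      individuals[[k]] <- generate_bone(ip, pose = "random")
    }
    groups[[g]] <- list(
      label = paste0("group", g),
      mean = gmean,
      mean_particles = particles_for_params(gparams, n_particles = n_particles),
      individuals = individuals
    )
  }
  list(overall = list(mean = overall, particles = overall_particles),
       groups = groups)
}
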