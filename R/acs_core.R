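# Construction of the anatomical coordinate system from the template-aligned
# bone: equal-width volumetric slab regions along each anatomical plane,
# region centroids of area-weighted surface samples, a primary axis through
# the extreme-slab centroids, a secondary axis through a designated "third
# point", and the tertiary axis by cross product.

#' Construct an anatomical coordinate system object
#'
#' @param origin 3-vector, millimetres.
#' @param ML,AP,SI unit axes (medial, anterior, superior positive).
#' @param space `"original"` or `"aligned"`.
#' @param bone_id,acs_variant provenance labels.
#' @param validate check orthonormality and right-handedness (1e-9).
#' @return an object of class `acs`.
#' @export
acs <- function(origin, ML, AP, SI, space = c("aligned", "original"),
                bone_id = NA_character_, acs_variant = NA_character_,
                validate = TRUE) {
  space <- match.arg(space)
  out <- structure(list(
    origin = as_point3(origin, "origin"),
    ML = as_point3(ML, "ML"), AP = as_point3(AP, "AP"), SI = as_point3(SI, "SI"),
    space = space, bone_id = bone_id, acs_variant = acs_variant
  ), class = "acs")
  if (validate) validate_acs(out)
  out
}

#' Validate ACS invariants
#'
#' Unit axes within 1e-9, pairwise orthogonal within 1e-9, and right-handed
#' (`ML x AP = SI`).
#'
#' @param x an [acs()].
#' @export
validate_acs <- function(x) {
  for (axn in c("ML", "AP", "SI")) {
    if (abs(vnorm(x[[axn]]) - 1) > 1e-9) {
      stop(axn, " axis is not unit length", call. = FALSE)
    }
  }
  if (abs(sum(x$ML * x$AP)) > 1e-9 || abs(sum(x$ML * x$SI)) > 1e-9 ||
      abs(sum(x$AP * x$SI)) > 1e-9) {
    stop("ACS axes are not pairwise orthogonal", call. = FALSE)
  }
  if (max(abs(cross3(x$ML, x$AP) - x$SI)) > 1e-9) {
    stop("ACS is not right-handed (ML x AP != SI)", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.acs <- function(x, ...) {
  cat(sprintf("<acs %s/%s in %s space>\n", x$bone_id, x$acs_variant, x$space))
  cat(sprintf("  origin: %8.3f %8.3f %8.3f\n", x$origin[1], x$origin[2], x$origin[3]))
  for (axn in c("ML", "AP", "SI")) {
    a <- x[[axn]]
    cat(sprintf("  %s:     %8.4f %8.4f %8.4f\n", axn, a[1], a[2], a[3]))
  }
  invisible(x)
}

#' Partition surface samples into equal-width slabs along an anatomical axis
#'
#' Slab boundaries are equally spaced across the sample extent along the
#' axis; slabs are half-open `[b_i, b_{i+1})` except the last, which is
#' closed. Empty slabs signal pathological cropping and raise an error.
#'
#' @param samples n x 3 matrix of surface points in aligned space.
#' @param axis `"ML"` (x), `"AP"` (y) or `"SI"` (z).
#' @param n_regions number of slabs (1, 3, 5 or 10).
#' @return a `region_partition`: `axis`, `n_regions`, `boundaries`
#'   (`n_regions + 1` ascending coordinates), `region_centroids`
#'   (`n_regions` x 3), `region_counts`.
#' @export
partition_regions <- function(samples, axis = c("ML", "AP", "SI"), n_regions) {
  axis <- match.arg(axis)
  samples <- as.matrix(samples)
  n_regions <- as.integer(n_regions)
  ai <- axis_to_index(axis)
  coord <- samples[, ai]
  if (nrow(samples) < n_regions) {
    stop("fewer samples (", nrow(samples), ") than regions (", n_regions, ")",
         call. = FALSE)
  }
  if (length(unique(coord)) < n_regions) {
    stop("fewer than ", n_regions, " distinct coordinates along ", axis,
         call. = FALSE)
  }
  boundaries <- seq(min(coord), max(coord), length.out = n_regions + 1L)
  idx <- findInterval(coord, boundaries, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_regions] <- n_regions
  counts <- tabulate(idx, n_regions)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L)
    kind <- if (any(empty %in% c(1L, n_regions))) "extreme" else "interior"
    stop("empty ", kind, " slab along ", axis, " (region ",
         paste(empty, collapse = ", "), "); geometry looks degenerate or cropped",
         call. = FALSE)
  }
  centroids <- rowsum(samples, idx) / counts
  structure(list(axis = axis, n_regions = n_regions, boundaries = boundaries,
                 region_centroids = unname(centroids), region_counts = counts),
            class = "region_partition")
}

#' Primary axis from the extreme-slab centroids
#'
#' The unit vector from the low-coordinate extreme-slab centroid to the
#' high-coordinate one, so it points toward +x (medial), +y (anterior) or +z
#' (superior) in template space, depending on the bone's primary plane.
#'
#' @param partition a `region_partition` along the bone's primary axis.
#' @return list with `axis` (unit 3-vector) and `anchors` (2 x 3 matrix: low
#'   and high extreme-slab centroids).
#' @export
compute_primary_axis <- function(partition) {
  lo <- partition$region_centroids[1, ]
  hi <- partition$region_centroids[partition$n_regions, ]
  if (vnorm(hi - lo) < 1e-6) {
    stop("extreme-slab centroids coincide; primary axis undefined", call. = FALSE)
  }
  list(axis = unitize(hi - lo), anchors = rbind(lo, hi))
}

#' Third point: centroid of the designated extreme slab
#'
#' The tibia and fibula use the most lateral region (lowest x, since medial
#' is +x in template space); all other bones use the most superior region
#' (highest z).
#'
#' @param partition a `region_partition` along SI (superior rule) or ML
#'   (lateral rule).
#' @param spec the `bone_spec`.
#' @return 3-vector centroid of the designated slab.
#' @export
compute_third_point <- function(partition, spec) {
  if (spec$third_point_region == "superior") {
    if (partition$axis != "SI") {
      stop("superior third point needs an SI partition", call. = FALSE)
    }
    partition$region_centroids[partition$n_regions, ]
  } else {
    if (partition$axis != "ML") {
      stop("lateral third point needs an ML partition", call. = FALSE)
    }
    partition$region_centroids[1, ]
  }
}

#' Secondary axis: orthogonal from the primary line toward the third point
#'
#' The third point is projected orthogonally onto the primary line; the
#' secondary axis is the unit vector from that projection toward the third
#' point, exactly orthogonal to the primary axis by construction.
#'
#' @param primary unit 3-vector.
#' @param anchor any point on the primary line.
#' @param third_point 3-vector off the primary line (perpendicular distance
#'   at least 1e-6 mm).
#' @return unit 3-vector.
#' @export
compute_secondary_axis <- function(primary, anchor, third_point) {
  primary <- unitize(as_point3(primary, "primary"))
  anchor <- as_point3(anchor, "anchor")
  third_point <- as_point3(third_point, "third_point")
  w <- third_point - anchor
  perp <- w - sum(w * primary) * primary
  if (vnorm(perp) < 1e-6) {
    stop("third point lies on the primary axis; secondary axis undefined",
         call. = FALSE)
  }
  sec <- unitize(perp)
  # remove residual rounding so the dot product is < 1e-12 exactly
  unitize(sec - sum(sec * primary) * primary)
}

#' Assemble the labeled ACS from primary and secondary axes
#'
#' The tertiary axis is the cross product of primary and secondary; the three
#' axes are relabeled to ML/AP/SI through the bone's `axis_role_map`, the ML
#' and AP signs corrected toward +x and +y of the aligned template frame, and
#' SI recomputed as `ML x AP` to enforce right-handedness. A downward SI
#' indicates catastrophic misalignment and errors.
#'
#' @param primary,secondary orthogonal unit 3-vectors.
#' @param spec the `bone_spec`.
#' @param origin ACS origin in aligned space.
#' @return an [acs()] in aligned space.
#' @export
assemble_acs <- function(primary, secondary, spec, origin = c(0, 0, 0)) {
  primary <- unitize(as_point3(primary, "primary"))
  secondary <- unitize(as_point3(secondary, "secondary"))
  if (abs(sum(primary * secondary)) > 1e-9) {
    stop("primary and secondary axes must be orthogonal", call. = FALSE)
  }
  tertiary <- unitize(cross3(primary, secondary))
  roles <- spec$axis_role_map
  axes <- list()
  axes[[roles[["primary"]]]] <- primary
  axes[[roles[["secondary"]]]] <- secondary
  axes[[roles[["tertiary"]]]] <- tertiary
  ML <- axes$ML; AP <- axes$AP; SI <- axes$SI
  # sign convention: medial +x, anterior +y in the aligned template frame
  if (ML[1] < 0) ML <- -ML
  if (AP[2] < 0) AP <- -AP
  SI <- unitize(cross3(ML, AP))
  if (SI[3] <= 0) {
    stop("assembled SI axis points inferior; alignment or laterality is wrong",
         call. = FALSE)
  }
  acs(origin = origin, ML = ML, AP = AP, SI = SI, space = "aligned",
      bone_id = spec$bone_id, acs_variant = spec$acs_variant)
}

#' Place the ACS origin
#'
#' `bone_center`: area-weighted surface centroid of the aligned mesh.
#' `joint_surface`: first intersection of the ray from the bone center along
#' the bone's joint direction (expressed in ACS coordinates and mapped
#' through the assembled axes) with the mesh surface.
#'
#' @param mesh aligned-space `triangle_mesh`.
#' @param spec the `bone_spec`.
#' @param acs_axes an [acs()] giving the axis directions (aligned space).
#' @param mode `"bone_center"` or `"joint_surface"`.
#' @return 3-vector origin, millimetres.
#' @export
place_origin <- function(mesh, spec, acs_axes,
                         mode = c("bone_center", "joint_surface")) {
  mode <- match.arg(mode)
  if (!mode %in% spec$origin_modes) {
    stop("origin mode '", mode, "' not available for ", spec$template_id,
         call. = FALSE)
  }
  center <- mesh_centroid(mesh)
  if (mode == "bone_center") return(center)
  jd <- spec$joint_direction
  dir <- jd[["ML"]] * acs_axes$ML + jd[["AP"]] * acs_axes$AP +
    jd[["SI"]] * acs_axes$SI
  hit <- cpp_ray_mesh(matrix(center, 1), matrix(unitize(dir), 1),
                      mesh$vertices, mesh$faces, 1e-9)
  if (is.na(hit$t[1])) {
    stop("joint-surface ray missed the mesh; bone appears open or cropped",
         call. = FALSE)
  }
  as.numeric(hit$points[1, ])
}

#' Assign an anatomical coordinate system to a bone mesh
#'
#' End-to-end orchestration: mirror right-side bones to left, provisional
#' principal-axes alignment, template selection (partial-length templates for
#' cropped tibias/fibulas/metatarsals), ICP refinement, area-weighted surface
#' sampling, slab partitioning per the bone's rules, primary / third-point /
#' secondary / tertiary axis construction, origin placement, and mapping of
#' the result back to the bone's original space. Deterministic given `seed`.
#'
#' @param mesh the bone `triangle_mesh` in its original (scanner) space.
#' @param bone_id,acs_variant bone / variant pair (see [get_bone_spec()]).
#' @param templates a `template_set` from [load_template_set()].
#' @param side `"left"` or `"right"` (rights are mirrored to left).
#' @param origin_mode `"bone_center"` or `"joint_surface"`.
#' @param seed RNG seed driving every sampling step.
#' @param n_surface_samples samples for region centroids (default 20000).
#' @param icp_sample_count samples for ICP (default 2000).
#' @param max_iterations,tolerance ICP controls (see [icp_align()]).
#' @return list with `acs_aligned`, `acs_original`, `alignment` (the
#'   [icp_align()] result), `template` (the selected `bone_template`),
#'   `partitions`, and `warnings`.
#' @export
assign_acs <- function(mesh, bone_id, acs_variant = "default", templates,
                       side = "left", origin_mode = "bone_center", seed = 0,
                       n_surface_samples = 20000, icp_sample_count = 2000,
                       max_iterations = 100, tolerance = 1e-4) {
  spec <- get_bone_spec(bone_id, acs_variant)
  warnings <- character()

  work <- mesh
  mirrored <- identical(side, "right")
  if (mirrored) work <- mirror_mesh(work)

  ctx <- function(e) {
    stop(sprintf("[%s/%s '%s'] %s", bone_id, acs_variant, mesh$name,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    tpl <- select_template(templates, bone_id, acs_variant)
    init <- initial_alignment(work, tpl, n_samples = icp_sample_count,
                              seed = derive_seed(seed, 1))
    if (!init$confident) {
      warnings <- c(warnings, "principal axes nearly degenerate; centroid-only initialization")
    }

    # partial-length handling for cropped long bones
    if (bone_id %in% PARTIAL_BONES) {
      prov <- apply_transform(init$transform,
                              with_seed(derive_seed(seed, 2),
                                        sample_mesh_surface(work, 1000)))
      ratio <- axis_extent(prov, axis_to_index(spec$primary_region_axis)) /
        tpl$extent_along_primary
      tpl <- select_template(templates, bone_id, acs_variant, ratio)
      warnings <- c(warnings, tpl$warnings)
      if (tpl$partial_variant == "partial") {
        init <- initial_alignment(work, tpl, n_samples = icp_sample_count,
                                  seed = derive_seed(seed, 1))
      }
    }

    align <- icp_align(work, tpl, initial = init$transform,
                       max_iterations = max_iterations, tolerance = tolerance,
                       sample_count = icp_sample_count,
                       seed = derive_seed(seed, 3))
    transform <- align$transform
    if (mirrored) {
      transform <- rigid_transform(transform$rotation, transform$translation,
                                   mirrored = TRUE)
    }

    aligned_mesh <- transform_mesh(work, align$transform)
    samples <- with_seed(derive_seed(seed, 4),
                         sample_mesh_surface(aligned_mesh, n_surface_samples))

    n <- spec$regions_per_plane
    partitions <- list(
      ML = partition_regions(samples, "ML", n),
      AP = partition_regions(samples, "AP", n),
      SI = partition_regions(samples, "SI", n)
    )
    prim <- compute_primary_axis(partitions[[spec$primary_region_axis]])
    anchor <- colMeans(prim$anchors)
    third_axis <- if (spec$third_point_region == "superior") "SI" else "ML"
    third <- compute_third_point(partitions[[third_axis]], spec)
    secondary <- compute_secondary_axis(prim$axis, anchor, third)
    frame <- assemble_acs(prim$axis, secondary, spec, origin = c(0, 0, 0))
    origin <- place_origin(aligned_mesh, spec, frame, origin_mode)
    acs_aligned <- acs(origin, frame$ML, frame$AP, frame$SI, space = "aligned",
                       bone_id = bone_id, acs_variant = acs_variant)
    acs_original <- map_acs_between_spaces(acs_aligned, transform, "to_original")

    list(acs_aligned = acs_aligned, acs_original = acs_original,
         alignment = align, template = tpl, partitions = partitions,
         warnings = warnings)
  }, error = ctx)
}
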