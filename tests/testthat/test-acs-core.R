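# Hand-computed slab-membership oracle used to cross-check partition_regions.
slab_oracle <- function(samples, axis_index, n) {
  coord <- samples[, axis_index]
  b <- seq(min(coord), max(coord), length.out = n + 1)
  idx <- vapply(coord, function(x) {
    for (k in seq_len(n)) {
      hi_ok <- if (k == n) x <= b[k + 1] else x < b[k + 1]
      if (x >= b[k] && hi_ok) return(k)
    }
    NA_integer_
  }, 1L)
  list(boundaries = b,
       centroids = t(vapply(seq_len(n), function(k) {
         colMeans(samples[idx == k, , drop = FALSE])
       }, numeric(3))),
       counts = tabulate(idx, n))
}

test_that("slab partitioning matches the hand oracle on collinear points", {
  pts <- cbind(0:9, 0, 0)
  part <- partition_regions(pts, "ML", 3)
  expect_equal(part$boundaries, c(0, 3, 6, 9))
  # [0,3): {0,1,2}; [6,9]: {6,7,8,9}
  expect_equal(part$region_centroids[1, 1], 1.0)
  expect_equal(part$region_centroids[3, 1], 7.5)
  expect_equal(part$region_counts, c(3L, 3L, 4L))
})

test_that("slab partitioning agrees with the oracle on random clouds", {
  set.seed(7)
  for (i in 1:10) {
    pts <- matrix(runif(300, -10, 10), ncol = 3)
    n <- sample(c(3L, 5L, 10L), 1)
    axis <- sample(c("ML", "AP", "SI"), 1)
    part <- partition_regions(pts, axis, n)
    oracle <- slab_oracle(pts, match(axis, c("ML", "AP", "SI")), n)
    expect_equal(part$boundaries, oracle$boundaries)
    expect_equal(part$region_counts, oracle$counts)
    expect_equal(part$region_centroids, unname(oracle$centroids),
                 tolerance = 1e-12)
    expect_equal(sum(part$region_counts), nrow(pts))
  }
})

test_that("degenerate partitions error instead of returning partial geometry", {
  # single region: centroid is the global mean
  pts <- matrix(runif(60), ncol = 3)
  part <- partition_regions(pts, "AP", 1)
  expect_equal(part$region_centroids[1, ], colMeans(pts), tolerance = 1e-12)

  # symmetric points: extreme-slab centroids mirror in x
  pts <- cbind(c(-9, -8, -7, 7, 8, 9, 0.5, -0.5), 1:8, 0)
  part <- partition_regions(pts, "ML", 3)
  expect_equal(part$region_centroids[1, 1], -part$region_centroids[3, 1])

  # empty interior slab
  gap <- cbind(c(0, 0.1, 0.2, 9.8, 9.9, 10), 0, 0)
  expect_error(partition_regions(gap, "ML", 3), "interior")
  expect_error(partition_regions(matrix(runif(6), 2), "ML", 3), "fewer")
})

test_that("the primary axis runs from the low to the high extreme centroid", {
  part <- list(region_centroids = rbind(c(0, 0, 0), c(5, 5, 5), c(10, 0, 0)),
               n_regions = 3L, axis = "ML")
  class(part) <- "region_partition"
  prim <- compute_primary_axis(part)
  expect_equal(prim$axis, c(1, 0, 0))

  part$region_centroids <- rbind(c(0, -40, 5), c(0, 0, 0), c(0, 40, -5))
  prim <- compute_primary_axis(part)
  expect_equal(prim$axis, c(0, 80, -10) / sqrt(80^2 + 100), tolerance = 1e-12)

  part$region_centroids <- rbind(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0))
  expect_error(compute_primary_axis(part), "coincide")
})

test_that("the third point picks the designated extreme slab", {
  spec_sup <- get_bone_spec("calcaneus", "calcaneocuboid")
  part <- partition_regions(cbind(0, 0, c(2, 3, 10, 17, 18)), "SI", 3)
  expect_equal(compute_third_point(part, spec_sup)[3], 17.5)

  spec_lat <- get_bone_spec("tibia")
  pts <- cbind(seq(-10, 10, length.out = 21), 0, 0)
  part <- partition_regions(pts, "ML", 3)
  # most lateral = lowest-x slab [-10, -10 + 20/3)
  members <- pts[pts[, 1] < -10 + 20 / 3, 1]
  expect_equal(compute_third_point(part, spec_lat)[1], mean(members))
  expect_error(compute_third_point(part, spec_sup), "SI partition")
})

test_that("the secondary axis is the orthogonal direction toward the third point", {
  expect_equal(compute_secondary_axis(c(1, 0, 0), c(0, 0, 0), c(5, 0, 7)),
               c(0, 0, 1))
  expect_equal(compute_secondary_axis(c(0, 1, 0), c(0, 0, 0), c(3, 12, 4)),
               c(0.6, 0, 0.8), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:100) {
    primary <- footacs:::unitize(rnorm(3))
    anchor <- rnorm(3, sd = 10)
    third <- rnorm(3, sd = 10)
    skip <- abs(sum((third - anchor) * primary) - sqrt(sum((third - anchor)^2)))
    if (skip < 1e-6) next
    sec <- compute_secondary_axis(primary, anchor, third)
    expect_lt(abs(sum(sec * primary)), 1e-12)
    expect_equal(sqrt(sum(sec^2)), 1, tolerance = 1e-12)
  }
  expect_error(compute_secondary_axis(c(1, 0, 0), c(0, 0, 0), c(5, 0, 0)),
               "primary axis")
})

test_that("assembly relabels, sign-corrects and enforces right-handedness", {
  spec <- get_bone_spec("cuboid") # AP primary, SI secondary, ML tertiary
  a <- assemble_acs(c(0, 1, 0), c(0, 0, 1), spec)
  expect_equal(a$ML, c(1, 0, 0))
  expect_equal(a$AP, c(0, 1, 0))
  expect_equal(a$SI, c(0, 0, 1))
  expect_equal(det(cbind(a$ML, a$AP, a$SI)), 1, tolerance = 1e-12)

  # sign-flipped primary input is corrected
  b <- assemble_acs(c(0, -1, 0), c(0, 0, 1), spec)
  expect_equal(b$AP, c(0, 1, 0))
  expect_equal(det(cbind(b$ML, b$AP, b$SI)), 1, tolerance = 1e-12)

  # a downward secondary is absorbed by the sign-correction rules, and the
  # rebuilt frame still points superior
  cc <- assemble_acs(c(0, 1, 0), c(0, 0, -1), spec)
  expect_equal(cc$SI, c(0, 0, 1))

  # random valid inputs always satisfy the frame invariants
  set.seed(23)
  specs <- all_bone_specs()
  for (i in 1:50) {
    spec_i <- specs[[sample(length(specs), 1)]]
    # a mildly perturbed canonical frame, as alignment would produce
    rot <- footacs:::orthonormalize_axes(diag(3) + matrix(rnorm(9, sd = 0.1), 3))
    primary <- rot[, footacs:::axis_to_index(spec_i$primary_region_axis)]
    sec_lab <- spec_i$axis_role_map[["secondary"]]
    secondary <- rot[, footacs:::axis_to_index(sec_lab)]
    out <- assemble_acs(primary, secondary, spec_i)
    expect_s3_class(out, "acs") # constructor validates all invariants
  }

})

test_that("origins land at the bone center or on the joint surface", {
  spec <- get_bone_spec("cuboid")
  frame <- acs(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               bone_id = "cuboid", acs_variant = "default")

  sph <- sphere_mesh(r = 1)
  expect_lt(max(abs(place_origin(sph, spec, frame, "bone_center"))), 1e-6)
  # cuboid joint direction is anterior: ray hits (0, 1, 0) exactly (the
  # fixture has vertices on the coordinate axes)
  expect_equal(place_origin(sph, spec, frame, "joint_surface"), c(0, 1, 0),
               tolerance = 1e-6)

  sph2 <- sphere_mesh(r = 10, ctr = c(2, 0, 0))
  spec_tt <- get_bone_spec("talus", "tibiotalar") # joint direction superior
  expect_equal(place_origin(sph2, spec_tt, frame, "joint_surface"),
               c(2, 0, 10), tolerance = 1e-6)

  expect_error(place_origin(sph, spec, frame, "sideways"))
})

test_that("end-to-end assignment recovers ground truth and maps spaces back", {
  tpl <- template_fixture()
  p <- synthetic_bone_params("metatarsal4", seed = 31)
  rec <- generate_bone(p, pose = "random")
  res <- assign_acs(rec$mesh, "metatarsal4", "default", tpl, seed = 8)
  validate_acs(res$acs_aligned)
  validate_acs(res$acs_original)
  expect_lt(max_axis_error_deg(res$acs_original, rec$true_acs), 5)

  # aligned and original frames are the same frame expressed in two spaces
  back <- map_acs_between_spaces(res$acs_aligned, res$alignment$transform,
                                 "to_original")
  expect_lt(max_axis_error_deg(back, res$acs_original), 1e-9)

  # errors carry bone and file context
  expect_error(assign_acs(rec$mesh, "navicular", "tibiotalar", tpl),
               "navicular")
})

test_that("axis directions are invariant to uniform scaling of bone and template", {
  p <- synthetic_bone_params("cuboid", seed = 17)
  rec <- generate_bone(p, pose = "identity")
  tpl <- template_fixture()
  res1 <- assign_acs(rec$mesh, "cuboid", "default", tpl, seed = 4)

  scaled_templates <- tpl
  entry <- scaled_templates[["cuboid/default"]]
  entry$full$vertices <- entry$full$vertices * 2
  entry$extent_along_primary <- entry$extent_along_primary * 2
  scaled_templates[["cuboid/default"]] <- entry
  class(scaled_templates) <- "template_set"
  scaled_mesh <- rec$mesh
  scaled_mesh$vertices <- scaled_mesh$vertices * 2
  res2 <- assign_acs(scaled_mesh, "cuboid", "default", scaled_templates, seed = 4)
  expect_lt(max_axis_error_deg(res1$acs_aligned, res2$acs_aligned), 1e-6)
})
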