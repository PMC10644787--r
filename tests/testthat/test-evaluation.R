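make_acs <- function(R = diag(3), origin = c(0, 0, 0), space = "aligned") {
  acs(origin, R[, 1], R[, 2], R[, 3], space = space)
}

test_that("per-axis angle differences follow rotation geometry", {
  a <- make_acs()
  expect_equal(unlist(angle_difference(a, a)[1:3]),
               c(theta_ML = 0, theta_AP = 0, theta_SI = 0))

  # a 10-degree rotation about SI moves ML and AP by 10, SI by 0
  b <- make_acs(footacs:::axis_rotation("z", 10))
  d <- angle_difference(a, b)
  expect_equal(d$theta_ML, 10, tolerance = 1e-9)
  expect_equal(d$theta_AP, 10, tolerance = 1e-9)
  expect_equal(d$theta_SI, 0, tolerance = 1e-6)

  # orthogonal axes read 90; flipped axes read ~180 (direction-sensitive)
  cc <- make_acs(footacs:::axis_rotation("z", 90))
  expect_equal(angle_difference(a, cc)$theta_ML, 90)
  dd <- make_acs(footacs:::axis_rotation("z", 180))
  expect_equal(angle_difference(a, dd)$theta_ML, 180, tolerance = 1e-6)

  # symmetric in its arguments, invariant to a common rotation
  set.seed(5)
  for (i in 1:20) {
    r1 <- footacs:::random_rotation()
    r2 <- footacs:::random_rotation()
    q <- footacs:::random_rotation()
    x <- make_acs(r1); y <- make_acs(r2)
    d1 <- angle_difference(x, y)
    d2 <- angle_difference(y, x)
    expect_equal(unlist(d1[1:3]), unlist(d2[1:3]), tolerance = 1e-9)
    d3 <- angle_difference(make_acs(q %*% r1), make_acs(q %*% r2))
    expect_equal(unlist(d1[1:3]), unlist(d3[1:3]), tolerance = 1e-6)
  }

  orig <- make_acs(space = "original")
  expect_error(angle_difference(a, orig), "different spaces")
})

test_that("axis projections hit the analytic sphere points", {
  a <- make_acs()
  sph <- sphere_mesh(r = 10)
  pts <- project_axis_to_surface(a, sph)
  expect_equal(unname(pts["ML", ]), c(10, 0, 0), tolerance = 1e-6)
  expect_equal(unname(pts["AP", ]), c(0, 10, 0), tolerance = 1e-6)
  expect_equal(unname(pts["SI", ]), c(0, 0, 10), tolerance = 1e-6)

  off <- make_acs(origin = c(5, 0, 0))
  expect_equal(unname(project_axis_to_surface(off, sph)["ML", ]),
               c(10, 0, 0), tolerance = 1e-6)

  # projected points lie on the surface of an arbitrary synthetic bone
  p <- synthetic_bone_params("talus", "subtalar_talus", seed = 2)
  bone <- generate_bone(p)$mesh
  frame <- make_acs(origin = mesh_centroid(bone))
  pts <- project_axis_to_surface(frame, bone)
  d <- footacs:::cpp_closest_on_mesh(pts, bone$vertices, bone$faces)$dist
  expect_lt(max(d), 1e-6)
})

test_that("nearest-particle search matches a brute-force scan", {
  ps <- particle_set(rbind(c(1, 0, 0), c(0, 2, 0)))
  hit <- nearest_particle(c(0, 0, 0), ps)
  expect_equal(hit$index, 1L)
  expect_equal(hit$distance, 1)

  expect_equal(nearest_particle(c(0, 2, 0), ps)$distance, 0)

  set.seed(31)
  pts <- matrix(rnorm(3000), ncol = 3)
  ps <- particle_set(pts)
  for (i in 1:20) {
    q <- rnorm(3)
    d <- sqrt(colSums((t(pts) - q)^2)) # brute force oracle
    hit <- nearest_particle(q, ps)
    expect_equal(hit$index, which.min(d))
    expect_equal(hit$distance, min(d), tolerance = 1e-12)
  }

  # ties resolve to the lowest index
  tie <- particle_set(rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(nearest_particle(c(0, 0, 0), tie)$index, 1L)
})

test_that("correspondence distances reduce to self-distance and are rigid-invariant", {
  p <- synthetic_bone_params("navicular", seed = 8)
  rec <- generate_bone(p)
  particles <- footacs:::particles_for_params(p, n_particles = 64)
  frame <- make_acs(origin = c(0, 0, 0), space = "original")
  frame$bone_id <- "navicular"
  ref <- list(acs = frame, mesh = rec$mesh, particles = particles)

  self <- correspondence_distance(ref, ref)
  for (i in 1:3) {
    np <- nearest_particle(project_axis_to_surface(frame, rec$mesh)[i, ],
                           particles)
    expect_equal(self$d[i], np$distance) # exactly, same arithmetic path
    expect_equal(self$particle_index[i], np$index)
  }

  # translating mesh + particles + frame together leaves d unchanged
  shift <- c(4, -7, 11)
  mesh2 <- rec$mesh
  mesh2$vertices <- sweep(mesh2$vertices, 2, shift, "+")
  parts2 <- particle_set(sweep(particles$points, 2, shift, "+"))
  frame2 <- frame
  frame2$origin <- frame$origin + shift
  tgt <- list(acs = frame2, mesh = mesh2, particles = parts2)
  moved <- correspondence_distance(ref, tgt)
  expect_equal(moved$d, self$d, tolerance = 1e-9)

  expect_error(
    correspondence_distance(ref, list(acs = frame, mesh = rec$mesh,
                                      particles = particle_set(rbind(c(0, 0, 0))))),
    "correspondence")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), cc = c(3, 4, 5))
  # oracle: group means 2,3,4; grand 3; SSB = 3*(1+0+1) = 6 (df 2);
  # SSW = 2+2+2 = 6 (df 6); F = (6/2)/(6/6) = 3
  res <- one_way_anova(groups)
  expect_equal(res$F, 3)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE))

  # zero between-group variance
  same <- list(a = c(1, 5, 3), b = c(1, 5, 3))
  expect_equal(one_way_anova(same)$F, 0)

  # location invariance
  shifted <- lapply(groups, function(g) g + 17.3)
  expect_equal(one_way_anova(shifted)$F, res$F, tolerance = 1e-12)

  expect_error(one_way_anova(list(a = 1:3)), "at least 2 groups")
  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
})

test_that("Tukey HSD reduces to the pooled t statistic for two groups", {
  set.seed(61)
  a <- rnorm(8); b <- rnorm(8, mean = 1)
  tk <- tukey_hsd(list(a = a, b = b))
  tt <- stats::t.test(b, a, var.equal = TRUE)
  expect_equal(tk$q, sqrt(2) * abs(unname(tt$statistic)), tolerance = 1e-9)
  expect_equal(tk$mean_diff, mean(b) - mean(a), tolerance = 1e-12)

  # identical groups: nothing significant, zero differences
  g <- rnorm(6)
  tk0 <- tukey_hsd(list(a = g, b = g, cc = g))
  expect_true(all(!tk0$significant))
  expect_true(all(abs(tk0$mean_diff) < 1e-12))

  # one far-shifted group (>= 10 pooled SDs, n = 8) flags all its pairs
  set.seed(62)
  base <- list(a = rnorm(8), b = rnorm(8), cc = rnorm(8) + 12)
  tk1 <- tukey_hsd(base)
  involved <- grepl("cc", tk1$pair)
  expect_true(all(tk1$significant[involved]))
  expect_true(all(!tk1$significant[!involved]))
  # the significance calls agree with the adjusted p values
  expect_equal(tk1$significant, tk1$p_adj < 0.05)
})

test_that("group summaries use sample SD and pool per-observation", {
  df <- data.frame(bone = rep(c("x", "y"), each = 4),
                   group = rep(c("g1", "g2"), 4),
                   value = c(1, 3, 2, 2, 5, 5, 1, 3))
  s <- summarize_by_group(df)
  one <- s$long[s$long$bone == "x" & s$long$group == "g1", ]
  expect_equal(one$mean, mean(c(1, 2)))
  expect_equal(one$sd, stats::sd(c(1, 2))) # n-1 denominator

  pooled <- s$long[s$long$bone == "Mean" & s$long$group == "g1", ]
  expect_equal(pooled$mean, mean(df$value[df$group == "g1"]))
  expect_equal(pooled$n, 4)

  single <- summarize_by_group(data.frame(bone = "x", group = "g", value = 7))
  expect_equal(single$long$mean, c(7, 7))
  expect_equal(single$long$sd, c(0, 0))

  # wide table: one row per bone plus the pooled Mean row
  expect_equal(s$wide$bone, c("x", "y", "Mean"))
  expect_equal(ncol(s$wide), 3L)
})
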