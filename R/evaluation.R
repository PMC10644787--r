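# Comparison analyses between assigned coordinate systems: per-axis angle
# differences, correspondence-particle projection distances, and one-way
# ANOVA with Tukey's post hoc across population groups.

#' Per-axis angle difference between two coordinate systems
#'
#' Both systems must live in the same space (comparisons are made in the
#' shared template-aligned frame). The angle per labeled axis is
#' `acos(u . v)` in degrees, direction-sensitive: a flipped axis reads as
#' roughly 180 degrees, a genuine failure signal.
#'
#' @param acs_a,acs_b [acs()] objects in the same space.
#' @return list with `theta_ML`, `theta_AP`, `theta_SI` (degrees in
#'   \[0, 180\]), `bone_id` and `pair`.
#' @export
angle_difference <- function(acs_a, acs_b) {
  if (!identical(acs_a$space, acs_b$space)) {
    stop("ACSs live in different spaces ('", acs_a$space, "' vs '",
         acs_b$space, "'); map them to a common frame first", call. = FALSE)
  }
  list(
    theta_ML = angle_between_deg(acs_a$ML, acs_b$ML),
    theta_AP = angle_between_deg(acs_a$AP, acs_b$AP),
    theta_SI = angle_between_deg(acs_a$SI, acs_b$SI),
    bone_id = acs_a$bone_id,
    pair = paste(acs_a$bone_id, acs_b$bone_id, sep = " vs ")
  )
}

#' Project the ACS axes to the bone surface
#'
#' For each of ML/AP/SI, the nearest ray-surface intersection from the origin
#' along the positive axis direction.
#'
#' @param acs an [acs()].
#' @param mesh a `triangle_mesh` in the same space, enclosing the origin.
#' @return 3 x 3 matrix with rows ML, AP, SI: the surface points.
#' @export
project_axis_to_surface <- function(acs, mesh) {
  dirs <- rbind(acs$ML, acs$AP, acs$SI)
  origins <- matrix(acs$origin, 3, 3, byrow = TRUE)
  hit <- cpp_ray_mesh(origins, dirs, mesh$vertices, mesh$faces, 1e-9)
  if (any(is.na(hit$t))) {
    miss <- c("ML", "AP", "SI")[is.na(hit$t)]
    stop("axis ray(s) ", paste(miss, collapse = ", "),
         " missed the surface; mesh looks open or cropped", call. = FALSE)
  }
  out <- hit$points
  rownames(out) <- c("ML", "AP", "SI")
  out
}

#' Nearest correspondence particle to a point
#'
#' Exhaustive Euclidean nearest neighbour; ties resolve to the lowest index.
#'
#' @param point 3-vector.
#' @param particles a `particle_set`.
#' @return list with `index` and `distance` (mm).
#' @export
nearest_particle <- function(point, particles) {
  if (!inherits(particles, "particle_set")) {
    stop("`particles` must be a particle_set", call. = FALSE)
  }
  p <- as_point3(point)
  d2 <- rowSums(sweep(particles$points, 2, p)^2)
  i <- which.min(d2) # which.min takes the first (lowest-index) minimum
  list(index = i, distance = sqrt(d2[i]))
}

#' Correspondence-particle projection distances between mean shapes
#'
#' On the reference shape (the overall mean) each axis is projected to the
#' surface and the nearest correspondence particle recorded. On the target
#' shape (a group mean) the same axis is projected and the distance to the
#' particle with that SAME index is reported — the particle marks the same
#' relative anatomical location on both shapes.
#'
#' @param reference,target lists with components `acs`, `mesh`, `particles`;
#'   both particle sets must have equal counts and both pairs must share a
#'   space.
#' @return data frame with one row per axis: `axis`, `particle_index`, `d`
#'   (mm), projected and particle point coordinates.
#' @export
correspondence_distance <- function(reference, target) {
  nref <- nrow(reference$particles$points)
  ntgt <- nrow(target$particles$points)
  if (nref != ntgt) {
    stop("particle counts differ (", nref, " vs ", ntgt,
         "); sets are not in correspondence", call. = FALSE)
  }
  ref_proj <- project_axis_to_surface(reference$acs, reference$mesh)
  tgt_proj <- project_axis_to_surface(target$acs, target$mesh)
  rows <- lapply(c("ML", "AP", "SI"), function(axn) {
    np <- nearest_particle(ref_proj[axn, ], reference$particles)
    tp <- target$particles$points[np$index, ]
    pp <- tgt_proj[axn, ]
    data.frame(axis = axn, particle_index = np$index,
               d = vnorm(pp - tp),
               proj_x = pp[1], proj_y = pp[2], proj_z = pp[3],
               part_x = tp[1], part_y = tp[2], part_z = tp[3])
  })
  do.call(rbind, rows)
}

check_anova_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  values <- unlist(groups)
  if (stats::var(values) == 0) {
    stop("all observations identical; ANOVA is degenerate", call. = FALSE)
  }
  if (all(vapply(groups, stats::var, 0) == 0)) {
    stop("zero within-group variance in every group; ANOVA is degenerate",
         call. = FALSE)
  }
  invisible(groups)
}

stack_groups <- function(groups) {
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- labels
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)),
                   levels = names(groups))
  )
}

#' Classical one-way ANOVA
#'
#' Equal-variance F test, `F = (SSB/df_b) / (SSW/df_w)`, with the p value
#' from the F distribution.
#'
#' @param groups named list of numeric vectors (one per population group),
#'   each with at least 2 observations.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  check_anova_groups(groups)
  df <- stack_groups(groups)
  fit <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  list(F = unname(fit$statistic),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]),
       p = unname(fit$p.value))
}

#' Tukey's honestly-significant-difference post hoc
#'
#' Studentized-range test on all group pairs with pooled within-group
#' variance; the `q` statistic is compared with the critical value
#' `qtukey(1 - alpha, k, df_within)`.
#'
#' @param groups named list of numeric vectors (as for [one_way_anova()]).
#' @param alpha significance level (default 0.05).
#' @return data frame with one row per pair: `pair`, `mean_diff`, `q`,
#'   `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  check_anova_groups(groups)
  df <- stack_groups(groups)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  msw <- sum(stats::residuals(fit)^2) / fit$df.residual
  ns <- vapply(groups, length, 0L)
  labels <- rownames(tk)
  parts <- strsplit(labels, "-", fixed = TRUE)
  q <- vapply(seq_along(labels), function(i) {
    gi <- parts[[i]][1]; gj <- parts[[i]][2]
    se <- sqrt(msw / 2 * (1 / ns[[gi]] + 1 / ns[[gj]]))
    abs(tk[i, "diff"]) / se
  }, 0)
  crit <- stats::qtukey(1 - alpha, nmeans = length(groups), df = fit$df.residual)
  data.frame(
    pair = labels,
    mean_diff = unname(tk[, "diff"]),
    q = unname(q),
    p_adj = unname(tk[, "p adj"]),
    significant = unname(q > crit)
  )
}

#' Per-bone / per-group mean and SD summary table
#'
#' Sample SD (n - 1 denominator) throughout. Returns the long summary plus a
#' wide character table shaped like the usual per-bone results tables (one
#' row per bone plus a pooled `Mean` row; one `mean +/- sd` column per
#' group).
#'
#' @param results data frame with columns `bone`, `group`, `value`.
#' @return list with `long` (bone, group, n, mean, sd) and `wide`.
#' @export
summarize_by_group <- function(results) {
  stopifnot(all(c("bone", "group", "value") %in% names(results)),
            nrow(results) > 0)
  agg <- function(df) {
    data.frame(n = nrow(df), mean = mean(df$value),
               sd = if (nrow(df) > 1) stats::sd(df$value) else 0)
  }
  keys <- unique(results[, c("bone", "group")])
  long <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$bone == keys$bone[i] & results$group == keys$group[i], ]
    cbind(keys[i, , drop = FALSE], agg(sub))
  }))
  # pooled per-group rows across bones
  pooled <- do.call(rbind, lapply(unique(results$group), function(g) {
    sub <- results[results$group == g, ]
    cbind(data.frame(bone = "Mean", group = g), agg(sub))
  }))
  long <- rbind(long, pooled)
  rownames(long) <- NULL

  bones <- c(unique(as.character(results$bone)), "Mean")
  gshow <- unique(as.character(results$group))
  wide <- data.frame(bone = bones, stringsAsFactors = FALSE)
  for (g in gshow) {
    col <- vapply(bones, function(b) {
      row <- long[long$bone == b & long$group == g, ]
      if (!nrow(row)) return(NA_character_)
      sprintf("%.2f ± %.2f", row$mean[1], row$sd[1])
    }, "")
    wide[[g]] <- col
  }
  list(long = long, wide = wide)
}
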