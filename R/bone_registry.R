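# Per-bone construction rules and template management.
#
# Each of the 14 foot and ankle bones carries one or more ACS variants
# (joint-specific coordinate systems); every (bone, variant) pair has fixed
# rules: how many equal-width regions per anatomical plane, which template
# axis the primary axis runs along, where the "third point" lives, and which
# anatomical labels the primary/secondary/tertiary axes receive.

BONES <- c("tibia", "fibula", "talus", "calcaneus", "navicular", "cuboid",
           "medial_cuneiform", "intermediate_cuneiform", "lateral_cuneiform",
           paste0("metatarsal", 1:5))

ACS_VARIANTS <- c("default", "talonavicular", "tibiotalar", "subtalar_talus",
                  "subtalar_calcaneus", "calcaneocuboid")

# variants admitted per bone: talus and calcaneus are joint-specific, the rest
# carry a single default ACS
variants_for_bone <- function(bone_id) {
  switch(bone_id,
    talus = c("talonavicular", "tibiotalar", "subtalar_talus"),
    calcaneus = c("subtalar_calcaneus", "calcaneocuboid"),
    "default"
  )
}

# bones whose field of view is often cropped and that therefore carry a
# partial-length template variant
PARTIAL_BONES <- c("tibia", "fibula", paste0("metatarsal", 1:5))

regions_for_bone <- function(bone_id) {
  if (bone_id == "calcaneus") return(10L)
  if (bone_id %in% c("navicular", "cuboid")) return(5L)
  3L
}

primary_axis_for <- function(bone_id, acs_variant) {
  if (bone_id %in% c("tibia", "fibula")) return("SI")
  if (bone_id == "navicular") return("ML")
  if (bone_id == "talus" && acs_variant == "tibiotalar") return("ML")
  "AP"
}

third_point_region_for <- function(bone_id) {
  if (bone_id %in% c("tibia", "fibula")) "lateral" else "superior"
}

# direction (in ACS coordinates ML/AP/SI) from the bone center toward the
# articulating joint surface, used by the joint_surface origin mode
joint_direction_for <- function(bone_id, acs_variant) {
  switch(acs_variant,
    talonavicular = c(ML = 0, AP = 1, SI = 0),
    tibiotalar = c(ML = 0, AP = 0, SI = 1),
    subtalar_talus = c(ML = 0, AP = 0, SI = -1),
    subtalar_calcaneus = c(ML = 0, AP = 0, SI = 1),
    calcaneocuboid = c(ML = 0, AP = 1, SI = 0),
    # default-variant bones: distal articulation
    switch(bone_id,
      tibia = c(ML = 0, AP = 0, SI = -1),
      fibula = c(ML = 0, AP = 0, SI = -1),
      c(ML = 0, AP = 1, SI = 0)
    )
  )
}

#' Construction rules for one bone / ACS-variant pair
#'
#' @param bone_id one of the 14 bone identifiers (see [all_bone_specs()]).
#' @param acs_variant `"default"` for most bones; the talus admits
#'   `"talonavicular"`, `"tibiotalar"` and `"subtalar_talus"`, the calcaneus
#'   `"subtalar_calcaneus"` and `"calcaneocuboid"`.
#' @return a `bone_spec` list: `regions_per_plane` (3, 5 or 10),
#'   `primary_region_axis` (`ML`, `AP` or `SI`), `third_point_region`
#'   (`superior` or `lateral`), `axis_role_map` (anatomical labels of the
#'   primary/secondary/tertiary axes), `origin_modes`, `joint_direction`
#'   and `template_id`.
#' @export
get_bone_spec <- function(bone_id, acs_variant = "default") {
  if (!bone_id %in% BONES) {
    stop("unknown bone_id '", bone_id, "'; valid bones: ",
         paste(BONES, collapse = ", "), call. = FALSE)
  }
  ok <- variants_for_bone(bone_id)
  if (!acs_variant %in% ok) {
    stop("bone '", bone_id, "' does not admit ACS variant '", acs_variant,
         "'; valid variants: ", paste(ok, collapse = ", "), call. = FALSE)
  }
  primary <- primary_axis_for(bone_id, acs_variant)
  third <- third_point_region_for(bone_id)
  secondary <- if (third == "superior") "SI" else "ML"
  tertiary <- setdiff(c("ML", "AP", "SI"), c(primary, secondary))
  spec <- structure(list(
    bone_id = bone_id,
    acs_variant = acs_variant,
    regions_per_plane = regions_for_bone(bone_id),
    primary_region_axis = primary,
    third_point_region = third,
    axis_role_map = c(primary = primary, secondary = secondary,
                      tertiary = tertiary),
    origin_modes = c("bone_center", "joint_surface"),
    joint_direction = joint_direction_for(bone_id, acs_variant),
    template_id = paste(bone_id, acs_variant, sep = "/")
  ), class = "bone_spec")
  validate_bone_spec(spec)
  spec
}

validate_bone_spec <- function(spec) {
  stopifnot(spec$regions_per_plane %in% c(3L, 5L, 10L))
  roles <- spec$axis_role_map
  if (!setequal(roles, c("ML", "AP", "SI")) ||
      roles[["primary"]] != spec$primary_region_axis) {
    stop("axis_role_map must be a bijection onto ML/AP/SI with primary = ",
         spec$primary_region_axis, call. = FALSE)
  }
  if (!spec$third_point_region %in% c("superior", "lateral")) {
    stop("invalid third_point_region", call. = FALSE)
  }
  invisible(spec)
}

#' Enumerate every bone / ACS-variant pair
#'
#' @return a list of 17 `bone_spec` objects: two calcaneus variants, three
#'   talus variants, the five other tarsals, the five metatarsals, tibia and
#'   fibula.
#' @export
all_bone_specs <- function() {
  out <- list()
  for (b in BONES) {
    for (v in variants_for_bone(b)) {
      out[[paste(b, v, sep = "/")]] <- get_bone_spec(b, v)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Filename detection

# keyword table for bone detection; patterns are matched case-insensitively
# against the filename, most specific first ("metatarsal" contains "tal", so
# metatarsals are resolved before the talus)
BONE_KEYWORDS <- list(
  list(pattern = "(met[a-z]*|mt)[ _-]?([1-5])", bone = "metatarsal"),
  list(pattern = "(med[a-z]*[ _-]?cun)|(cun[a-z]*[ _-]?med)", bone = "medial_cuneiform"),
  list(pattern = "((int|mid)[a-z]*[ _-]?cun)|(cun[a-z]*[ _-]?(int|mid))", bone = "intermediate_cuneiform"),
  list(pattern = "(lat[a-z]*[ _-]?cun)|(cun[a-z]*[ _-]?lat)", bone = "lateral_cuneiform"),
  list(pattern = "calc", bone = "calcaneus"),
  list(pattern = "nav", bone = "navicular"),
  list(pattern = "cub", bone = "cuboid"),
  list(pattern = "tal", bone = "talus"),
  list(pattern = "tib", bone = "tibia"),
  list(pattern = "fib", bone = "fibula")
)

#' Detect bone identity and laterality from a filename
#'
#' Matches a documented keyword table (e.g. `"tal"` for the talus, `"calc"`
#' for the calcaneus, `"met3"`/`"mt3"` for the third metatarsal) and standalone
#' side tokens (`r`/`rt`/`right` vs `l`/`lt`/`left`). Never throws: when either
#' field cannot be resolved the `confident` flag is `FALSE`, signalling the
#' batch driver to ask for an override.
#'
#' @param filename file name or path.
#' @return list with `bone_id` (or `NA`), `side` (`"left"`, `"right"` or
#'   `NA`), and `confident`.
#' @export
detect_bone_and_side <- function(filename) {
  stopifnot(is.character(filename), length(filename) == 1L, nzchar(filename))
  base <- tolower(tools::file_path_sans_ext(basename(filename)))

  bone <- NA_character_
  for (kw in BONE_KEYWORDS) {
    m <- regmatches(base, regexec(kw$pattern, base))[[1]]
    if (length(m)) {
      bone <- if (kw$bone == "metatarsal") paste0("metatarsal", m[3]) else kw$bone
      break
    }
  }

  tokens <- strsplit(base, "[^a-z0-9]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  is_right <- tokens %in% c("r", "rt", "rgt", "right")
  is_left <- tokens %in% c("l", "lt", "lft", "left")
  side <- NA_character_
  if (any(is_right) && !any(is_left)) side <- "right"
  if (any(is_left) && !any(is_right)) side <- "left"

  list(bone_id = bone, side = side,
       confident = !is.na(bone) && !is.na(side))
}

# ---------------------------------------------------------------------------
# Template management
#
# Directory layout: <templates>/<bone_id>/<acs_variant>/{full,partial}.ply
# plus manifest.json with template_id and extent_along_primary (mm, of the
# full template). Templates are left-side anatomy, pre-oriented with medial
# +x, anterior +y, superior +z.

#' Load a template directory
#'
#' @param dir template directory (see Details for layout).
#' @return a `template_set`: named list keyed `bone_id/acs_variant`, each
#'   entry holding the full (and where present partial) template mesh and its
#'   manifest.
#' @details Layout: `dir/<bone_id>/<acs_variant>/full.ply`, optionally
#'   `partial.ply`, and `manifest.json` carrying `template_id` and
#'   `extent_along_primary` in millimetres.
#' @export
load_template_set <- function(dir) {
  if (!dir.exists(dir)) stop("template directory not found: ", dir, call. = FALSE)
  out <- list()
  for (b in list.dirs(dir, recursive = FALSE)) {
    for (v in list.dirs(b, recursive = FALSE)) {
      mf_path <- file.path(v, "manifest.json")
      full_path <- file.path(v, "full.ply")
      if (!file.exists(mf_path) || !file.exists(full_path)) {
        stop("template entry missing manifest.json or full.ply: ", v,
             call. = FALSE)
      }
      mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
      key <- paste(basename(b), basename(v), sep = "/")
      entry <- list(
        bone_id = basename(b), acs_variant = basename(v),
        template_id = mf$template_id,
        extent_along_primary = as.numeric(mf$extent_along_primary),
        full = read_mesh(full_path),
        partial = NULL
      )
      pp <- file.path(v, "partial.ply")
      if (file.exists(pp)) entry$partial <- read_mesh(pp)
      out[[key]] <- entry
    }
  }
  structure(out, class = "template_set")
}

#' Select the template for a bone, switching to a partial-length variant
#'
#' Tibias, fibulas and metatarsals are often cropped by the scanner field of
#' view; when the subject's extent along the primary axis falls below 60% of
#' the full template's extent, the partial-length template is used instead,
#' and below 30% a cropping warning is attached (the construction becomes
#' unreliable for such limited geometry).
#'
#' @param templates a `template_set` from [load_template_set()].
#' @param bone_id,acs_variant bone / variant pair.
#' @param aligned_extent_ratio subject extent along the primary axis divided
#'   by the full template extent, estimated after provisional alignment.
#' @param partial_threshold extent ratio below which the partial-length
#'   template is used (default 0.6).
#' @param warn_threshold extent ratio below which a cropping warning is
#'   attached (default 0.3).
#' @return a `bone_template`: list with `mesh`, `bone_id`, `acs_variant`,
#'   `partial_variant` (`"full"`, `"partial"` or `"n/a"`), `template_id`,
#'   `extent_along_primary`, and `warnings` (character).
#' @export
select_template <- function(templates, bone_id, acs_variant = "default",
                            aligned_extent_ratio = 1,
                            partial_threshold = 0.6, warn_threshold = 0.3) {
  key <- paste(bone_id, acs_variant, sep = "/")
  entry <- templates[[key]]
  if (is.null(entry)) {
    stop("no template registered for ", key, call. = FALSE)
  }
  warnings <- character()
  if (bone_id %in% PARTIAL_BONES) {
    if (aligned_extent_ratio < warn_threshold) {
      warnings <- sprintf(
        "cropped %s covers only %.0f%% of the template extent; ACS may be unreliable",
        bone_id, 100 * aligned_extent_ratio)
    }
    if (aligned_extent_ratio < partial_threshold) {
      if (is.null(entry$partial)) {
        stop("partial template missing for ", key, call. = FALSE)
      }
      mesh <- entry$partial
      pv <- "partial"
    } else {
      mesh <- entry$full
      pv <- "full"
    }
  } else {
    mesh <- entry$full
    pv <- "n/a"
  }
  structure(list(mesh = mesh, bone_id = bone_id, acs_variant = acs_variant,
                 partial_variant = pv, template_id = entry$template_id,
                 extent_along_primary = entry$extent_along_primary,
                 warnings = warnings),
            class = "bone_template")
}

axis_to_index <- function(axis) {
  match(axis, c("ML", "AP", "SI"))
}
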