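# Irradiated tissue mass fraction (f_i) estimators.
#
# f_i = mass of a tissue inside the exposed volume / that tissue's whole-body
# mass. The numerators come from the phantom's measured geometry (bone cross
# sections, layer perimeters, muscle masses per 2.5 cm layer); the
# denominators from reference anatomy (total red-marrow mass, whole-body bone
# surface, Du Bois body surface area, total muscle mass).

#' Describe the layered phantom geometry
#'
#' @param layers A data frame with columns `layer` (integer index),
#'   `perimeter_cm` (layer cross-section perimeter), `bones` and `muscles`
#'   (list-columns of named numeric vectors: bone cross-section areas in cm²
#'   and muscle masses in g within the layer). Empty entries are allowed.
#' @param layer_thickness_cm Slice thickness; default 2.5 cm.
#' @param exposed_layers Integer vector of layer indices inside the field of
#'   view; must be a subset of `layers$layer`.
#' @return An object of class `phantom_geometry`.
#' @seealso [elbow_phantom_geometry()] for a complete example.
#' @export
phantom_geometry <- function(layers, layer_thickness_cm = 2.5,
                             exposed_layers) {
  if (!is.data.frame(layers) ||
      !all(c("layer", "perimeter_cm") %in% names(layers))) {
    abort("`layers` must be a data frame with columns layer and perimeter_cm.")
  }
  layers <- as_tibble(layers)
  if (!"bones" %in% names(layers)) layers$bones <- list(numeric(0))
  if (!"muscles" %in% names(layers)) layers$muscles <- list(numeric(0))
  if (!is.numeric(layer_thickness_cm) || layer_thickness_cm <= 0) {
    abort("`layer_thickness_cm` must be positive.")
  }
  exposed_layers <- as.integer(exposed_layers)
  if (!all(exposed_layers %in% layers$layer)) {
    abort("`exposed_layers` must be a subset of the declared layer indices.")
  }
  vals <- c(layers$perimeter_cm, unlist(layers$bones), unlist(layers$muscles))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("Perimeters, bone areas and muscle masses must be non-negative.")
  }
  structure(
    list(layers = layers, layer_thickness_cm = layer_thickness_cm,
         exposed_layers = sort(exposed_layers)),
    class = "phantom_geometry"
  )
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("<phantom_geometry>", nrow(x$layers), "layers of",
      x$layer_thickness_cm, "cm; exposed:",
      paste(range(x$exposed_layers), collapse = "-"), "\n")
  invisible(x)
}

exposed_layers_tbl <- function(geometry) {
  filter(geometry$layers, .data$layer %in% geometry$exposed_layers)
}

#' Reference anatomy for mass-fraction denominators
#'
#' Bundles the whole-body reference values the fraction estimators divide by.
#' Defaults describe an ICRP-style reference adult: total bone marrow as 4% of
#' a 73 kg body weight with one-third of it active red marrow of density
#' 1.03 g/cm³, 28 000 g total muscle mass, and a 5% lymphatic-node content of
#' the elbow/knee fossa region.
#'
#' @param body_mass_kg,body_height_cm Body dimensions feeding the Du Bois
#'   body-surface-area denominator of the skin fraction.
#' @param bm_weight_share Total bone marrow as a share of body weight.
#' @param active_marrow_share Red (active) marrow share of total marrow.
#' @param rbm_density_g_cm3 Red bone marrow density.
#' @param total_muscle_mass_g Whole-body muscle mass.
#' @param lymph_node_fraction Lymphatic-node mass fraction of the exposed
#'   region (a configured constant, not derived from geometry).
#' @param skeleton_mass_g,bone_density_g_cm3 Whole-skeleton fresh mass and
#'   fresh-bone density, converting per-bone weight percentages to volumes.
#' @param total_bone_surface_cm2 Whole-body bone surface area.
#' @param bones A data frame with columns `bone`, `fresh_weight_percent`
#'   (share of skeleton mass), `surface_to_volume_cm2_cm3` and
#'   `irradiated_length_fraction` (share of the bone's length inside the
#'   field of view; a free parameter of the anatomy description).
#' @return An object of class `reference_anatomy`.
#' @export
reference_anatomy <- function(body_mass_kg = 73,
                              body_height_cm = 176,
                              bm_weight_share = 0.04,
                              active_marrow_share = 1 / 3,
                              rbm_density_g_cm3 = 1.03,
                              total_muscle_mass_g = 28000,
                              lymph_node_fraction = 0.05,
                              skeleton_mass_g = 10500,
                              bone_density_g_cm3 = 1.3,
                              total_bone_surface_cm2 = 51600,
                              bones = reference_bone_table()) {
  scalars <- c(body_mass_kg = body_mass_kg, body_height_cm = body_height_cm,
               bm_weight_share = bm_weight_share,
               active_marrow_share = active_marrow_share,
               rbm_density_g_cm3 = rbm_density_g_cm3,
               total_muscle_mass_g = total_muscle_mass_g,
               lymph_node_fraction = lymph_node_fraction,
               skeleton_mass_g = skeleton_mass_g,
               bone_density_g_cm3 = bone_density_g_cm3,
               total_bone_surface_cm2 = total_bone_surface_cm2)
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    abort("All reference-anatomy scalars must be positive and finite.")
  }
  shares <- c(bm_weight_share, active_marrow_share, lymph_node_fraction)
  if (any(shares > 1)) {
    abort("Shares (bm_weight_share, active_marrow_share, lymph_node_fraction) must lie in (0, 1].")
  }
  if (!is.data.frame(bones) ||
      !all(c("bone", "fresh_weight_percent", "surface_to_volume_cm2_cm3",
             "irradiated_length_fraction") %in% names(bones))) {
    abort(paste("`bones` needs columns bone, fresh_weight_percent,",
                "surface_to_volume_cm2_cm3, irradiated_length_fraction."))
  }
  structure(
    c(as.list(scalars), list(bones = as_tibble(bones))),
    class = "reference_anatomy"
  )
}

#' @export
print.reference_anatomy <- function(x, ...) {
  cat("<reference_anatomy>", x$body_mass_kg, "kg,", x$body_height_cm,
      "cm;", nrow(x$bones), "bone entries\n")
  invisible(x)
}

#' Reconstructed per-bone reference table for the elbow region
#'
#' Per-bone fresh-weight percentages of the skeleton, surface-to-volume ratios
#' and irradiated length fractions for ulna, radius and humerus. This is a
#' synthetic reconstruction calibrated so that the shipped calibration
#' geometry reproduces the elbow-region organ totals (see
#' [elbow_phantom_geometry()]); the irradiated length fractions are free
#' parameters of the anatomy description.
#'
#' @return A tibble with one row per bone.
#' @export
reference_bone_table <- function() {
  tibble(
    bone = c("ulna", "radius", "humerus"),
    fresh_weight_percent = c(1.4, 1.1, 3.7),
    surface_to_volume_cm2_cm3 = c(6, 6, 4.5),
    irradiated_length_fraction = c(0.304, 0.378, 0.357)
  )
}

# Estimators -------------------------------------------------------------------

sum_bone_areas <- function(geometry) {
  exposed <- exposed_layers_tbl(geometry)
  areas <- unlist(exposed$bones)
  if (length(areas) == 0 || sum(areas) == 0) {
    abort("No bone cross-section data in the exposed layers.")
  }
  tapply(areas, names(areas), sum)
}

#' Red bone marrow fraction from phantom bone volumes
#'
#' Bone-marrow volume is taken as the summed bone cross-sections of the
#' exposed layers times the layer thickness; the active (red) marrow mass is
#' `active_marrow_share` of that volume times the red-marrow density; the
#' fraction divides by the whole-body red-marrow mass
#' (`active_marrow_share * bm_weight_share * body mass`).
#'
#' @param geometry A [phantom_geometry()].
#' @param anatomy A [reference_anatomy()].
#' @param by_bone If `TRUE`, return a per-bone breakdown tibble instead of the
#'   total.
#' @return The fraction (dimensionless), or a tibble `bone`/`fraction`.
#' @export
rbm_fraction <- function(geometry, anatomy, by_bone = FALSE) {
  per_bone_area <- sum_bone_areas(geometry)
  total_rbm_g <- anatomy$active_marrow_share * anatomy$bm_weight_share *
    anatomy$body_mass_kg * 1000
  frac <- anatomy$active_marrow_share * anatomy$rbm_density_g_cm3 *
    per_bone_area * geometry$layer_thickness_cm / total_rbm_g
  if (by_bone) {
    tibble(bone = names(frac), fraction = unname(frac))
  } else {
    sum(frac)
  }
}

#' Exposed red bone marrow mass (g)
#'
#' The numerator of [rbm_fraction()]: one-third (or the configured active
#' share) of the exposed bone-marrow volume times the red-marrow density.
#'
#' @inheritParams rbm_fraction
#' @return Mass in grams.
#' @export
rbm_mass <- function(geometry, anatomy) {
  sum(sum_bone_areas(geometry)) * geometry$layer_thickness_cm *
    anatomy$active_marrow_share * anatomy$rbm_density_g_cm3
}

#' Bone surface fraction from surface-to-volume ratios
#'
#' For each bone present in the exposed layers, the exposed surface is
#' `(S/V) * whole-bone volume * irradiated length fraction`, with the
#' whole-bone volume derived from its fresh-weight percentage of the skeleton
#' mass and the fresh-bone density. The fraction divides the summed exposed
#' surface by the whole-body bone surface.
#'
#' @inheritParams rbm_fraction
#' @return The fraction, or a per-bone tibble when `by_bone = TRUE`.
#' @export
bone_surface_fraction <- function(geometry, anatomy, by_bone = FALSE) {
  present <- names(sum_bone_areas(geometry))
  bones <- filter(anatomy$bones, .data$bone %in% present)
  missing <- setdiff(present, bones$bone)
  if (length(missing) > 0) {
    abort(paste0("Reference anatomy lacks bone entries for: ",
                 paste(missing, collapse = ", ")))
  }
  volume_cm3 <- bones$fresh_weight_percent / 100 * anatomy$skeleton_mass_g /
    anatomy$bone_density_g_cm3
  exposed_cm2 <- bones$surface_to_volume_cm2_cm3 * volume_cm3 *
    bones$irradiated_length_fraction
  frac <- exposed_cm2 / anatomy$total_bone_surface_cm2
  if (by_bone) tibble(bone = bones$bone, fraction = frac) else sum(frac)
}

#' Du Bois body surface area
#'
#' `BSA (m²) = 0.007184 * mass_kg^0.425 * height_cm^0.725`. The constants are
#' stored as arguments so variant coefficients can be explored.
#'
#' @param mass_kg,height_cm Body mass and height; must be positive.
#' @param coef,mass_exp,height_exp The formula constants.
#' @return Body surface area in m².
#' @examples
#' dubois_bsa(70, 180) # ~1.886 m²
#' @export
dubois_bsa <- function(mass_kg, height_cm, coef = 0.007184,
                       mass_exp = 0.425, height_exp = 0.725) {
  if (any(mass_kg <= 0) || any(height_cm <= 0)) {
    abort("Body mass and height must be positive.")
  }
  coef * mass_kg^mass_exp * height_cm^height_exp
}

#' Skin fraction from layer perimeters
#'
#' Exposed skin area is the sum of the exposed layers' perimeters times the
#' layer thickness; the whole-body denominator is the Du Bois body surface
#' area.
#'
#' @inheritParams rbm_fraction
#' @return The fraction (dimensionless).
#' @export
skin_fraction <- function(geometry, anatomy) {
  exposed <- exposed_layers_tbl(geometry)
  if (nrow(exposed) == 0) abort("No exposed layers with perimeter data.")
  exposed_cm2 <- sum(exposed$perimeter_cm) * geometry$layer_thickness_cm
  total_cm2 <- dubois_bsa(anatomy$body_mass_kg, anatomy$body_height_cm) * 1e4
  exposed_cm2 / total_cm2
}

#' Muscle fraction from per-layer muscle masses
#'
#' Sums the per-muscle masses over the exposed layers and divides by the
#' whole-body muscle mass.
#'
#' @inheritParams rbm_fraction
#' @param by_muscle If `TRUE`, return a per-muscle breakdown.
#' @return The fraction, or a tibble `muscle`/`fraction`.
#' @export
muscle_fraction <- function(geometry, anatomy, by_muscle = FALSE) {
  exposed <- exposed_layers_tbl(geometry)
  masses <- unlist(exposed$muscles)
  if (length(masses) == 0) {
    abort("No muscle mass data in the exposed layers.")
  }
  frac <- tapply(masses, names(masses), sum) / anatomy$total_muscle_mass_g
  if (by_muscle) {
    tibble(muscle = names(frac), fraction = unname(frac))
  } else {
    sum(frac)
  }
}

#' Lymphatic-node fraction
#'
#' The lymphatic-node content of the exposed region is a configured constant
#' of the reference anatomy (default 5%), not derived from geometry.
#'
#' @inheritParams rbm_fraction
#' @return The configured fraction.
#' @export
lymph_fraction <- function(anatomy) {
  anatomy$lymph_node_fraction
}

#' All five organ fractions at once
#'
#' @inheritParams rbm_fraction
#' @return A tibble with columns `organ` and `fraction` for bone marrow, bone
#'   surface, skin, lymphatic nodes and muscle.
#' @examples
#' estimate_fractions(elbow_phantom_geometry(), elbow_reference_anatomy())
#' @export
estimate_fractions <- function(geometry, anatomy) {
  tibble(
    organ = c("bone_marrow", "bone_surface", "skin", "lymphatic_nodes",
              "muscle"),
    fraction = c(
      rbm_fraction(geometry, anatomy),
      bone_surface_fraction(geometry, anatomy),
      skin_fraction(geometry, anatomy),
      lymph_fraction(anatomy),
      muscle_fraction(geometry, anatomy)
    )
  )
}

# Turning fraction estimates into a tissue map ---------------------------------

#' Sub-structure split and dosimeter assignments of the elbow study
#'
#' How each organ's total irradiated fraction distributes over its named
#' sub-structures, and which dosimeters sample each sub-structure. The bone
#' and muscle splits are recomputed from geometry by [build_tissue_map()];
#' the `share` column is only used for organs whose geometry gives a single
#' total (skin perimeters do not resolve individual muscles' skin patches).
#'
#' @return A tibble with columns `organ`, `name`, `share` (within-organ), and
#'   `dosimeters` (list of dosimeter ids).
#' @export
elbow_substructure_split <- function() {
  flat <- tidy(elbow_tissue_map())
  flat |>
    distinct(.data$organ, .data$substructure, .keep_all = FALSE) |>
    left_join(
      flat |>
        group_by(.data$organ, .data$substructure) |>
        summarise(f_i = dplyr::first(.data$f_i),
                  dosimeters = list(unique(.data$dosimeter_id)),
                  .groups = "drop"),
      by = c("organ", "substructure")
    ) |>
    group_by(.data$organ) |>
    mutate(share = .data$f_i / sum(.data$f_i)) |>
    ungroup() |>
    select(organ = "organ", name = "substructure", "share", "dosimeters")
}

#' Build a tissue map from estimated fractions
#'
#' Runs the five fraction estimators and distributes each organ total over the
#' named sub-structures: bones and muscles keep their geometry-derived
#' per-structure fractions; organs whose geometry yields only a total (skin,
#' lymphatic nodes) use the split table's within-organ shares. Tissue
#' weighting factors, remainder flags and dosimeter assignments come from the
#' split/weights arguments.
#'
#' @inheritParams rbm_fraction
#' @param split Sub-structure split and dosimeter assignments; default
#'   [elbow_substructure_split()].
#' @param weights Named numeric vector of ICRP weighting factors per organ.
#' @param remainder Character vector of remainder organ names.
#' @param w_R,remainder_organ_count Passed to [tissue_map()].
#' @return A [tissue_map()] consumable by [effective_dose()].
#' @examples
#' map <- build_tissue_map(elbow_phantom_geometry(), elbow_reference_anatomy())
#' glance(map)
#' @export
build_tissue_map <- function(geometry, anatomy,
                             split = elbow_substructure_split(),
                             weights = c(bone_marrow = 0.12,
                                         bone_surface = 0.01,
                                         skin = 0.01,
                                         lymphatic_nodes = 0.12,
                                         muscle = 0.12),
                             remainder = c("lymphatic_nodes", "muscle"),
                             w_R = 1, remainder_organ_count = 13L) {
  totals <- estimate_fractions(geometry, anatomy)
  per_structure <- list(
    bone_marrow = rename(rbm_fraction(geometry, anatomy, by_bone = TRUE),
                         name = "bone"),
    bone_surface = rename(
      bone_surface_fraction(geometry, anatomy, by_bone = TRUE),
      name = "bone"
    ),
    muscle = rename(muscle_fraction(geometry, anatomy, by_muscle = TRUE),
                    name = "muscle")
  )
  organs <- purrr::map_dfr(unique(split$organ), function(org) {
    org_split <- filter(split, .data$organ == org)
    if (org %in% names(per_structure)) {
      fi <- per_structure[[org]] |>
        left_join(select(org_split, "name", "dosimeters"), by = "name")
      if (any(purrr::map_lgl(fi$dosimeters, is.null))) {
        abort(paste0("Split table lacks dosimeter assignments for some ",
                     org, " sub-structures."))
      }
      subs <- tibble(name = fi$name, f_i = fi$fraction,
                     dosimeters = fi$dosimeters)
    } else {
      total <- totals$fraction[totals$organ == org]
      subs <- tibble(name = org_split$name,
                     f_i = total * org_split$share,
                     dosimeters = org_split$dosimeters)
    }
    tibble(organ = org, w_T = unname(weights[[org]]),
           is_remainder = org %in% remainder, substructures = list(subs))
  })
  tissue_map(organs, w_R = w_R, remainder_organ_count = remainder_organ_count)
}

# Calibration fixtures ---------------------------------------------------------

#' Reconstructed calibration geometry of the elbow phantom
#'
#' The study that the built-in fixtures encode did not publish its phantom's
#' raw geometry. This synthetic calibration geometry (layers 10-18 of a
#' 24-layer arm phantom, 2.5 cm slices, field of view over layers 11-17) was
#' reconstructed so that the fraction estimators reproduce the study's organ
#' totals — red bone marrow 1.0%, bone surface 1.7%, skin 2.9%, muscle 0.9% of
#' their whole-body masses — and the per-bone / per-muscle splits of
#' [elbow_tissue_map()].
#'
#' @return A [phantom_geometry()].
#' @export
elbow_phantom_geometry <- function() {
  b <- function(...) list(c(...))
  layers <- tibble(
    layer = 10:18,
    perimeter_cm = c(28.0, 28.4, 29.0, 29.8, 31.0, 31.9, 32.6, 33.4, 34.0),
    bones = c(
      b(ulna = 0.48, radius = 0.53),
      b(ulna = 0.50, radius = 0.55),
      b(ulna = 0.53, radius = 0.59),
      b(ulna = 0.55, radius = 0.61),
      b(ulna = 0.575, radius = 0.632),
      b(humerus = 2.1),
      b(humerus = 2.3),
      b(humerus = 2.405),
      b(humerus = 2.5)
    ),
    muscles = c(
      b(flexor_carpi_ulnaris = 3.0),
      b(flexor_carpi_ulnaris = 4.0, extensor_carpi_radialis_longus = 5.0),
      b(flexor_carpi_ulnaris = 4.0, extensor_carpi_radialis_longus = 5.0,
        brachioradialis = 17.0),
      b(flexor_carpi_ulnaris = 3.2, extensor_carpi_radialis_longus = 4.0,
        brachioradialis = 17.0),
      b(brachioradialis = 16.4),
      b(bicep = 22.0, tricep = 40.0),
      b(bicep = 22.0, tricep = 40.0),
      b(bicep = 17.6, tricep = 32.0),
      b(tricep = 20.0)
    )
  )
  phantom_geometry(layers, layer_thickness_cm = 2.5, exposed_layers = 11:17)
}

#' Reference anatomy matching the calibration geometry
#'
#' [reference_anatomy()] with its defaults: a 73 kg / 176 cm reference adult,
#' marrow 4% of body weight with one-third active, 28 000 g muscle, 5%
#' lymphatic-node fraction, and the reconstructed per-bone table of
#' [reference_bone_table()].
#'
#' @return A [reference_anatomy()].
#' @export
elbow_reference_anatomy <- function() {
  reference_anatomy()
}

# YAML serialisation -----------------------------------------------------------

#' Read / write phantom geometry and reference anatomy as YAML
#'
#' Geometry schema: `{layer_thickness_cm, exposed_layers, layers: [{layer,
#' perimeter_cm, bones: {name: area_cm2}, muscles: {name: mass_g}}]}`.
#' Anatomy schema: the [reference_anatomy()] scalars plus a `bones` list.
#'
#' @param path File path.
#' @param geometry A [phantom_geometry()].
#' @param anatomy A [reference_anatomy()].
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) abort(paste0("Geometry file not found: ", path))
  x <- yaml::read_yaml(path)
  layers <- purrr::map_dfr(x$layers, function(l) {
    tibble(
      layer = as.integer(l$layer), perimeter_cm = l$perimeter_cm,
      bones = list(unlist(l$bones) %||% numeric(0)),
      muscles = list(unlist(l$muscles) %||% numeric(0))
    )
  })
  phantom_geometry(layers, layer_thickness_cm = x$layer_thickness_cm,
                   exposed_layers = unlist(x$exposed_layers))
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  x <- list(
    layer_thickness_cm = geometry$layer_thickness_cm,
    exposed_layers = as.integer(geometry$exposed_layers),
    layers = purrr::map(seq_len(nrow(geometry$layers)), function(i) {
      row <- geometry$layers[i, ]
      list(layer = as.integer(row$layer), perimeter_cm = row$perimeter_cm,
           bones = as.list(row$bones[[1]]), muscles = as.list(row$muscles[[1]]))
    })
  )
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' @rdname read_geometry
#' @export
read_anatomy <- function(path) {
  if (!file.exists(path)) abort(paste0("Anatomy file not found: ", path))
  x <- yaml::read_yaml(path)
  bones <- purrr::map_dfr(x$bones, as_tibble)
  x$bones <- NULL
  do.call(reference_anatomy, c(x, list(bones = bones)))
}

#' @rdname read_geometry
#' @export
write_anatomy <- function(anatomy, path) {
  stopifnot(inherits(anatomy, "reference_anatomy"))
  x <- unclass(anatomy)
  x$bones <- purrr::map(seq_len(nrow(anatomy$bones)), function(i) {
    as.list(anatomy$bones[i, ])
  })
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}
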