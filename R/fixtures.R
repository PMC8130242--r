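# Built-in study fixtures: a published comparative elbow dosimetry data set
# (11 MOSFET dosimeters in a layered RANDO arm phantom, 7 imaging protocols
# across a radiography device, an MSCT scanner and two CBCT scanners).
# Absorbed doses are the study's printed per-dosimeter means in mGy; the
# radiography column is the sum of its AP and LAT projections as printed.

elbow_dosimeter_info <- function() {
  tibble(
    dosimeter_id = 1:11,
    layer = c(17L, 16L, 16L, 16L, 15L, 14L, 14L, 13L, 12L, 12L, 11L),
    location = c(
      "Humerus", "Humerus", "Triceps brachii", "Biceps brachii", "Humerus",
      "Cubital nodes", "Ulna", "Ulna", "Radius/Flexor carpi ulnaris",
      "Ulna", "Ulna"
    )
  )
}

elbow_dose_matrix <- function() {
  m <- rbind(
    c(0.3, 11.5, 0.3, 0.1, 0.5, 0.5, 0.3),
    c(0.5, 17.1, 2.9, 0.9, 0.8, 1.0, 1.3),
    c(0.6, 18.8, 1.5, 0.5, 1.1, 1.1, 1.4),
    c(1.1, 21.6, 4.9, 1.3, 1.1, 1.3, 1.4),
    c(0.5, 16.4, 3.3, 1.0, 0.8, 0.8, 1.4),
    c(0.9, 18.5, 4.2, 1.3, 1.5, 1.2, 1.3),
    c(0.3, 15.1, 3.0, 1.0, 0.9, 0.9, 1.3),
    c(0.4, 14.9, 2.6, 0.7, 1.2, 0.5, 1.0),
    c(1.1, 19.3, 0.5, 0.2, 0.6, 1.0, 1.1),
    c(0.4, 13.3, 0.3, 0.1, 0.9, 0.5, 0.7),
    c(0.4, 11.1, 0.6, 0.2, 1.0, 0.3, 0.4)
  )
  colnames(m) <- elbow_protocol_ids()
  rownames(m) <- as.character(1:11)
  m
}

#' Protocol identifiers of the built-in elbow study
#'
#' @return Character vector of the seven protocol ids, radiography first.
#' @export
elbow_protocol_ids <- function() {
  c("shimadzu_fh21", "siemens_sensation", "newtom5g_hires_12x8",
    "newtom5g_std_12x8", "newtom5g_std_15x12", "newtom5g_std_18x16",
    "planmed_verity")
}

#' Built-in elbow study dosimeter readings
#'
#' Per-dosimeter absorbed doses (mGy) for 11 MOSFET dosimeters under 7 imaging
#' protocols, as a tidy readings table (one "measured mean" replicate per
#' dosimeter and protocol; the radiography column already sums its AP and LAT
#' projections).
#'
#' @return A tibble with columns `protocol_id`, `exposure_id`, `dosimeter_id`,
#'   `layer`, `location`, `replicate`, `absorbed_dose_mGy` (77 rows).
#' @examples
#' elbow_readings() |> effective_dose(elbow_tissue_map(), elbow_protocols())
#' @export
elbow_readings <- function() {
  m <- elbow_dose_matrix()
  info <- elbow_dosimeter_info()
  purrr::map_dfr(colnames(m), function(p) {
    tibble(
      protocol_id = p,
      exposure_id = if (p == "shimadzu_fh21") "AP+LAT" else "scan",
      dosimeter_id = 1:11,
      layer = info$layer,
      location = info$location,
      replicate = 1L,
      absorbed_dose_mGy = unname(m[, p])
    )
  })
}

#' Built-in elbow study tissue map
#'
#' ICRP 103 tissue weighting factors, irradiated mass fractions and dosimeter
#' assignments for the organs inside the elbow field of view: bone marrow
#' (w_T 0.12), bone surface (0.01), skin (0.01), and the two remainder organs
#' present in the region — lymphatic (cubital) nodes and muscle — sharing the
#' remainder weight (0.12) over the 13 ICRP remainder organs.
#'
#' @return A [tissue_map()].
#' @export
elbow_tissue_map <- function() {
  sub <- function(name, f_pct, ids) {
    tibble(name = name, f_i = f_pct / 100, dosimeters = list(as.integer(ids)))
  }
  organs <- tibble(
    organ = c("bone_marrow", "bone_surface", "skin", "lymphatic_nodes",
              "muscle"),
    w_T = c(0.12, 0.01, 0.01, 0.12, 0.12),
    is_remainder = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    substructures = list(
      bind_rows(
        sub("ulna", 0.19, c(7, 8, 10, 11)),
        sub("radius", 0.21, c(6, 8, 10, 11)),
        sub("humerus", 0.60, c(1, 2, 5, 6))
      ),
      bind_rows(
        sub("ulna", 0.40, c(6, 9)),
        sub("radius", 0.39, c(6, 9)),
        sub("humerus", 0.93, c(1, 2, 5, 6))
      ),
      bind_rows(
        sub("flexor_carpi_ulnaris", 0.83, 9),
        sub("extensor_carpi_radialis_longus", 0.80, 8),
        sub("bicep", 0.81, 4),
        sub("tricep", 0.42, 3)
      ),
      sub("cubital_nodes", 5.00, 6),
      bind_rows(
        sub("flexor_carpi_ulnaris", 0.04, 9),
        sub("extensor_carpi_radialis_longus", 0.05, 6),
        sub("brachioradialis", 0.18, 6),
        sub("bicep", 0.22, 4),
        sub("tricep", 0.40, 3)
      )
    )
  )
  tissue_map(organs, w_R = 1, remainder_organ_count = 13L)
}

#' Built-in elbow study protocol metadata
#'
#' Exposure parameters of the seven protocols: device, modality, tube
#' potential, tube current-exposure time product (mAs, used for the normalised
#' effective dose), field of view and, where applicable, CTDIvol and DLP.
#'
#' @return A tibble, one row per protocol.
#' @export
elbow_protocols <- function() {
  tibble(
    protocol_id = elbow_protocol_ids(),
    device = c("Shimadzu FH-21 HR", "Siemens Sensation Open",
               "NewTom 5G", "NewTom 5G", "NewTom 5G", "NewTom 5G",
               "Planmed Verity"),
    modality = c("radiography", "MSCT", "CBCT", "CBCT", "CBCT", "CBCT",
                 "CBCT"),
    setting = c("AP+LAT", "standard", "HiRes", "Standard Scan",
                "Standard Scan", "Standard Scan", "ULD"),
    kVp = c(59, 120, 110, 110, 110, 110, 92),
    mAs = c(12.6, 115, 27.7, 3.5, 2.6, 2.4, 22.5),
    fov = c("13x16", "13x16", "12x8", "12x8", "15x12", "18x16", "13x16"),
    ctdi_vol_mGy = c(NA, 11.0, 4.40, 1.16, 1.15, 1.14, NA),
    dlp_mGy_cm = c(NA, 179, 39.6, 10.5, 14.7, 18.2, NA)
  )
}

#' Published summary values of the built-in elbow study
#'
#' The study's own printed per-protocol summary rows: effective dose, the
#' mAs-normalised effective dose, the effective-dose ratio against the
#' radiography baseline, the mean absorbed organ dose and its ratio. These are
#' reference values for comparison with pipeline output — useful as inputs to
#' [dose_ratios()] / [ratio_correlation()] when working from the published
#' summary rather than recomputing from readings.
#'
#' @return A tibble, one row per protocol.
#' @export
elbow_published_doses <- function() {
  tibble(
    protocol_id = elbow_protocol_ids(),
    effective_dose_uSv = c(1.5, 37.4, 6.7, 2.0, 2.5, 2.1, 2.6),
    normalized_uSv_per_mAs = c(0.12, 0.32, 0.24, 0.58, 0.95, 0.86, 0.11),
    effective_dose_ratio = c(1.0, 25.4, 4.6, 1.4, 1.7, 1.4, 1.8),
    mean_absorbed_mGy = c(0.6, 16.1, 2.2, 0.7, 1.0, 0.8, 1.1),
    absorbed_dose_ratio = c(1.0, 28.4, 3.9, 1.2, 1.7, 1.5, 1.9)
  )
}
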