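# Fraction estimators: closed-form anchor cases, scaling/monotonicity
# properties, and the reconstructed calibration fixture's organ totals.

test_that("red bone marrow mass and fraction follow the one-third rule", {
  # one layer, one bone of 4 cm2, 2.5 cm slices, density 1, share 1/3
  geom <- phantom_geometry(
    tibble::tibble(layer = 1L, perimeter_cm = 10,
                   bones = list(c(humerus = 4)),
                   muscles = list(c(bicep = 1))),
    layer_thickness_cm = 2.5, exposed_layers = 1L
  )
  anat <- reference_anatomy(rbm_density_g_cm3 = 1)
  expect_equal(rbm_mass(geom, anat), 10 / 3)

  # multi-layer random geometry vs a term-by-term summation oracle
  set.seed(21)
  layers <- tibble::tibble(
    layer = 1:6,
    perimeter_cm = runif(6, 20, 35),
    bones = purrr::map(1:6, ~ c(ulna = runif(1, 0, 2),
                                radius = runif(1, 0, 2))),
    muscles = purrr::map(1:6, ~ c(bicep = runif(1, 0, 50)))
  )
  geom2 <- phantom_geometry(layers, 2.5, exposed_layers = 2:5)
  anat2 <- elbow_reference_anatomy()
  manual_vol <- 0
  for (i in 2:5) manual_vol <- manual_vol + sum(layers$bones[[i]]) * 2.5
  manual_mass <- manual_vol * anat2$active_marrow_share *
    anat2$rbm_density_g_cm3
  total_rbm <- anat2$active_marrow_share * anat2$bm_weight_share *
    anat2$body_mass_kg * 1000
  expect_equal(rbm_mass(geom2, anat2), manual_mass, tolerance = 1e-12)
  expect_equal(rbm_fraction(geom2, anat2), manual_mass / total_rbm,
               tolerance = 1e-12)

  # doubling every cross-section doubles the mass
  doubled <- layers
  doubled$bones <- purrr::map(doubled$bones, ~ .x * 2)
  geom3 <- phantom_geometry(doubled, 2.5, exposed_layers = 2:5)
  expect_equal(rbm_mass(geom3, anat2), 2 * rbm_mass(geom2, anat2))
})

test_that("Du Bois body surface area matches the hand-evaluated formula", {
  expect_equal(dubois_bsa(70, 180), 1.8863, tolerance = 1e-4)
  # monotone in both mass and height
  expect_gt(dubois_bsa(80, 180), dubois_bsa(70, 180))
  expect_gt(dubois_bsa(70, 190), dubois_bsa(70, 180))
  expect_error(dubois_bsa(-1, 180), "positive")
})

test_that("skin and bone-surface estimators handle degenerate input", {
  layers <- tibble::tibble(layer = 1:2, perimeter_cm = c(0, 0),
                           bones = list(c(ulna = 1), c(ulna = 1)),
                           muscles = list(numeric(0), numeric(0)))
  geom <- phantom_geometry(layers, 2.5, exposed_layers = 1:2)
  anat <- elbow_reference_anatomy()
  expect_equal(skin_fraction(geom, anat), 0)

  # zero surface-to-volume ratio gives a zero bone-surface fraction
  anat0 <- reference_anatomy(bones = tibble::tibble(
    bone = "ulna", fresh_weight_percent = 1.4,
    surface_to_volume_cm2_cm3 = 0, irradiated_length_fraction = 0.3
  ))
  expect_equal(bone_surface_fraction(geom, anat0), 0)
  # missing per-bone entries are an error
  anat_missing <- reference_anatomy(bones = tibble::tibble(
    bone = "femur", fresh_weight_percent = 4,
    surface_to_volume_cm2_cm3 = 5, irradiated_length_fraction = 0.3
  ))
  expect_error(bone_surface_fraction(geom, anat_missing), "ulna")
})

test_that("muscle fraction is mass over whole-body muscle mass", {
  geom <- phantom_geometry(
    tibble::tibble(layer = 1L, perimeter_cm = 30,
                   bones = list(c(ulna = 1)),
                   muscles = list(c(bicep = 280))),
    2.5, exposed_layers = 1L
  )
  expect_equal(muscle_fraction(geom, elbow_reference_anatomy()),
               280 / 28000)
  # random masses vs summation oracle
  set.seed(4)
  masses <- purrr::map(1:4, ~ c(bicep = runif(1, 0, 60),
                                tricep = runif(1, 0, 60)))
  geom2 <- phantom_geometry(
    tibble::tibble(layer = 1:4, perimeter_cm = rep(30, 4),
                   bones = purrr::map(1:4, ~ c(ulna = 1)),
                   muscles = masses),
    2.5, exposed_layers = 1:4
  )
  expect_equal(muscle_fraction(geom2, elbow_reference_anatomy()),
               sum(unlist(masses)) / 28000, tolerance = 1e-12)
})

test_that("lymph fraction is the configured constant and survives config IO", {
  expect_equal(lymph_fraction(elbow_reference_anatomy()), 0.05)
  anat <- reference_anatomy(lymph_node_fraction = 0.02)
  expect_equal(lymph_fraction(anat), 0.02)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_anatomy(anat, path)
  expect_equal(lymph_fraction(read_anatomy(path)), 0.02)
})

test_that("calibration fixture reproduces the elbow-region organ totals", {
  fr <- estimate_fractions(elbow_phantom_geometry(),
                           elbow_reference_anatomy())
  pct <- 100 * fr$fraction[match(
    c("bone_marrow", "bone_surface", "skin", "muscle", "lymphatic_nodes"),
    fr$organ)]
  expect_equal(pct, c(1.0, 1.7, 2.9, 0.9, 5.0), tolerance = 0.05)
  expect_true(all(fr$fraction > 0 & fr$fraction < 1))
})

test_that("fractions are monotone in the exposed geometry", {
  geom <- elbow_phantom_geometry()
  anat <- elbow_reference_anatomy()
  wider <- phantom_geometry(geom$layers, geom$layer_thickness_cm,
                            exposed_layers = 10:18)
  base <- estimate_fractions(geom, anat)
  more <- estimate_fractions(wider, anat)
  expect_true(all(more$fraction >= base$fraction))
})

test_that("the regenerated tissue map matches the study's f_i table", {
  map <- build_tissue_map(elbow_phantom_geometry(),
                          elbow_reference_anatomy())
  want <- tidy(elbow_tissue_map()) |>
    dplyr::distinct(organ, substructure, f_i, dosimeter_id)
  got <- tidy(map) |>
    dplyr::distinct(organ, substructure, f_i, dosimeter_id)
  joined <- dplyr::inner_join(want, got,
                              by = c("organ", "substructure", "dosimeter_id"),
                              suffix = c("_study", "_rebuilt"))
  expect_equal(nrow(joined), nrow(want))
  expect_equal(joined$f_i_rebuilt, joined$f_i_study, tolerance = 3e-3)
  expect_true(max(abs(joined$f_i_rebuilt - joined$f_i_study)) < 1e-4)

  # and the rebuilt map drives the dose engine to near-identical results
  e_study <- glance(effective_dose(elbow_readings(), elbow_tissue_map()))
  e_rebuilt <- glance(effective_dose(elbow_readings(), map))
  expect_equal(e_rebuilt$effective_dose_uSv, e_study$effective_dose_uSv,
               tolerance = 2e-3)
})

test_that("geometry and anatomy YAML round trips preserve the estimates", {
  geom <- elbow_phantom_geometry()
  anat <- elbow_reference_anatomy()
  gpath <- withr::local_tempfile(fileext = ".yaml")
  apath <- withr::local_tempfile(fileext = ".yaml")
  write_geometry(geom, gpath)
  write_anatomy(anat, apath)
  expect_equal(estimate_fractions(read_geometry(gpath), read_anatomy(apath)),
               estimate_fractions(geom, anat), tolerance = 1e-12)
})
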