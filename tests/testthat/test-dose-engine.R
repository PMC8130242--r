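# Worked examples frozen from independent hand/spreadsheet computation, plus
# property-style checks of the engine against an exhaustive summation oracle.

test_that("equivalent dose reproduces hand-computed anchor cases", {
  msct <- elbow_readings() |>
    dplyr::filter(protocol_id == "siemens_sensation")
  eq <- equivalent_doses(msct, elbow_tissue_map())

  # lymphatic nodes: f = 0.05, dosimeter 6 reads 18.5 mGy
  expect_equal(eq$equivalent_dose_uSv[eq$organ == "lymphatic_nodes"],
               0.05 * 18.5 * 1000)

  # muscle: five sub-structures, term-by-term spreadsheet sum
  # 0.0004*19.3 + 0.0005*18.5 + 0.0018*18.5 + 0.0022*21.6 + 0.0040*18.8 mGy
  expect_equal(eq$equivalent_dose_uSv[eq$organ == "muscle"], 172.99,
               tolerance = 1e-9)

  # identity case: one sub-structure, f = 1, one dosimeter at 1 mGy, w_R = 1
  tiny_map <- tissue_map(tibble::tibble(
    organ = "skin", w_T = 0.01, is_remainder = FALSE,
    substructures = list(tibble::tibble(name = "s", f_i = 1,
                                        dosimeters = list(1L)))
  ))
  tiny <- tibble::tibble(protocol_id = "p", dosimeter_id = 1L,
                         absorbed_dose_mGy = 1)
  expect_equal(equivalent_doses(tiny, tiny_map)$equivalent_dose_uSv, 1000)

  # all-zero readings give zero everywhere
  zero <- dplyr::mutate(msct, absorbed_dose_mGy = 0)
  expect_warning(res <- effective_dose(zero, elbow_tissue_map()),
                 "zero")
  expect_equal(glance(res)$effective_dose_uSv, 0)
  expect_true(all(is.na(tidy(res)$contribution_pct)))
})

test_that("remainder weighting follows the shared-over-13 convention", {
  msct <- elbow_readings() |>
    dplyr::filter(protocol_id == "siemens_sensation")
  org <- tidy(effective_dose(msct, elbow_tissue_map()))
  lymph <- org[org$organ == "lymphatic_nodes", ]
  muscle <- org[org$organ == "muscle", ]
  expect_equal(lymph$effective_weight, 0.12 / 13)
  expect_equal(lymph$contribution_uSv, 925 * 0.12 / 13)
  expect_equal(muscle$contribution_uSv, 172.99 * 0.12 / 13, tolerance = 1e-9)
  # non-remainder organ: plain product
  bm <- org[org$organ == "bone_marrow", ]
  expect_equal(bm$contribution_uSv, 0.12 * bm$equivalent_dose_uSv)
})

test_that("engine equals the exhaustive summation oracle on random maps", {
  set.seed(42)
  for (rep in 1:20) {
    ids <- sort(sample(1:11, sample(3:11, 1)))
    map <- random_tissue_map(ids)
    doses <- random_doses(ids)
    expected <- oracle_effective_dose(doses, map)
    res <- effective_dose(readings_from_doses(doses), map)
    expect_equal(glance(res)$effective_dose_uSv,
                 expected$effective_dose_uSv, tolerance = 1e-12)
    org <- tidy(res)
    for (o in names(expected$per_organ)) {
      expect_equal(org$equivalent_dose_uSv[org$organ == o],
                   unname(expected$per_organ[[o]]["H"]), tolerance = 1e-12)
    }
  }
})

test_that("effective dose is linear, conservative and monotone in readings", {
  set.seed(7)
  ids <- 1:11
  map <- elbow_tissue_map()
  doses <- random_doses(ids)
  base <- effective_dose(readings_from_doses(doses), map)
  e0 <- glance(base)$effective_dose_uSv

  # conservation: sum of weighted contributions equals E to 1e-9 relative
  expect_equal(sum(tidy(base)$contribution_uSv), e0, tolerance = 1e-9)
  expect_equal(sum(tidy(base)$contribution_pct), 100, tolerance = 1e-9)

  # linearity: scaling all readings by c scales everything by exactly c
  for (c_scale in c(0.5, 3, 17.3)) {
    scaled <- effective_dose(
      readings_from_doses(doses * c_scale), map)
    expect_equal(glance(scaled)$effective_dose_uSv, c_scale * e0,
                 tolerance = 1e-12)
    expect_equal(tidy(scaled)$contribution_uSv,
                 c_scale * tidy(base)$contribution_uSv, tolerance = 1e-12)
  }

  # monotonicity: increasing any single reading never decreases E
  for (d in ids) {
    bumped <- doses
    bumped[as.character(d)] <- bumped[as.character(d)] + 1
    e1 <- glance(effective_dose(readings_from_doses(bumped),
                                map))$effective_dose_uSv
    expect_gte(e1, e0)
  }
})

test_that("sub-exposures sum and replicates average before the dose equation", {
  # AP and LAT stored separately must equal their printed sum
  ap_lat <- elbow_readings() |>
    dplyr::filter(protocol_id == "shimadzu_fh21")
  split <- dplyr::bind_rows(
    dplyr::mutate(ap_lat, exposure_id = "AP",
                  absorbed_dose_mGy = absorbed_dose_mGy * 0.3),
    dplyr::mutate(ap_lat, exposure_id = "LAT",
                  absorbed_dose_mGy = absorbed_dose_mGy * 0.7)
  )
  expect_equal(
    glance(effective_dose(split, elbow_tissue_map()))$effective_dose_uSv,
    glance(effective_dose(ap_lat, elbow_tissue_map()))$effective_dose_uSv
  )

  # replicates collapse to their mean
  reps <- dplyr::bind_rows(
    dplyr::mutate(ap_lat, replicate = 1L,
                  absorbed_dose_mGy = absorbed_dose_mGy - 0.05),
    dplyr::mutate(ap_lat, replicate = 2L,
                  absorbed_dose_mGy = absorbed_dose_mGy + 0.05)
  )
  expect_equal(
    glance(effective_dose(reps, elbow_tissue_map()))$effective_dose_uSv,
    glance(effective_dose(ap_lat, elbow_tissue_map()))$effective_dose_uSv
  )
})

test_that("missing dosimeters and malformed input raise informative errors", {
  msct <- elbow_readings() |>
    dplyr::filter(protocol_id == "siemens_sensation", dosimeter_id != 6)
  expect_error(effective_dose(msct, elbow_tissue_map()),
               "dosimeter #6")
  expect_error(effective_dose(data.frame(), elbow_tissue_map()),
               "missing required column")
  dup <- dplyr::bind_rows(elbow_readings(), elbow_readings()[1, ])
  expect_error(effective_dose(dup, elbow_tissue_map()), "Duplicate")
})

test_that("mean absorbed dose matches direct averaging", {
  set.seed(11)
  expect_equal(
    mean_absorbed_dose(elbow_readings()) |>
      dplyr::filter(protocol_id == "siemens_sensation") |>
      dplyr::pull(mean_absorbed_mGy),
    177.6 / 11
  )
  const <- readings_from_doses(stats::setNames(rep(2.5, 11), 1:11))
  expect_equal(mean_absorbed_dose(const)$mean_absorbed_mGy, 2.5)
  doses <- random_doses(1:7)
  expect_equal(mean_absorbed_dose(readings_from_doses(doses))$mean_absorbed_mGy,
               sum(doses) / length(doses))
})

test_that("dose ratios divide by the baseline and catch degenerate input", {
  pub <- elbow_published_doses()
  r <- dose_ratios(pub, "shimadzu_fh21")
  expect_equal(r$dose_ratio[r$protocol_id == "shimadzu_fh21"], 1.0)
  expect_equal(r$dose_ratio, pub$effective_dose_uSv / 1.5)

  set.seed(3)
  tab <- tibble::tibble(protocol_id = letters[1:5],
                        effective_dose_uSv = runif(5, 1, 40))
  rr <- dose_ratios(tab, "c")
  expect_equal(rr$dose_ratio,
               tab$effective_dose_uSv / tab$effective_dose_uSv[3])

  zero <- tibble::tibble(protocol_id = "a", effective_dose_uSv = 0)
  expect_error(dose_ratios(zero, "a"), "zero")
  expect_error(dose_ratios(tab, "nope"), "exactly once")
})

test_that("ratio correlation is Pearson and baseline-invariant", {
  x <- c(1, 2, 3, 4.5, 9)
  expect_equal(ratio_correlation(x, 2 * x), 1.0)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(6)
    b <- runif(6)
    expect_equal(ratio_correlation(a, b), oracle_pearson(a, b),
                 tolerance = 1e-12)
  }
  # invariant to the (positive) baseline chosen for either ratio vector
  e <- runif(7, 1, 40)
  m <- e * runif(7, 0.8, 1.2)
  r1 <- ratio_correlation(e / e[1], m / m[1])
  r2 <- ratio_correlation(e / e[4], m / m[4])
  expect_equal(r1, r2, tolerance = 1e-12)

  expect_error(ratio_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(ratio_correlation(1:2, 1:2), "At least 3")
  expect_error(ratio_correlation(1:4, 1:5), "equal length")
})

test_that("group dose differences convert to background-day equivalents", {
  pub <- elbow_published_doses()
  cbct <- elbow_protocol_ids()[3:7]
  d <- dose_difference(pub, "siemens_sensation", cbct)
  expect_equal(d$difference_uSv, 37.4 - mean(c(6.7, 2.0, 2.5, 2.1, 2.6)))
  # ~4 days of background at 3.1 mSv/yr
  expect_equal(d$background_days, d$difference_uSv / 3100 * 365.25)
  expect_equal(round(d$background_days), 4)

  same <- dose_difference(pub, cbct, cbct)
  expect_equal(same$difference_uSv, 0)
  expect_error(dose_difference(pub, "nope", cbct), "Unknown protocol")
})

test_that("normalized dose uses mAs and reports absent when it cannot", {
  res <- effective_dose(elbow_readings(), elbow_tissue_map(),
                        elbow_protocols())
  g <- glance(res)
  expect_equal(
    g$normalized_uSv_per_mAs,
    g$effective_dose_uSv / g$mAs
  )
  no_mAs <- dplyr::mutate(elbow_protocols(), mAs = NA_real_)
  g2 <- glance(effective_dose(elbow_readings(), elbow_tissue_map(), no_mAs))
  expect_true(all(is.na(g2$normalized_uSv_per_mAs)))
})
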