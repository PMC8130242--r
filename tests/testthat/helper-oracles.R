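# Independent oracles and random-case generators. The oracles recompute the
# package's quantities by plain loops over the flattened inputs — no shared
# code paths with the engine.

# Effective dose by exhaustive term-by-term summation. `doses` is a named
# numeric vector (names = dosimeter ids, mGy) for ONE protocol.
oracle_effective_dose <- function(doses, map) {
  total <- 0
  per_organ <- list()
  for (i in seq_len(nrow(map$organs))) {
    org <- map$organs[i, ]
    subs <- org$substructures[[1]]
    h_mGy <- 0
    for (j in seq_len(nrow(subs))) {
      ids <- as.character(subs$dosimeters[[j]])
      h_mGy <- h_mGy + subs$f_i[[j]] * mean(doses[ids])
    }
    h_uSv <- map$w_R * 1000 * h_mGy
    w_eff <- if (org$is_remainder) {
      org$w_T / map$remainder_organ_count
    } else {
      org$w_T
    }
    per_organ[[org$organ]] <- c(H = h_uSv, contribution = w_eff * h_uSv)
    total <- total + w_eff * h_uSv
  }
  list(effective_dose_uSv = total, per_organ = per_organ)
}

# Textbook Pearson correlation, written out.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Readings table for one protocol from a named dose vector.
readings_from_doses <- function(doses, protocol_id = "p1") {
  tibble::tibble(
    protocol_id = protocol_id,
    dosimeter_id = as.integer(names(doses)),
    absorbed_dose_mGy = unname(doses)
  )
}

# Random small tissue map over the given dosimeter ids.
random_tissue_map <- function(dosimeter_ids, n_organs = sample(2:5, 1)) {
  organs <- purrr::map_dfr(seq_len(n_organs), function(i) {
    n_subs <- sample(1:3, 1)
    subs <- purrr::map_dfr(seq_len(n_subs), function(j) {
      tibble::tibble(
        name = paste0("sub", i, "_", j),
        f_i = runif(1, 0.001, 0.2),
        dosimeters = list(sample(dosimeter_ids,
                                 sample(seq_along(dosimeter_ids), 1)))
      )
    })
    tibble::tibble(
      organ = paste0("organ", i),
      w_T = runif(1, 0.01, 0.2),
      is_remainder = runif(1) < 0.4,
      substructures = list(subs)
    )
  })
  tissue_map(organs, w_R = 1, remainder_organ_count = 13L)
}

random_doses <- function(dosimeter_ids, max_mGy = 25) {
  stats::setNames(runif(length(dosimeter_ids), 0.05, max_mGy),
                  dosimeter_ids)
}

msct_doses <- function() {
  r <- collapse_readings(elbow_readings())
  r <- r[r$protocol_id == "siemens_sensation", ]
  stats::setNames(r$dose_mGy, r$dosimeter_id)
}
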