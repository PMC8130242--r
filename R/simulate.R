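# Synthetic replicate generator. Emulates the statistical structure of the
# measurements — repeated positive readings scattered around a true dose with
# a configurable coefficient of variation — without any beam physics.
#
# Each (protocol, dosimeter) pair gets its own RNG stream derived from the
# master seed and the pair's identifiers, so adding a protocol to the true
# dose field never perturbs the draws of existing pairs.

pair_seed <- function(seed, protocol, dosimeter) {
  key <- paste0(protocol, "\r", dosimeter)
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + seed * 7919) %% 2147483647)
}

draw_replicates <- function(n, mean_mGy, cv, noise_model) {
  if (mean_mGy == 0) return(rep(0, n))
  switch(noise_model,
    lognormal = {
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(n, meanlog = log(mean_mGy) - sdlog^2 / 2, sdlog = sdlog)
    },
    truncated_normal = {
      out <- rnorm(n, mean_mGy, cv * mean_mGy)
      while (any(out <= 0)) {
        bad <- out <= 0
        out[bad] <- rnorm(sum(bad), mean_mGy, cv * mean_mGy)
      }
      out
    }
  )
}

#' Simulate replicate dosimeter readings around a true dose field
#'
#' Draws `replicates` positive readings per (protocol, dosimeter) pair with
#' mean equal to the true dose and per-replicate coefficient of variation
#' `cv_pct` (so the type A uncertainty of the replicate mean is about
#' `cv_pct / sqrt(replicates)`; set `cv_of_mean = TRUE` to specify the mean's
#' CV directly instead). The default noise model is lognormal — readings are
#' positive, and at large CV a normal model would put mass below zero; a
#' zero-truncated normal is available for sensitivity checks. Identical
#' `seed` + inputs give an identical dataset.
#'
#' @param true_doses A data frame with columns `protocol_id`, `dosimeter_id`,
#'   `true_mGy` (optionally `layer`, `location`, carried through; and
#'   `cv_pct` for per-dosimeter noise levels). Defaults to the built-in elbow
#'   study's per-dosimeter doses.
#' @param replicates Number of replicate readings per pair; default 10.
#' @param cv_pct Per-replicate coefficient of variation in percent (scalar),
#'   ignored where `true_doses` has its own `cv_pct` column. Default 30.
#' @param noise_model `"lognormal"` (default) or `"truncated_normal"`.
#' @param seed Master seed (integer).
#' @param cv_of_mean If `TRUE`, interpret `cv_pct` as the target CV of the
#'   replicate mean (per-draw CV is then `cv_pct * sqrt(replicates)`).
#' @return A readings tibble compatible with [effective_dose()]:
#'   `protocol_id`, `exposure_id`, `dosimeter_id`, (`layer`, `location`,)
#'   `replicate`, `absorbed_dose_mGy`.
#' @examples
#' sim <- simulate_readings(replicates = 10, cv_pct = 30, seed = 1)
#' type_a_from_readings(sim)
#' @export
simulate_readings <- function(true_doses = elbow_true_doses(),
                              replicates = 10, cv_pct = 30,
                              noise_model = c("lognormal", "truncated_normal"),
                              seed = 1, cv_of_mean = FALSE) {
  noise_model <- match.arg(noise_model)
  if (!is.data.frame(true_doses) ||
      !all(c("protocol_id", "dosimeter_id", "true_mGy") %in%
           names(true_doses))) {
    abort(paste("`true_doses` must have columns protocol_id, dosimeter_id,",
                "true_mGy."))
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2) {
    abort("`replicates` must be an integer >= 2.")
  }
  if (any(true_doses$true_mGy < 0)) abort("True doses must be non-negative.")
  cvs <- if ("cv_pct" %in% names(true_doses)) {
    true_doses$cv_pct
  } else {
    rep(cv_pct, nrow(true_doses))
  }
  if (any(!is.finite(cvs)) || any(cvs <= 0)) {
    abort("`cv_pct` must be positive.")
  }
  if (cv_of_mean) cvs <- cvs * sqrt(replicates)
  seed <- as.integer(seed)

  meta <- intersect(c("layer", "location"), names(true_doses))
  purrr::map_dfr(seq_len(nrow(true_doses)), function(i) {
    row <- true_doses[i, ]
    # restore the caller's RNG state afterwards: the generator owns its streams
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(pair_seed(seed, row$protocol_id, row$dosimeter_id))
    draws <- draw_replicates(replicates, row$true_mGy, cvs[i] / 100,
                             noise_model)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    out <- tibble(
      protocol_id = row$protocol_id, exposure_id = "sim",
      dosimeter_id = row$dosimeter_id,
      replicate = seq_len(replicates), absorbed_dose_mGy = draws
    )
    for (m in meta) out[[m]] <- row[[m]]
    out
  })
}

#' True dose field of the built-in elbow study
#'
#' The per-dosimeter absorbed doses of [elbow_readings()] reshaped as a true
#' dose field for [simulate_readings()].
#'
#' @return A tibble `protocol_id`, `dosimeter_id`, `layer`, `location`,
#'   `true_mGy`.
#' @export
elbow_true_doses <- function() {
  collapse_readings(elbow_readings()) |>
    rename(true_mGy = "dose_mGy")
}

#' The complete built-in study fixture
#'
#' Readings, tissue map and protocol metadata of the built-in elbow study in
#' one call, e.g. for feeding [run_pipeline()].
#'
#' @return A list with elements `readings`, `tissue_map`, `protocols`.
#' @export
paper_fixture <- function() {
  list(
    readings = elbow_readings(),
    tissue_map = elbow_tissue_map(),
    protocols = elbow_protocols()
  )
}
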