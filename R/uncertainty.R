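# Uncertainty propagation: type A (replicate scatter) and type B (systematic)
# relative uncertainties combined by weighted sums of variances.
#
# Components are assumed independent. A component applies at one of three
# levels: per dosimeter (e.g. dosimeter positioning), per sub-structure
# (the irradiated-fraction estimate f_i), or globally (x-ray source output,
# cable irradiation). Level matters because a component attached to a small
# contributor is shrunk by its squared share of the effective dose, while a
# global component passes through at full size.

#' Type A relative uncertainty of a replicate set
#'
#' Relative standard uncertainty, in percent, of repeated readings of one
#' dosimeter. With `of_mean = TRUE` (default) the standard deviation of the
#' mean is reported (`s / (mean * sqrt(n))`), matching the use of the
#' replicate mean in the dose computation; `of_mean = FALSE` gives the
#' per-reading scatter `s / mean`.
#'
#' @param x Numeric vector of >= 2 replicate readings with positive mean.
#' @param of_mean Report the uncertainty of the mean (default) or of a single
#'   reading.
#' @return Relative 1SD in percent.
#' @examples
#' type_a_uncertainty(c(9, 11)) # 10%
#' @export
type_a_uncertainty <- function(x, of_mean = TRUE) {
  if (length(x) < 2) {
    abort("Type A uncertainty needs at least 2 replicates.")
  }
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    abort("Type A uncertainty is undefined for a non-positive mean.")
  }
  rel <- sd(x) / m
  if (of_mean) rel <- rel / sqrt(length(x))
  100 * rel
}

#' Combine relative uncertainties in quadrature
#'
#' `sqrt(sum(c_i^2))` over independent relative components.
#'
#' @param components Numeric vector of relative 1SD values in percent.
#' @return Combined relative 1SD in percent.
#' @examples
#' combine_quadrature(c(3, 4)) # 5
#' @export
combine_quadrature <- function(components) {
  if (length(components) == 0) return(0)
  if (any(!is.finite(components)) || any(components < 0)) {
    abort("Uncertainty components must be non-negative and finite.")
  }
  sqrt(sum(components^2))
}

#' Default systematic uncertainty components
#'
#' Dosimeter positioning 10% and phantom positioning 10% (per dosimeter),
#' irradiated-fraction estimate 25% (per sub-structure), x-ray source output
#' variation 5% and cable irradiation 1% (global).
#'
#' @return A tibble with columns `component`, `relative_1sd_pct`,
#'   `applies_to` (one of `per_dosimeter`, `per_substructure`, `global`).
#' @export
default_uncertainty_components <- function() {
  tibble(
    component = c("dosimeter_position", "phantom_position",
                  "fraction_irradiated", "source_variation",
                  "cable_irradiation"),
    relative_1sd_pct = c(10, 10, 25, 5, 1),
    applies_to = c("per_dosimeter", "per_dosimeter", "per_substructure",
                   "global", "global")
  )
}

check_components <- function(components) {
  if (!is.data.frame(components) ||
      !all(c("component", "relative_1sd_pct", "applies_to") %in%
           names(components))) {
    abort(paste("`components` must be a data frame with columns component,",
                "relative_1sd_pct, applies_to."))
  }
  ok <- components$applies_to %in%
    c("per_dosimeter", "per_substructure", "global")
  if (!all(ok)) {
    abort(paste0("Unknown `applies_to` level(s): ",
                 paste(unique(components$applies_to[!ok]), collapse = ", "),
                 " (expected per_dosimeter, per_substructure or global)."))
  }
  if (any(components$relative_1sd_pct < 0)) {
    abort("Relative uncertainties must be non-negative.")
  }
  as_tibble(components)
}

#' Read / write uncertainty components as YAML
#'
#' Schema: `components: [{component, relative_1sd_pct, applies_to}]`.
#'
#' @param path File path.
#' @param components A components table as from
#'   [default_uncertainty_components()].
#' @return The reader returns the components tibble; the writer returns
#'   `path` invisibly.
#' @export
read_uncertainty_components <- function(path) {
  if (!file.exists(path)) abort(paste0("Budget file not found: ", path))
  x <- yaml::read_yaml(path)
  check_components(purrr::map_dfr(x$components, as_tibble))
}

#' @rdname read_uncertainty_components
#' @export
write_uncertainty_components <- function(components, path) {
  components <- check_components(components)
  yaml::write_yaml(
    list(components = purrr::map(seq_len(nrow(components)), function(i) {
      as.list(components[i, ])
    })),
    path, precision = 12L
  )
  invisible(path)
}

# Normalise the many accepted type-A input shapes to a lookup function
# (protocol_id, dosimeter_id) -> percent.
type_a_lookup <- function(type_a) {
  if (is.null(type_a)) {
    return(function(protocol, dosimeter) 0)
  }
  if (is.numeric(type_a) && length(type_a) == 1) {
    return(function(protocol, dosimeter) type_a)
  }
  if (is.numeric(type_a) && !is.null(names(type_a))) {
    return(function(protocol, dosimeter) {
      val <- type_a[as.character(dosimeter)]
      if (any(is.na(val))) {
        abort(paste0("No type A value for dosimeter(s) ",
                     paste(dosimeter[is.na(val)], collapse = ", "), "."))
      }
      unname(val)
    })
  }
  if (is.data.frame(type_a)) {
    if (!all(c("dosimeter_id", "type_a_pct") %in% names(type_a))) {
      abort("Type A data frame needs columns dosimeter_id and type_a_pct.")
    }
    has_protocol <- "protocol_id" %in% names(type_a)
    return(function(protocol, dosimeter) {
      tab <- type_a
      if (has_protocol) tab <- tab[tab$protocol_id == protocol, ]
      val <- tab$type_a_pct[match(dosimeter, tab$dosimeter_id)]
      if (any(is.na(val))) {
        abort(paste0("No type A value for protocol '", protocol,
                     "', dosimeter(s) ",
                     paste(dosimeter[is.na(val)], collapse = ", "), "."))
      }
      val
    })
  }
  abort("`type_a` must be NULL, a single percent, a named vector or a data frame.")
}

#' Estimate per-dosimeter type A uncertainties from replicate readings
#'
#' Applies [type_a_uncertainty()] to every (protocol, dosimeter) replicate
#' set in a readings table.
#'
#' @inheritParams collapse_readings
#' @param of_mean Passed to [type_a_uncertainty()].
#' @return A tibble `protocol_id`, `dosimeter_id`, `n`, `type_a_pct`.
#' @export
type_a_from_readings <- function(readings, of_mean = TRUE) {
  readings <- check_readings(readings)
  readings |>
    group_by(.data$protocol_id, .data$dosimeter_id) |>
    summarise(n = dplyr::n(),
              type_a_pct = type_a_uncertainty(.data$absorbed_dose_mGy,
                                              of_mean = of_mean),
              .groups = "drop")
}

#' Propagate uncertainties to the effective dose
#'
#' Combined relative uncertainty of each protocol's effective dose as a
#' weighted sum of variances, built tissue by tissue. Per dosimeter, type A
#' scatter and the `per_dosimeter` systematic components combine in
#' quadrature to `u_d`. Per tissue, the dosimeter uncertainties aggregate by
#' quadrature weighted by each dosimeter's share of the tissue's equivalent
#' dose, and the `per_substructure` components (the f_i estimate) by the
#' squared within-tissue sub-structure shares, giving `u_T`. At the
#' effective-dose level, `u_E^2 = sum_T share_T^2 * u_T^2` plus the squared
#' `global` components, where `share_T` is the tissue's contribution share of
#' the effective dose. The expanded uncertainty uses coverage factor k = 2.
#'
#' @inheritParams equivalent_doses
#' @param type_a Per-dosimeter type A relative uncertainties in percent: a
#'   single number, a vector named by dosimeter id, a data frame with columns
#'   `dosimeter_id`, `type_a_pct` (optionally `protocol_id`), or `NULL` (no
#'   replicate scatter). When `readings` carries >= 2 replicates per dosimeter
#'   and `type_a` is `NULL`, it is estimated with [type_a_from_readings()].
#' @param components Systematic components table; default
#'   [default_uncertainty_components()].
#' @param coverage_factor Multiplier for the expanded uncertainty; default 2.
#' @return A tibble with one row per protocol: `protocol_id`,
#'   `dosimeter_var`, `substructure_var`, `global_var` (squared-percent
#'   variance contributions), `combined_1sd_pct` and `expanded_pct`
#'   (`coverage_factor * combined_1sd_pct`, exact).
#' @examples
#' effective_dose_uncertainty(elbow_readings(), elbow_tissue_map(),
#'                            type_a = 30 / sqrt(10))
#' @export
effective_dose_uncertainty <- function(readings, tissue_map, type_a = NULL,
                                       components =
                                         default_uncertainty_components(),
                                       coverage_factor = 2) {
  components <- check_components(components)
  readings <- check_readings(readings)
  if (is.null(type_a)) {
    counts <- readings |>
      dplyr::count(.data$protocol_id, .data$dosimeter_id)
    if (all(counts$n >= 2)) type_a <- type_a_from_readings(readings)
  }
  lookup <- type_a_lookup(type_a)

  per_dosim_b <- components$relative_1sd_pct[
    components$applies_to == "per_dosimeter"]
  per_sub_b <- combine_quadrature(
    components$relative_1sd_pct[components$applies_to == "per_substructure"])
  global_b <- combine_quadrature(
    components$relative_1sd_pct[components$applies_to == "global"])

  terms <- engine_terms(readings, tissue_map)

  purrr::map_dfr(unique(terms$protocol_id), function(p) {
    tt <- filter(terms, .data$protocol_id == p)
    total <- sum(tt$weighted_term_uSv)
    if (total <= 0) {
      abort(paste0("Effective dose for protocol '", p,
                   "' is zero; relative uncertainty is undefined."))
    }
    tissues <- purrr::map_dfr(unique(tt$organ), function(org) {
      ot <- filter(tt, .data$organ == org)
      h_t <- sum(ot$term_uSv)
      # dosimeter share of the tissue's equivalent dose (summed across the
      # tissue's sub-structures: the same physical dosimeter is one error
      # source within a tissue)
      dosim <- ot |>
        group_by(.data$dosimeter_id) |>
        summarise(w = sum(.data$term_uSv) / h_t, .groups = "drop") |>
        mutate(u_pct = purrr::map_dbl(.data$dosimeter_id, function(d) {
          combine_quadrature(c(lookup(p, d), per_dosim_b))
        }))
      subs <- ot |>
        group_by(.data$substructure) |>
        summarise(w = sum(.data$term_uSv) / h_t, .groups = "drop")
      tibble(
        organ = org,
        share = sum(ot$weighted_term_uSv) / total,
        u_dosim_sq = sum(dosim$w^2 * dosim$u_pct^2),
        u_frac_sq = sum(subs$w^2) * per_sub_b^2
      )
    })
    if (abs(sum(tissues$share) - 1) > 1e-3) {
      abort("Internal error: tissue contribution shares do not sum to 1.")
    }
    dosimeter_var <- sum(tissues$share^2 * tissues$u_dosim_sq)
    substructure_var <- sum(tissues$share^2 * tissues$u_frac_sq)
    global_var <- global_b^2
    combined <- sqrt(dosimeter_var + substructure_var + global_var)
    tibble(
      protocol_id = p, dosimeter_var = dosimeter_var,
      substructure_var = substructure_var, global_var = global_var,
      combined_1sd_pct = combined,
      expanded_pct = coverage_factor * combined
    )
  })
}
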