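# Dose engine: equivalent doses per organ, ICRP-weighted contributions,
# effective dose and derived comparison metrics.
#
# Equivalent dose of tissue T:  H_T = w_R * sum_i f_i * D_Ti   (mGy -> uSv)
# where D_Ti is the mean absorbed dose of the dosimeters assigned to
# sub-structure i and f_i its irradiated mass fraction.
# Effective dose:               E = sum_T w_T * H_T
# with the remainder weight shared equally over the ICRP remainder organs.

# Join collapsed readings onto the flattened tissue map, one row per
# (protocol, organ, sub-structure, dosimeter) term. Errors on dosimeters the
# map references but the readings lack.
engine_terms <- function(readings, map) {
  stopifnot(inherits(map, "tissue_map"))
  doses <- collapse_readings(readings)
  flat <- tidy(map)

  missing <- flat |>
    distinct(.data$organ, .data$dosimeter_id) |>
    tidyr::crossing(protocol_id = unique(doses$protocol_id)) |>
    anti_join(doses, by = c("protocol_id", "dosimeter_id"))
  if (nrow(missing) > 0) {
    first <- missing[1, ]
    abort(paste0(
      "Tissue map references dosimeter(s) absent from the readings: organ '",
      first$organ, "' needs dosimeter #", first$dosimeter_id,
      " for protocol '", first$protocol_id, "' (",
      nrow(missing), " missing assignment(s) in total)."
    ))
  }

  flat |>
    left_join(select(doses, "protocol_id", "dosimeter_id", "dose_mGy"),
              by = "dosimeter_id", relationship = "many-to-many") |>
    mutate(
      effective_weight = ifelse(.data$is_remainder,
                                .data$w_T / map$remainder_organ_count,
                                .data$w_T),
      # one dosimeter's share of the sub-structure mean, in uSv
      term_uSv = map$w_R * 1000 * .data$f_i * .data$dose_mGy /
        .data$n_dosimeters,
      weighted_term_uSv = .data$effective_weight * .data$term_uSv
    )
}

#' Equivalent doses and weighted contributions per organ
#'
#' For each protocol and organ, computes the equivalent dose
#' `H_T = w_R * sum over sub-structures of f_i * mean(assigned dosimeter
#' doses)` (converted from mGy to uSv) and its contribution to the effective
#' dose, `w_T * H_T` for ordinary organs and `(w_remainder / n_remainder) *
#' H_T` for remainder organs.
#'
#' @inheritParams collapse_readings
#' @param tissue_map A [tissue_map()].
#' @return A tibble with one row per protocol and organ: `protocol_id`,
#'   `organ`, `w_T`, `is_remainder`, `effective_weight`,
#'   `equivalent_dose_uSv`, `contribution_uSv`.
#' @examples
#' equivalent_doses(elbow_readings(), elbow_tissue_map())
#' @export
equivalent_doses <- function(readings, tissue_map) {
  engine_terms(readings, tissue_map) |>
    group_by(.data$protocol_id, .data$organ) |>
    summarise(
      w_T = dplyr::first(.data$w_T),
      is_remainder = dplyr::first(.data$is_remainder),
      effective_weight = dplyr::first(.data$effective_weight),
      equivalent_dose_uSv = sum(.data$term_uSv),
      contribution_uSv = sum(.data$weighted_term_uSv),
      .groups = "drop"
    )
}

#' Effective dose per protocol
#'
#' Runs the full ICRP 103 computation: equivalent doses per organ, weighted
#' contributions (remainder weight shared over
#' `tissue_map$remainder_organ_count` organs), their sum — the effective dose —
#' per-organ contribution percentages, and, when protocol metadata with an
#' `mAs` column is supplied, the mAs-normalised effective dose.
#'
#' @inheritParams equivalent_doses
#' @param protocols Optional data frame of protocol metadata with columns
#'   `protocol_id` and `mAs` (see [elbow_protocols()]). Protocols without a
#'   usable `mAs` get `NA` normalised dose.
#' @return An object of class `effective_dose_result`. [tidy()] returns the
#'   per-organ table (with contribution percentages), [glance()] the
#'   per-protocol summary (`effective_dose_uSv`, `normalized_uSv_per_mAs`,
#'   `mean_absorbed_mGy`), [autoplot()] a stacked contribution chart.
#' @examples
#' res <- effective_dose(elbow_readings(), elbow_tissue_map(), elbow_protocols())
#' glance(res)
#' tidy(res)
#' @export
effective_dose <- function(readings, tissue_map, protocols = NULL) {
  organs <- equivalent_doses(readings, tissue_map)

  summary <- organs |>
    group_by(.data$protocol_id) |>
    summarise(effective_dose_uSv = sum(.data$contribution_uSv),
              .groups = "drop")

  if (any(summary$effective_dose_uSv == 0)) {
    warn(paste(
      "Effective dose is zero for protocol(s):",
      paste(summary$protocol_id[summary$effective_dose_uSv == 0],
            collapse = ", "),
      "- contribution percentages reported as NA."
    ))
  }

  organs <- organs |>
    left_join(summary, by = "protocol_id") |>
    mutate(contribution_pct = ifelse(
      .data$effective_dose_uSv > 0,
      100 * .data$contribution_uSv / .data$effective_dose_uSv, NA_real_
    )) |>
    select(-"effective_dose_uSv")

  summary <- summary |>
    left_join(mean_absorbed_dose(readings), by = "protocol_id")

  if (!is.null(protocols) && "mAs" %in% names(protocols)) {
    summary <- summary |>
      left_join(select(protocols, "protocol_id", "mAs"), by = "protocol_id") |>
      mutate(normalized_uSv_per_mAs = ifelse(
        !is.na(.data$mAs) & .data$mAs > 0,
        .data$effective_dose_uSv / .data$mAs, NA_real_
      ))
  } else {
    summary$mAs <- NA_real_
    summary$normalized_uSv_per_mAs <- NA_real_
  }

  structure(
    list(organs = organs, summary = summary, tissue_map = tissue_map,
         protocols = protocols, doses = collapse_readings(readings)),
    class = "effective_dose_result"
  )
}

#' @export
print.effective_dose_result <- function(x, digits = 1, ...) {
  cat("<effective_dose_result>", nrow(x$summary), "protocol(s),",
      length(unique(x$organs$organ)), "organs\n")
  out <- x$summary |>
    mutate(effective_dose_uSv = round(.data$effective_dose_uSv, digits))
  print(out)
  invisible(x)
}

#' @rdname effective_dose
#' @param x,object An `effective_dose_result`.
#' @param ... Unused.
#' @method tidy effective_dose_result
#' @export
tidy.effective_dose_result <- function(x, ...) x$organs

#' @rdname effective_dose
#' @method glance effective_dose_result
#' @export
glance.effective_dose_result <- function(x, ...) x$summary

#' @rdname effective_dose
#' @method autoplot effective_dose_result
#' @export
autoplot.effective_dose_result <- function(object, ...) {
  ggplot2::ggplot(
    object$organs,
    ggplot2::aes(x = .data$protocol_id, y = .data$contribution_uSv,
                 fill = .data$organ)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "Contribution to effective dose (µSv)",
      fill = "Organ",
      title = "Effective dose composition by protocol"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

# Derived comparison metrics --------------------------------------------------

#' Mean absorbed organ dose per protocol
#'
#' Arithmetic mean of the per-dosimeter absorbed doses (replicates averaged,
#' sub-exposures summed first).
#'
#' @inheritParams collapse_readings
#' @return A tibble with `protocol_id` and `mean_absorbed_mGy`.
#' @examples
#' mean_absorbed_dose(elbow_readings())
#' @export
mean_absorbed_dose <- function(readings) {
  collapse_readings(readings) |>
    group_by(.data$protocol_id) |>
    summarise(mean_absorbed_mGy = mean(.data$dose_mGy), .groups = "drop")
}

#' Dose ratios against a baseline protocol
#'
#' Divides a per-protocol dose column by its value for a baseline protocol
#' (typically the conventional radiography examination). The baseline's ratio
#' is exactly 1.
#'
#' @param data A data frame with a `protocol_id` column, e.g.
#'   `glance(effective_dose(...))` or [elbow_published_doses()].
#' @param baseline Protocol id of the comparison baseline.
#' @param value Column to take ratios of (tidy-eval); default
#'   `effective_dose_uSv`.
#' @return `data` with an added `dose_ratio` column.
#' @examples
#' elbow_published_doses() |> dose_ratios("shimadzu_fh21")
#' @export
dose_ratios <- function(data, baseline, value = "effective_dose_uSv") {
  if (!is.data.frame(data) || !"protocol_id" %in% names(data)) {
    abort("`data` must be a data frame with a `protocol_id` column.")
  }
  value <- rlang::as_name(rlang::enquo(value))
  if (!value %in% names(data)) {
    abort(paste0("Column '", value, "' not found in `data`."))
  }
  idx <- which(data$protocol_id == baseline)
  if (length(idx) != 1) {
    abort(paste0("Baseline protocol '", baseline,
                 "' must appear exactly once in `data`."))
  }
  base <- data[[value]][idx]
  if (!is.finite(base) || base == 0) {
    abort(paste0("Baseline dose for '", baseline,
                 "' is zero or non-finite; ratios are undefined."))
  }
  mutate(data, dose_ratio = .data[[value]] / base)
}

#' Pearson correlation between two dose-ratio vectors
#'
#' Used to compare how effective-dose ratios and mean-absorbed-dose ratios
#' rank the protocols. Pearson product-moment correlation; errors on constant
#' or short input rather than returning NA.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single number in `[-1, 1]`.
#' @export
ratio_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("At least 3 paired ratios are required.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Ratio vectors must be finite.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a constant ratio vector.")
  }
  cor(x, y)
}

#' Mean effective-dose difference between two protocol groups
#'
#' `mean(E over group_a) - mean(E over group_b)`, also expressed as days of
#' natural background radiation at a configurable annual background dose.
#'
#' @param data A data frame with `protocol_id` and a dose column.
#' @param group_a,group_b Character vectors of protocol ids; both non-empty.
#' @param value Dose column (tidy-eval); default `effective_dose_uSv`.
#' @param background_mSv_per_year Annual background dose used for the
#'   day-equivalent; default 3.1 mSv/yr.
#' @return A one-row tibble: `mean_a_uSv`, `mean_b_uSv`, `difference_uSv`,
#'   `background_days`.
#' @examples
#' res <- effective_dose(elbow_readings(), elbow_tissue_map())
#' cbct <- elbow_protocol_ids()[3:7]
#' dose_difference(glance(res), "siemens_sensation", cbct)
#' @export
dose_difference <- function(data, group_a, group_b,
                            value = "effective_dose_uSv",
                            background_mSv_per_year = 3.1) {
  value <- rlang::as_name(rlang::enquo(value))
  if (!is.data.frame(data) ||
      !all(c("protocol_id", value) %in% names(data))) {
    abort(paste0("`data` must contain columns protocol_id and ", value, "."))
  }
  unknown <- setdiff(c(group_a, group_b), data$protocol_id)
  if (length(unknown) > 0) {
    abort(paste0("Unknown protocol id(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("Both protocol groups must be non-empty.")
  }
  mean_a <- mean(data[[value]][data$protocol_id %in% group_a])
  mean_b <- mean(data[[value]][data$protocol_id %in% group_b])
  diff_uSv <- mean_a - mean_b
  tibble(
    mean_a_uSv = mean_a, mean_b_uSv = mean_b, difference_uSv = diff_uSv,
    background_days = diff_uSv / (background_mSv_per_year * 1000) * 365.25
  )
}
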