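# Readers, writers, report assembly. One flat readings CSV spans all
# protocols so a multi-device comparison is a single run; protocol metadata
# travels separately as JSON.

#' Read / write dosimeter readings as CSV
#'
#' Expected columns: `protocol_id, exposure_id, dosimeter_id, layer, location,
#' replicate, absorbed_dose_mGy` (header required; `exposure_id`, `layer`,
#' `location` and `replicate` may be omitted). Rows are validated and
#' duplicate (protocol, exposure, dosimeter, replicate) records rejected.
#'
#' @param path File path.
#' @param readings A readings tibble.
#' @return `read_readings()` returns a validated readings tibble;
#'   `write_readings()` returns `path` invisibly.
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) abort(paste0("Readings file not found: ", path))
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Failed to parse ", path, ": ",
                                     conditionMessage(e)))
  )
  if (nrow(out) == 0) {
    abort(paste0("Readings file ", path, " contains no data rows."))
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed readings in ", path, " at line(s) ",
                 paste(unique(probs$row), collapse = ", "), "."))
  }
  check_readings(out)
}

#' @rdname read_readings
#' @export
write_readings <- function(readings, path) {
  readings <- check_readings(readings)
  readr::write_csv(readings, path)
  invisible(path)
}

#' Read / write protocol metadata as JSON
#'
#' An array of objects with at least `protocol_id`; typically also `device`,
#' `modality`, `kVp`, `mAs`, `fov` and dose indices.
#'
#' @param path File path.
#' @param protocols A protocols tibble, e.g. [elbow_protocols()].
#' @return The reader returns a tibble; the writer returns `path` invisibly.
#' @export
read_protocols <- function(path) {
  if (!file.exists(path)) abort(paste0("Protocol file not found: ", path))
  as_tibble(jsonlite::fromJSON(path))
}

#' @rdname read_protocols
#' @export
write_protocols <- function(protocols, path) {
  jsonlite::write_json(protocols, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full dosimetry pipeline
#'
#' Readings + tissue map (+ protocol metadata, uncertainty components) in;
#' per-protocol effective doses, dose ratios against a baseline, the
#' effective-vs-absorbed ratio correlation, modality group differences and an
#' uncertainty budget out. Every input can be given as an in-memory object or
#' a file path (CSV readings, YAML tissue map / budget, JSON protocols).
#'
#' @param readings Readings tibble or CSV path.
#' @param tissue_map A [tissue_map()] or YAML path.
#' @param protocols Optional protocols tibble or JSON path.
#' @param baseline Protocol id used for dose ratios; defaults to the first
#'   radiography protocol in `protocols`, else the first protocol.
#' @param components Uncertainty components table or YAML path; default
#'   [default_uncertainty_components()].
#' @param type_a Passed to [effective_dose_uncertainty()]. When `NULL` and the
#'   readings carry fewer than 2 replicates, the uncertainty budget reflects
#'   systematic components only.
#' @param background_mSv_per_year Annual background dose for day-equivalents.
#' @param out_dir If given, the report is written there as `report.json`
#'   (full precision) plus rounded CSV tables `effective_doses.csv` and
#'   `absorbed_doses.csv`.
#' @param rounding Decimals for the CSV tables; default 1.
#' @return An object of class `dose_report`: a list with `result` (the
#'   [effective_dose()] object), `summary` (per-protocol tibble incl. ratios
#'   and uncertainties), `organs`, `uncertainty`, `correlation`,
#'   `group_difference` (MSCT vs CBCT when modalities allow, else `NULL`),
#'   and `baseline`.
#' @examples
#' fx <- paper_fixture()
#' rep <- run_pipeline(fx$readings, fx$tissue_map, fx$protocols)
#' rep$summary
#' @export
run_pipeline <- function(readings, tissue_map, protocols = NULL,
                         baseline = NULL,
                         components = default_uncertainty_components(),
                         type_a = NULL, background_mSv_per_year = 3.1,
                         out_dir = NULL, rounding = 1) {
  readings <- resolve_input(readings, read_readings)
  tissue_map <- resolve_input(tissue_map, read_tissue_map)
  protocols <- resolve_input(protocols, read_protocols)
  components <- resolve_input(components, read_uncertainty_components)

  result <- effective_dose(readings, tissue_map, protocols)
  summary <- glance(result)

  if (is.null(baseline)) {
    baseline <- if (!is.null(protocols) && "modality" %in% names(protocols) &&
                    any(protocols$modality == "radiography")) {
      protocols$protocol_id[protocols$modality == "radiography"][1]
    } else {
      summary$protocol_id[1]
    }
  }

  correlation <- NULL
  base_e <- summary$effective_dose_uSv[summary$protocol_id == baseline]
  base_m <- summary$mean_absorbed_mGy[summary$protocol_id == baseline]
  if (length(base_e) == 1 && base_e > 0) {
    summary <- dose_ratios(summary, baseline)
    if (nrow(summary) >= 3 && base_m > 0) {
      absorbed <- dose_ratios(summary, baseline,
                              value = "mean_absorbed_mGy") |>
        pull(.data$dose_ratio)
      if (sd(summary$dose_ratio) > 0 && sd(absorbed) > 0) {
        correlation <- ratio_correlation(summary$dose_ratio, absorbed)
      }
    }
  } else {
    warn(paste0("Baseline protocol '", baseline,
                "' has zero effective dose; dose ratios reported as absent."))
  }

  uncertainty <- NULL
  if (all(summary$effective_dose_uSv > 0)) {
    uncertainty <- effective_dose_uncertainty(readings, tissue_map,
                                              type_a = type_a,
                                              components = components)
    summary <- left_join(
      summary,
      select(uncertainty, "protocol_id", "combined_1sd_pct", "expanded_pct"),
      by = "protocol_id"
    )
  } else {
    warn("Zero effective dose present; uncertainty budget skipped.")
  }

  group_difference <- NULL
  if (!is.null(protocols) && "modality" %in% names(protocols)) {
    msct <- protocols$protocol_id[protocols$modality == "MSCT"]
    cbct <- protocols$protocol_id[protocols$modality == "CBCT"]
    if (length(msct) > 0 && length(cbct) > 0 &&
        all(c(msct, cbct) %in% summary$protocol_id)) {
      group_difference <- dose_difference(
        summary, msct, cbct,
        background_mSv_per_year = background_mSv_per_year
      )
    }
  }

  report <- structure(
    list(result = result, summary = summary, organs = tidy(result),
         uncertainty = uncertainty, correlation = correlation,
         group_difference = group_difference, baseline = baseline),
    class = "dose_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir, rounding = rounding)
  report
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report> baseline:", x$baseline, "\n")
  print(x$summary)
  if (!is.null(x$correlation)) {
    cat("effective vs absorbed ratio correlation:",
        format(x$correlation, digits = 6), "\n")
  }
  if (!is.null(x$group_difference)) {
    cat("MSCT - mean CBCT difference:",
        round(x$group_difference$difference_uSv, 1), "uSv (",
        round(x$group_difference$background_days, 1),
        "days of background )\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' `report.json` carries the full-precision tables; the CSV tables mirror the
#' presentation layout (tissues as rows, protocols as columns) rounded to
#' `rounding` decimals.
#'
#' @param report A `dose_report` from [run_pipeline()].
#' @param out_dir Output directory, created if missing.
#' @param rounding Decimals for the CSV tables.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, rounding = 1) {
  stopifnot(inherits(report, "dose_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    baseline = report$baseline,
    summary = report$summary,
    organs = report$organs,
    uncertainty = report$uncertainty,
    correlation = report$correlation,
    group_difference = report$group_difference
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  readr::write_csv(render_dose_table(report, "effective", rounding),
                   file.path(out_dir, "effective_doses.csv"))
  readr::write_csv(render_dose_table(report, "absorbed", rounding),
                   file.path(out_dir, "absorbed_doses.csv"))
  invisible(out_dir)
}

#' Render presentation tables from a report
#'
#' `what = "effective"`: tissues as rows, protocols as columns, with summary
#' rows for the effective dose, the mAs-normalised dose (one extra decimal)
#' and the dose ratio. `what = "absorbed"`: per-dosimeter absorbed doses with
#' mean-dose and ratio rows.
#'
#' @param report A `dose_report`.
#' @param what `"effective"` or `"absorbed"`.
#' @param rounding Decimals; default 1 (the normalised-dose row uses one
#'   more).
#' @return A tibble in presentation layout.
#' @export
render_dose_table <- function(report, what = c("effective", "absorbed"),
                              rounding = 1) {
  stopifnot(inherits(report, "dose_report"))
  what <- match.arg(what)
  protocols <- report$summary$protocol_id
  if (what == "effective") {
    body <- report$organs |>
      mutate(value = round(.data$contribution_uSv, rounding)) |>
      select("organ", "protocol_id", "value") |>
      tidyr::pivot_wider(names_from = "protocol_id",
                         values_from = "value") |>
      rename(row = "organ")
    summary_rows <- tibble(row = c("effective_dose_uSv",
                                   "normalized_uSv_per_mAs", "dose_ratio"))
    for (p in protocols) {
      s <- report$summary[report$summary$protocol_id == p, ]
      summary_rows[[p]] <- c(
        round(s$effective_dose_uSv, rounding),
        round(s$normalized_uSv_per_mAs %||% NA_real_, rounding + 1),
        if ("dose_ratio" %in% names(s)) round(s$dose_ratio, rounding)
        else NA_real_
      )
    }
    bind_rows(body, summary_rows)
  } else {
    body <- report$result$doses |>
      mutate(value = round(.data$dose_mGy, rounding)) |>
      select("dosimeter_id", "protocol_id", "value") |>
      tidyr::pivot_wider(names_from = "protocol_id", values_from = "value") |>
      mutate(row = paste0("dosimeter_", .data$dosimeter_id)) |>
      select(-"dosimeter_id") |>
      select("row", dplyr::everything())
    means <- report$summary
    mean_row <- tibble(row = "mean_absorbed_mGy")
    ratio_row <- tibble(row = "absorbed_dose_ratio")
    base_mean <- means$mean_absorbed_mGy[
      means$protocol_id == report$baseline]
    for (p in protocols) {
      m <- means$mean_absorbed_mGy[means$protocol_id == p]
      mean_row[[p]] <- round(m, rounding)
      ratio_row[[p]] <- if (length(base_mean) == 1 && base_mean > 0) {
        round(m / base_mean, rounding)
      } else {
        NA_real_
      }
    }
    bind_rows(body, mean_row, ratio_row)
  }
}
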