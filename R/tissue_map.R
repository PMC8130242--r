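# Tissue map: which organs the field of view touches, how much of each organ
# mass is irradiated (f_i), which dosimeters sample it, and the ICRP 103
# weights used to fold equivalent doses into an effective dose.

#' Build a tissue map
#'
#' A tissue map holds everything the equivalent/effective dose equations need
#' besides the readings: per-organ ICRP 103 tissue weighting factors `w_T`,
#' remainder flags, and per-sub-structure irradiated mass fractions `f_i`
#' together with the dosimeters assigned to each sub-structure. Remainder
#' organs (muscle, lymphatic nodes, ...) share the collective remainder weight
#' equally over `remainder_organ_count` organs, the ICRP 103 convention being
#' 13.
#'
#' @param organs A data frame with columns `organ` (character), `w_T`
#'   (positive numeric), `is_remainder` (logical) and `substructures`, a
#'   list-column of data frames with columns `name`, `f_i` (fractions in
#'   (0, 1], e.g. 0.0019 for 0.19%) and `dosimeters` (list-column of integer
#'   dosimeter ids).
#' @param w_R Radiation weighting factor in Sv/Gy; 1 for photons.
#' @param remainder_organ_count Number of ICRP remainder organs sharing the
#'   remainder weight. Default 13.
#' @return An object of class `tissue_map`.
#' @seealso [elbow_tissue_map()] for a complete worked example,
#'   [read_tissue_map()] / [write_tissue_map()] for YAML serialisation.
#' @export
tissue_map <- function(organs, w_R = 1, remainder_organ_count = 13L) {
  if (!is.data.frame(organs) ||
      !all(c("organ", "w_T", "is_remainder", "substructures") %in% names(organs))) {
    abort(paste("`organs` must be a data frame with columns organ, w_T,",
                "is_remainder, substructures."))
  }
  if (!is.numeric(w_R) || length(w_R) != 1 || w_R <= 0) {
    abort("`w_R` must be a single positive number (Sv/Gy).")
  }
  remainder_organ_count <- as.integer(remainder_organ_count)
  if (is.na(remainder_organ_count) || remainder_organ_count <= 0) {
    abort("`remainder_organ_count` must be a positive integer.")
  }
  organs <- as_tibble(organs)
  if (any(!is.finite(organs$w_T)) || any(organs$w_T <= 0)) {
    abort("Every organ must have a positive tissue weighting factor `w_T`.")
  }
  if (anyDuplicated(organs$organ)) {
    abort("Organ names in a tissue map must be unique.")
  }
  for (i in seq_len(nrow(organs))) {
    subs <- organs$substructures[[i]]
    org <- organs$organ[[i]]
    if (!is.data.frame(subs) || nrow(subs) == 0) {
      abort(paste0("Organ '", org, "' has no sub-structures; at least one ",
                   "(name, f_i, dosimeters) entry is required."))
    }
    if (!all(c("name", "f_i", "dosimeters") %in% names(subs))) {
      abort(paste0("Sub-structures of organ '", org,
                   "' need columns name, f_i, dosimeters."))
    }
    if (any(!is.finite(subs$f_i)) || any(subs$f_i <= 0) || any(subs$f_i > 1)) {
      abort(paste0("Irradiated fractions f_i of organ '", org,
                   "' must lie in (0, 1] (stored as fractions, not percent)."))
    }
    for (j in seq_len(nrow(subs))) {
      ids <- subs$dosimeters[[j]]
      if (length(ids) == 0 || any(is.na(ids))) {
        abort(paste0("Sub-structure '", subs$name[[j]], "' of organ '", org,
                     "' must list at least one dosimeter id."))
      }
    }
    organs$substructures[[i]] <- as_tibble(subs)
  }
  structure(
    list(w_R = w_R, remainder_organ_count = remainder_organ_count,
         organs = organs),
    class = "tissue_map"
  )
}

#' @export
print.tissue_map <- function(x, ...) {
  flat <- tidy(x)
  cat("<tissue_map> w_R =", x$w_R, "Sv/Gy,", nrow(x$organs), "organs,",
      nrow(flat), "sub-structure/dosimeter assignments\n")
  cat("remainder weight shared over", x$remainder_organ_count, "organs\n")
  print(flat, n = 8)
  invisible(x)
}

#' Flatten a tissue map to one row per sub-structure/dosimeter assignment
#'
#' @param x A [tissue_map()].
#' @param ... Unused.
#' @return A tibble with columns `organ`, `w_T`, `is_remainder`,
#'   `substructure`, `f_i`, `dosimeter_id`, `n_dosimeters` (dosimeters sharing
#'   the sub-structure).
#' @method tidy tissue_map
#' @export
tidy.tissue_map <- function(x, ...) {
  purrr::map2_dfr(x$organs$organ, seq_len(nrow(x$organs)), function(org, i) {
    row <- x$organs[i, ]
    subs <- row$substructures[[1]]
    purrr::map_dfr(seq_len(nrow(subs)), function(j) {
      ids <- as.integer(subs$dosimeters[[j]])
      tibble(
        organ = org, w_T = row$w_T, is_remainder = row$is_remainder,
        substructure = subs$name[[j]], f_i = subs$f_i[[j]],
        dosimeter_id = ids, n_dosimeters = length(ids)
      )
    })
  })
}

#' @rdname tidy.tissue_map
#' @method glance tissue_map
#' @export
glance.tissue_map <- function(x, ...) {
  flat <- tidy(x)
  tibble(
    n_organs = nrow(x$organs),
    n_substructures = nrow(distinct(flat, .data$organ, .data$substructure)),
    n_dosimeters = length(unique(flat$dosimeter_id)),
    w_R = x$w_R,
    remainder_organ_count = x$remainder_organ_count
  )
}

# YAML serialisation -----------------------------------------------------------

tissue_map_to_list <- function(map) {
  list(
    w_R = map$w_R,
    remainder_organ_count = map$remainder_organ_count,
    organs = purrr::map(seq_len(nrow(map$organs)), function(i) {
      row <- map$organs[i, ]
      subs <- row$substructures[[1]]
      list(
        organ = row$organ,
        w_T = row$w_T,
        is_remainder = row$is_remainder,
        substructures = purrr::map(seq_len(nrow(subs)), function(j) {
          list(name = subs$name[[j]], f_i = subs$f_i[[j]],
               dosimeters = as.integer(subs$dosimeters[[j]]))
        })
      )
    })
  )
}

list_to_tissue_map <- function(x) {
  organs <- purrr::map_dfr(x$organs, function(o) {
    tibble(
      organ = o$organ, w_T = o$w_T, is_remainder = isTRUE(o$is_remainder),
      substructures = list(purrr::map_dfr(o$substructures, function(s) {
        tibble(name = s$name, f_i = s$f_i,
               dosimeters = list(as.integer(unlist(s$dosimeters))))
      }))
    )
  })
  tissue_map(organs, w_R = x$w_R,
             remainder_organ_count = x$remainder_organ_count)
}

#' Read / write a tissue map as YAML
#'
#' The on-disk schema is
#' `{w_R, remainder_organ_count, organs: [{organ, w_T, is_remainder,
#' substructures: [{name, f_i, dosimeters: [ids]}]}]}`, with `f_i` stored as
#' fractions. The round trip is lossless.
#'
#' @param path File path.
#' @param map A [tissue_map()].
#' @return `read_tissue_map()` returns a `tissue_map`; `write_tissue_map()`
#'   returns `path` invisibly.
#' @export
read_tissue_map <- function(path) {
  if (!file.exists(path)) abort(paste0("Tissue map file not found: ", path))
  list_to_tissue_map(yaml::read_yaml(path))
}

#' @rdname read_tissue_map
#' @export
write_tissue_map <- function(map, path) {
  stopifnot(inherits(map, "tissue_map"))
  yaml::write_yaml(tissue_map_to_list(map), path, precision = 12L)
  invisible(path)
}
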