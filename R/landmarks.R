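#' The eleven pelvic canal landmarks
#'
#' Canonical names, in canonical order, of the 11 three-dimensional
#' landmarks that define the pelvic canal measurements: the paired ischial
#' spines and tuberosities, three sacral points (promontory, the point
#' between S4 and S5, and the S5 apex), the dorsal superior and inferior
#' pubic symphysis, and the paired points of maximum distance between the
#' iliopectineal lines.
#'
#' @return A character vector of length 11.
#' @export
#' @examples
#' pelvic_landmarks()
pelvic_landmarks <- function() {
  c(
    "ischial_spine_L", "ischial_spine_R",
    "ischial_tuberosity_L", "ischial_tuberosity_R",
    "sacral_promontory", "between_S4_S5", "apex_S5",
    "dorsal_sup_pubic_symphysis", "dorsal_inf_pubic_symphysis",
    "max_iliopectineal_L", "max_iliopectineal_R"
  )
}

# left/right pairs of the same structure; used by the coincidence check
.paired_landmarks <- list(
  c("ischial_spine_L", "ischial_spine_R"),
  c("ischial_tuberosity_L", "ischial_tuberosity_R"),
  c("max_iliopectineal_L", "max_iliopectineal_R")
)

.landmark_cols <- c(
  "specimen_id", "observer_id", "replicate_id",
  "landmark", "x_mm", "y_mm", "z_mm"
)

abort_pelvi <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("pelvimetrics_", class), "pelvimetrics_error"), ...)
}

#' Read a long-format landmark table
#'
#' Reads landmark coordinates from CSV or JSON. Both dialects share one
#' schema: one row (or record) per landmark with fields `specimen_id`,
#' `observer_id`, `replicate_id`, `landmark`, `x_mm`, `y_mm`, `z_mm`.
#' Coordinates are in millimetres; no anatomical axis alignment is assumed
#' (all downstream measures are invariant to rigid motion).
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A validated landmark tibble (see [validate_landmarks()]).
#' @seealso [write_landmarks()], [canal_measurements()]
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv  = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    abort_pelvi(
      sprintf("Unsupported landmark file extension '%s' (use csv or json).", ext),
      "schema_error"
    )
  )
  validate_landmarks(as_tibble(df))
}

#' Write a landmark table to CSV or JSON
#'
#' @param landmarks A landmark tibble (long format, one row per landmark).
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- validate_landmarks(landmarks)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv  = utils::write.csv(landmarks, path, row.names = FALSE),
    json = jsonlite::write_json(landmarks, path, digits = NA),
    abort_pelvi(
      sprintf("Unsupported landmark file extension '%s' (use csv or json).", ext),
      "schema_error"
    )
  )
  invisible(path)
}

#' Validate a landmark table
#'
#' Checks the long-format landmark schema and its invariants: required
#' columns present; every (specimen, observer, replicate) configuration has
#' exactly the 11 named landmarks, each once; all coordinates finite; and
#' no left/right pair of the same structure coincides.
#'
#' @param landmarks A data frame in the long landmark schema.
#' @return The validated table as a tibble, landmark factor-ordered.
#' @export
validate_landmarks <- function(landmarks) {
  landmarks <- as_tibble(landmarks)
  missing_cols <- setdiff(.landmark_cols, names(landmarks))
  if (length(missing_cols) > 0) {
    abort_pelvi(
      sprintf("Landmark table is missing column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      "schema_error"
    )
  }
  bad_name <- setdiff(unique(landmarks$landmark), pelvic_landmarks())
  if (length(bad_name) > 0) {
    abort_pelvi(
      sprintf("Unknown landmark name(s): %s.", paste(bad_name, collapse = ", ")),
      "schema_error"
    )
  }
  coords <- as.matrix(landmarks[, c("x_mm", "y_mm", "z_mm")])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    abort_pelvi("Non-finite landmark coordinates.", "invalid_landmark_error")
  }

  per_config <- landmarks %>%
    group_by(specimen_id, observer_id, replicate_id) %>%
    summarise(
      n_lm = dplyr::n(),
      n_unique = dplyr::n_distinct(landmark),
      missing = paste(setdiff(pelvic_landmarks(), landmark), collapse = ", "),
      .groups = "drop"
    )
  bad <- per_config %>% filter(n_lm != 11L | n_unique != 11L)
  if (nrow(bad) > 0) {
    abort_pelvi(
      sprintf(
        "Specimen %s (observer %s, replicate %s) does not have the 11 landmarks exactly once%s.",
        bad$specimen_id[1], bad$observer_id[1], bad$replicate_id[1],
        if (nzchar(bad$missing[1])) paste0("; missing: ", bad$missing[1]) else ""
      ),
      "schema_error"
    )
  }

  # paired landmarks of the same structure must not coincide
  for (pair in .paired_landmarks) {
    wide <- landmarks %>%
      filter(landmark %in% pair) %>%
      tidyr::pivot_wider(
        id_cols = c(specimen_id, observer_id, replicate_id),
        names_from = landmark, values_from = c(x_mm, y_mm, z_mm)
      )
    d <- sqrt(
      (wide[[paste0("x_mm_", pair[1])]] - wide[[paste0("x_mm_", pair[2])]])^2 +
      (wide[[paste0("y_mm_", pair[1])]] - wide[[paste0("y_mm_", pair[2])]])^2 +
      (wide[[paste0("z_mm_", pair[1])]] - wide[[paste0("z_mm_", pair[2])]])^2
    )
    if (any(d < 1e-9)) {
      abort_pelvi(
        sprintf("Paired landmarks %s and %s coincide for specimen %s.",
                pair[1], pair[2], wide$specimen_id[which(d < 1e-9)[1]]),
        "invalid_landmark_error"
      )
    }
  }
  landmarks
}

# extract one 3-vector (named landmark) from a per-configuration coordinate
# matrix built by .config_matrix()
.config_matrix <- function(landmarks_one) {
  m <- as.matrix(landmarks_one[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- landmarks_one$landmark
  m[pelvic_landmarks(), , drop = FALSE]
}
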