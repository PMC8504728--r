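#' Run the full gut–pelvis analysis pipeline
#'
#' Orchestrates the stages end-to-end: landmark measurement, fuzzy-landmark
#' replicate averaging, inter-observer ICC, gut volumetry, and the
#' sex-specific regression report, writing every intermediate artifact as
#' plain CSV/JSON plus a run manifest. With `simulate = TRUE` the inputs
#' are drawn from the synthetic generator; otherwise landmark and cohort
#' tables (and optionally mask files) are read from disk.
#'
#' All stages are pure functions of (inputs, config, seed); re-running with
#' the same config and seed reproduces the same tables.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [generator_config()]; its seed drives all randomness.
#' @param landmarks Optional landmark table (tibble or CSV/JSON path).
#' @param cohort Optional cohort table (tibble or CSV path) with
#'   `specimen_id`, `sex`, `body_weight_kg`, `stature_m` and, unless
#'   `masks` are supplied, `gut_volume_cc`.
#' @param masks Optional named list of [mask_stack()] objects or a
#'   directory of NIfTI masks (file stem = specimen id); volumetry then
#'   supplies `gut_volume_cc`.
#' @param simulate Generate inputs with the synthetic module (default:
#'   TRUE when no landmarks are given).
#' @param n_mask_specimens In simulate mode, how many specimens also get a
#'   synthetic mask stack run through volumetry as an end-to-end check.
#' @return Invisibly, a list with `cohort`, `measurements`, `averaged`,
#'   `icc`, `volumes`, `report`, `relative_weights_table`, `manifest`.
#' @export
run_pipeline <- function(out_dir, cfg = generator_config(),
                         landmarks = NULL, cohort = NULL, masks = NULL,
                         simulate = is.null(landmarks),
                         n_mask_specimens = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)

  if (simulate) {
    cohort_tbl <- simulate_cohort(cfg)
    lm_tbl <- simulate_landmarks(cohort_tbl, cfg)
  } else {
    if (is.character(landmarks)) { inputs <- c(inputs, landmarks); lm_tbl <- read_landmarks(landmarks) }
    else lm_tbl <- validate_landmarks(landmarks)
    if (is.character(cohort)) { inputs <- c(inputs, cohort); cohort_tbl <- as_tibble(utils::read.csv(cohort)) }
    else cohort_tbl <- as_tibble(cohort)
  }

  # stage 1: morphometry
  meas <- canal_measurements(lm_tbl)

  # stage 2: fuzzy-landmark replicate averaging (outlet ML), then a
  # consensus across observers for the analysis cohort
  averaged <- average_fuzzy_replicates(meas)
  consensus <- averaged %>%
    group_by(specimen_id) %>%
    summarise(across(dplyr::all_of(canal_responses()), mean), .groups = "drop")

  # stage 3: observer reliability on the raw per-observer measurements
  ratings <- averaged %>%
    tidyr::pivot_longer(dplyr::all_of(canal_responses()),
                        names_to = "measurement", values_to = "value") %>%
    select(specimen_id, observer_id, replicate_id, measurement, value)
  icc <- icc_report(ratings)

  # stage 4: volumetry
  volumes <- NULL
  if (!is.null(masks)) {
    if (is.character(masks)) {
      paths <- list.files(masks, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
      inputs <- c(inputs, paths)
      masks <- lapply(paths, read_mask_nifti)
    }
    volumes <- purrr::map(masks, gut_volume) %>% list_rbind()
    cohort_tbl <- cohort_tbl %>%
      select(-dplyr::any_of("gut_volume_cc")) %>%
      left_join(volumes %>% select(specimen_id, gut_volume_cc = volume_cc),
                by = "specimen_id")
  } else if (simulate && n_mask_specimens > 0) {
    idx <- head(seq_len(nrow(cohort_tbl)), n_mask_specimens)
    volumes <- purrr::map(idx, function(i) {
      gut_volume(simulate_mask_stack(cohort_tbl$gut_volume_cc[i], cfg,
                                     specimen_id = cohort_tbl$specimen_id[i]))
    }) %>% list_rbind()
  }

  # stage 5: inference on the measured (consensus) canal values
  analysis_cohort <- cohort_tbl %>%
    select(specimen_id, sex, body_weight_kg,
           dplyr::any_of("stature_m"), gut_volume_cc) %>%
    left_join(consensus, by = "specimen_id")
  if (anyNA(analysis_cohort)) {
    missing_row <- analysis_cohort$specimen_id[which(!stats::complete.cases(analysis_cohort))[1]]
    abort_pelvi(sprintf("Incomplete analysis record for specimen %s.", missing_row),
                "schema_error")
  }
  report <- regression_report(analysis_cohort)
  rw_table <- report %>%
    filter(flag_model == "**") %>%
    select(sex, response, rw_gv_pct, rw_weight_pct)

  # write artifacts
  paths <- list(
    landmarks = file.path(out_dir, "landmarks.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    measurements = file.path(out_dir, "measurements.csv"),
    averaged = file.path(out_dir, "measurements_averaged.csv"),
    icc = file.path(out_dir, "icc.csv"),
    volumes = file.path(out_dir, "volumes.csv"),
    report = file.path(out_dir, "regression_report.csv"),
    rw = file.path(out_dir, "relative_weights.csv"),
    json = file.path(out_dir, "report.json")
  )
  utils::write.csv(lm_tbl, paths$landmarks, row.names = FALSE)
  utils::write.csv(cohort_tbl, paths$cohort, row.names = FALSE)
  utils::write.csv(meas, paths$measurements, row.names = FALSE)
  utils::write.csv(averaged, paths$averaged, row.names = FALSE)
  utils::write.csv(icc, paths$icc, row.names = FALSE)
  if (!is.null(volumes)) utils::write.csv(volumes, paths$volumes, row.names = FALSE)
  utils::write.csv(report, paths$report, row.names = FALSE)
  utils::write.csv(rw_table, paths$rw, row.names = FALSE)
  jsonlite::write_json(
    list(icc = icc, regression = report, relative_weights = rw_table),
    paths$json, auto_unbox = TRUE, digits = NA
  )

  out_files <- unlist(paths[file.exists(unlist(paths))], use.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pelvimetrics")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("effects", "templates"))],
    effects = cfg$effects,
    timestamp = format(Sys.time(), tz = "UTC"),
    inputs = lapply(inputs, function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(out_files, function(p) list(path = basename(p),
                                                 md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    cohort = analysis_cohort, measurements = meas, averaged = averaged,
    icc = icc, volumes = volumes, report = report,
    relative_weights_table = rw_table, manifest = manifest
  ))
}
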