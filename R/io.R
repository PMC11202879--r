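# Cohort CSV schemas: long-format grid file and per-eye labels file.

#' Read / write cohort CSV files
#'
#' The grid file is long format with columns `patient_id`, `group`, `eye`
#' (OD|OS), `layer` (GCL|IPL), `row`, `col` (1-8 or 1-4), `thickness_um`,
#' `orientation`; the labels file has one row per eye: `patient_id`,
#' `group`, `eye`, `age`, `on_history`, `vf_defect`, `fixation_loss_pct`,
#' `false_pos_pct`, `false_neg_pct`, `mri_lesion` (none|right|left|NA).
#' Readers validate completeness per eye/layer; writers emit plain
#' comma-separated text.
#'
#' @param path File path.
#' @param grids,labels Tibbles in the schemas above.
#' @param cohort An `hm_cohort` (or compatible list); `write_cohort()`
#'   writes `<stem>_grids.csv`, `<stem>_labels.csv` and `<stem>_params.json`.
#' @param stem Path stem for the cohort bundle.
#' @return Readers return the validated tibble (or for `read_cohort()` a
#'   list with `grids` and `labels`); writers return the path(s) invisibly.
#' @export
read_grid_csv <- function(path) {
  grids <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      group = readr::col_character(),
      eye = readr::col_character(),
      layer = readr::col_character(),
      row = readr::col_integer(),
      col = readr::col_integer(),
      thickness_um = readr::col_double(),
      orientation = readr::col_character()
    )
  )
  check_grid_tbl(grids)
  grids
}

#' @rdname read_grid_csv
#' @export
write_grid_csv <- function(grids, path) {
  check_grid_tbl(grids)
  readr::write_csv(grids, path)
  invisible(path)
}

#' @rdname read_grid_csv
#' @export
read_labels_csv <- function(path) {
  labels <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      group = readr::col_character(),
      eye = readr::col_character(),
      age = readr::col_double(),
      on_history = readr::col_logical(),
      vf_defect = readr::col_logical(),
      fixation_loss_pct = readr::col_double(),
      false_pos_pct = readr::col_double(),
      false_neg_pct = readr::col_double(),
      mri_lesion = readr::col_character()
    )
  )
  ok_lesion <- is.na(labels$mri_lesion) |
    labels$mri_lesion %in% c("none", "right", "left")
  if (!all(ok_lesion)) {
    stop("mri_lesion must be none, right, left, or NA", call. = FALSE)
  }
  labels
}

#' @rdname read_grid_csv
#' @export
write_labels_csv <- function(labels, path) {
  readr::write_csv(labels, path)
  invisible(path)
}

#' @rdname read_grid_csv
#' @export
write_cohort <- function(cohort, stem) {
  write_grid_csv(cohort$grids, paste0(stem, "_grids.csv"))
  write_labels_csv(cohort$labels, paste0(stem, "_labels.csv"))
  if (!is.null(cohort$params)) {
    p <- unclass(cohort$params)
    jsonlite::write_json(p, paste0(stem, "_params.json"), digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(paste0(stem, c("_grids.csv", "_labels.csv", "_params.json")))
}

#' @rdname read_grid_csv
#' @export
read_cohort <- function(stem) {
  list(
    grids = read_grid_csv(paste0(stem, "_grids.csv")),
    labels = read_labels_csv(paste0(stem, "_labels.csv"))
  )
}
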