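# Two-step thickness correction: per-sector control-mean centering, plus an
# additive per-sector optic-neuritis (ON) offset for eyes with ON history.

#' Fit per-sector normative reference from control eyes
#'
#' Computes the per-sector mean and standard deviation of layer thickness over
#' all control eyes (both eyes pooled; sample SD with n-1 denominator). The
#' reference defines the zero point of the baseline adjustment and the sigma
#' scale of the atrophy flags.
#'
#' @param grids Patient-space central 4x4 grid tibble containing the control
#'   eyes (`group == "control"`); other rows are ignored.
#' @return A `sector_reference` tibble: `layer`, `row`, `col`, `mean_um`,
#'   `sd_um`, `n_eyes`, with attribute `n_controls` (number of control
#'   patients).
#' @export
fit_sector_reference <- function(grids) {
  check_grid_tbl(grids)
  controls <- dplyr::filter(grids, .data$group == "control")
  n_controls <- dplyr::n_distinct(controls$patient_id)
  if (n_controls < 2) {
    stop("need at least 2 control patients to fit a sector reference",
         call. = FALSE)
  }
  ref <- controls |>
    dplyr::summarise(
      mean_um = mean(.data$thickness_um, na.rm = TRUE),
      sd_um = stats::sd(.data$thickness_um, na.rm = TRUE),
      n_eyes = sum(!is.na(.data$thickness_um)),
      .by = c("layer", "row", "col")
    ) |>
    dplyr::arrange(.data$layer, .data$row, .data$col)
  attr(ref, "n_controls") <- n_controls
  class(ref) <- c("sector_reference", class(ref))
  ref
}

#' Center sector thicknesses on the control reference
#'
#' Baseline adjustment: subtracts the control-group mean of each sector from
#' the observed thickness, so corrected values are signed deviations in
#' micrometers centered on zero for healthy retinae.
#'
#' @param grids Patient-space central 4x4 grid tibble (any group).
#' @param ref A [fit_sector_reference()] result for the same layers.
#' @return The grid tibble with added columns `deviation_um`,
#'   `baseline_adjusted = TRUE`, `on_adjusted = FALSE`.
#' @export
baseline_adjust <- function(grids, ref) {
  check_grid_tbl(grids)
  if (!all(grids$orientation == "patient_space")) {
    stop("baseline_adjust() requires patient_space grids", call. = FALSE)
  }
  if (!all(grids$layer %in% ref$layer)) {
    stop("reference does not cover all layers in `grids`", call. = FALSE)
  }
  out <- grids |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(ref), "layer", "row", "col", "mean_um"),
      by = c("layer", "row", "col")
    )
  if (anyNA(out$mean_um)) {
    stop("reference does not cover every sector in `grids`", call. = FALSE)
  }
  out |>
    dplyr::mutate(
      deviation_um = .data$thickness_um - .data$mean_um,
      baseline_adjusted = TRUE,
      on_adjusted = FALSE
    ) |>
    dplyr::select(-"mean_um")
}

# Eyes counted as "ON" under a scope: the eye itself with ON history
# (scope "eye") or both eyes of any patient with ON history (scope "patient").
on_eye_set <- function(labels, on_scope) {
  if (on_scope == "eye") {
    dplyr::filter(labels, .data$on_history)
  } else {
    on_patients <- unique(labels$patient_id[labels$on_history])
    dplyr::filter(labels, .data$patient_id %in% on_patients)
  }
}

#' Fit the per-sector optic-neuritis offset
#'
#' ON causes diffuse inner-retinal thinning in the affected eye; the offset
#' compensates for it so that residual deviations reflect retrochiasmal
#' (trans-synaptic) damage. Per sector, delta = mean(reference eyes) -
#' mean(ON eyes); positive where ON eyes are thinner. The reference group is
#' either the healthy controls or the MS eyes without ON history.
#'
#' @param grids Patient-space central 4x4 grid tibble (patients and controls).
#' @param labels Per-eye label tibble with `patient_id`, `group`, `eye`,
#'   `on_history`.
#' @param on_reference `"controls"` (default) or `"non_on_patients"`.
#' @param on_scope `"eye"` (default: ON eyes only) or `"patient"` (both eyes
#'   of ON-history patients).
#' @return An `on_offset` tibble: `layer`, `row`, `col`, `delta_um`, with
#'   attributes `reference_group` and `on_scope`.
#' @export
fit_on_offset <- function(grids, labels,
                          on_reference = c("controls", "non_on_patients"),
                          on_scope = c("eye", "patient")) {
  on_reference <- match.arg(on_reference)
  on_scope <- match.arg(on_scope)
  check_grid_tbl(grids)
  on_eyes <- on_eye_set(dplyr::filter(labels, .data$group == "MS"), on_scope)
  if (nrow(on_eyes) == 0) {
    stop("no eyes with ON history; cannot fit an ON offset", call. = FALSE)
  }
  ref_eyes <- if (on_reference == "controls") {
    dplyr::filter(labels, .data$group == "control")
  } else {
    dplyr::anti_join(dplyr::filter(labels, .data$group == "MS"),
                     on_eyes, by = c("patient_id", "eye"))
  }
  if (nrow(ref_eyes) < 2) {
    stop("need at least 2 reference eyes to fit an ON offset", call. = FALSE)
  }
  sector_mean <- function(eyes) {
    grids |>
      dplyr::semi_join(eyes, by = c("patient_id", "eye")) |>
      dplyr::summarise(m = mean(.data$thickness_um, na.rm = TRUE),
                       .by = c("layer", "row", "col"))
  }
  offset <- dplyr::inner_join(
    sector_mean(ref_eyes), sector_mean(on_eyes),
    by = c("layer", "row", "col"), suffix = c("_ref", "_on")
  ) |>
    dplyr::mutate(delta_um = .data$m_ref - .data$m_on) |>
    dplyr::select("layer", "row", "col", "delta_um") |>
    dplyr::arrange(.data$layer, .data$row, .data$col)
  if (any(!is.finite(offset$delta_um))) {
    stop("ON offset is not finite in every sector", call. = FALSE)
  }
  attr(offset, "reference_group") <- on_reference
  attr(offset, "on_scope") <- on_scope
  class(offset) <- c("on_offset", class(offset))
  offset
}

#' Apply the ON offset to baseline-adjusted grids
#'
#' Adds the per-sector ON offset to the deviations of eyes with ON history
#' (under the offset's scope), restoring their expected sector means to the
#' reference group's. Non-ON eyes and controls are returned unchanged.
#' Re-applying to an already ON-adjusted grid is an error, never a silent
#' doubling.
#'
#' @param adjusted A [baseline_adjust()] result.
#' @param offset A [fit_on_offset()] result.
#' @param labels Per-eye label tibble with `on_history`.
#' @return The tibble with updated `deviation_um` and `on_adjusted = TRUE` on
#'   corrected eyes.
#' @export
apply_on_correction <- function(adjusted, offset, labels) {
  if (is.null(adjusted[["baseline_adjusted"]]) ||
      !all(adjusted[["baseline_adjusted"]])) {
    stop("ON correction requires baseline-adjusted grids", call. = FALSE)
  }
  on_scope <- attr(offset, "on_scope") %||% "eye"
  on_eyes <- on_eye_set(dplyr::filter(labels, .data$group == "MS"), on_scope)
  is_on <- !is.na(match(
    paste(adjusted$patient_id, adjusted$eye),
    paste(on_eyes$patient_id, on_eyes$eye)
  ))
  if (any(adjusted$on_adjusted & is_on)) {
    stop("grid is already ON-adjusted; refusing to apply the offset twice",
         call. = FALSE)
  }
  out <- adjusted |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(offset), "layer", "row", "col",
                    "delta_um"),
      by = c("layer", "row", "col")
    )
  out$deviation_um <- ifelse(is_on, out$deviation_um + out$delta_um,
                             out$deviation_um)
  out$on_adjusted <- out$on_adjusted | is_on
  dplyr::select(out, -"delta_um")
}

#' Serialize / read a correction model
#'
#' Writes the sector reference and ON offset as one JSON bundle at full
#' double precision, for audit and exact-round-trip reuse.
#'
#' @param ref A [fit_sector_reference()] result.
#' @param offset A [fit_on_offset()] result.
#' @param path File path for the JSON bundle.
#' @return `write_correction_model()` returns `path` invisibly;
#'   `read_correction_model()` returns `list(reference =, offset =)` equal to
#'   the serialized objects.
#' @export
write_correction_model <- function(ref, offset, path) {
  bundle <- list(
    reference = tibble::as_tibble(ref),
    n_controls = attr(ref, "n_controls"),
    offset = tibble::as_tibble(offset),
    reference_group = attr(offset, "reference_group"),
    on_scope = attr(offset, "on_scope")
  )
  jsonlite::write_json(bundle, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- tibble::as_tibble(bundle$reference)
  attr(ref, "n_controls") <- as.integer(bundle$n_controls)
  class(ref) <- c("sector_reference", class(ref))
  offset <- tibble::as_tibble(bundle$offset)
  attr(offset, "reference_group") <- bundle$reference_group
  attr(offset, "on_scope") <- bundle$on_scope
  class(offset) <- c("on_offset", class(offset))
  list(reference = ref, offset = offset)
}
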