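# Posterior-pole grid model: long-format sector tibbles, laterality and
# orientation conventions, central-grid extraction, hemi-macula geometry.

#' Retinal layers and eye lateralities used throughout the package
#'
#' The macular analysis is restricted to the two inner retinal layers that
#' track neurodegeneration: the ganglion cell layer (GCL) and the inner
#' plexiform layer (IPL). Eyes are labelled OD (right) and OS (left).
#'
#' @name conventions
#' @keywords internal
NULL

hm_layers <- function() c("GCL", "IPL")
hm_eyes <- function() c("OD", "OS")

grid_cols <- c("patient_id", "group", "eye", "layer", "row", "col",
               "thickness_um", "orientation")

#' Build a posterior-pole grid tibble from a thickness matrix
#'
#' Converts one eye/layer sector-thickness matrix into the long ("tidy") grid
#' format used by every function in the package: one row per sector with
#' `row`/`col` indices (1-based, row 1 = superior retina), thickness in
#' micrometers, and an `orientation` tag. In `"display"` orientation the map
#' is taken as fundus view with image-right = the patient's anatomical right
#' for both eyes; `"patient_space"` marks a grid whose columns are already
#' anatomical (hemi-macula queries are only legal in patient space).
#'
#' @param values Square numeric matrix (8x8 or 4x4) of sector thicknesses in
#'   micrometers; `NA` marks missing sectors.
#' @param eye `"OD"` or `"OS"`.
#' @param layer `"GCL"` or `"IPL"`.
#' @param patient_id Patient identifier.
#' @param group `"MS"` or `"control"`.
#' @param orientation `"display"` or `"patient_space"`.
#' @return A tibble with columns `patient_id`, `group`, `eye`, `layer`,
#'   `row`, `col`, `thickness_um`, `orientation`.
#' @examples
#' g <- ppole_grid(matrix(35, 4, 4), eye = "OD", layer = "GCL")
#' dplyr::count(g, eye, layer)
#' @export
ppole_grid <- function(values, eye, layer, patient_id = "P1", group = "MS",
                       orientation = c("display", "patient_space")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(values) || nrow(values) != ncol(values) ||
      !nrow(values) %in% c(4L, 8L)) {
    stop("`values` must be a square 8x8 or 4x4 matrix", call. = FALSE)
  }
  eye <- match.arg(eye, hm_eyes())
  layer <- match.arg(layer, hm_layers())
  n <- nrow(values)
  out <- tibble::tibble(
    patient_id = patient_id,
    group = group,
    eye = eye,
    layer = layer,
    row = rep(seq_len(n), each = n),
    col = rep(seq_len(n), times = n),
    thickness_um = as.vector(t(values)),
    orientation = orientation
  )
  check_grid_tbl(out)
  out
}

#' Validate a long-format grid tibble
#'
#' Checks the schema used by all grid operations: required columns, known eye
#' and layer codes, square 8x8 or 4x4 index range per eye/layer, one row per
#' sector, and thickness values within the 0-200 um sanity bound for inner
#' retinal layers.
#'
#' @param grids Grid tibble (see [ppole_grid()]).
#' @return `grids`, invisibly; errors describe the first violation found.
#' @export
check_grid_tbl <- function(grids) {
  missing_cols <- setdiff(grid_cols, names(grids))
  if (length(missing_cols) > 0) {
    stop("grid tibble is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(grids$eye %in% hm_eyes())) {
    stop("eye must be one of: ", paste(hm_eyes(), collapse = ", "),
         call. = FALSE)
  }
  if (!all(grids$layer %in% hm_layers())) {
    stop("layer must be one of: ", paste(hm_layers(), collapse = ", "),
         call. = FALSE)
  }
  if (!all(grids$orientation %in% c("display", "patient_space"))) {
    stop("unknown orientation tag", call. = FALSE)
  }
  bad <- !is.na(grids$thickness_um) &
    (grids$thickness_um < 0 | grids$thickness_um > 200)
  if (any(bad)) {
    stop("thickness values outside the [0, 200] um sanity bound", call. = FALSE)
  }
  sizes <- grids |>
    dplyr::summarise(
      size = max(.data$row, .data$col),
      n = dplyr::n(),
      .by = c("patient_id", "eye", "layer")
    )
  if (!all(sizes$size %in% c(4L, 8L)) || !all(sizes$n == sizes$size^2)) {
    stop("each eye/layer grid must be a complete square 8x8 or 4x4 grid",
         call. = FALSE)
  }
  invisible(grids)
}

grid_size <- function(grids) {
  s <- unique(pmax(
    tapply(grids$row, paste(grids$patient_id, grids$eye, grids$layer), max),
    tapply(grids$col, paste(grids$patient_id, grids$eye, grids$layer), max)
  ))
  if (length(s) != 1) stop("grids of mixed sizes", call. = FALSE)
  as.integer(s)
}

#' Extract one eye/layer grid as a thickness matrix
#'
#' @param grids Grid tibble.
#' @param patient_id,eye,layer Selectors for a single grid.
#' @return A square numeric matrix (row 1 = grid row 1).
#' @export
grid_matrix <- function(grids, patient_id, eye, layer) {
  g <- dplyr::filter(grids, .data$patient_id == !!patient_id,
                     .data$eye == !!eye, .data$layer == !!layer)
  if (nrow(g) == 0) stop("no matching grid", call. = FALSE)
  n <- max(g$row, g$col)
  m <- matrix(NA_real_, n, n)
  m[cbind(g$row, g$col)] <- g$thickness_um
  m
}

#' Extract the central 4x4 sectors of 8x8 posterior-pole grids
#'
#' The posterior-pole protocol reports an 8x8 sector chart per layer; only
#' the 16 centermost sectors (rows and columns 3-6 of the 8x8 grid, the
#' symmetric center) enter the hemi-macular analysis. Row/column indices are
#' renumbered 1-4; laterality, layer, and orientation are preserved.
#'
#' @param grids Grid tibble where every grid is 8x8.
#' @return Grid tibble of 4x4 central grids.
#' @examples
#' m <- outer(1:8, 1:8, function(r, c) 10 * r + c)
#' g8 <- ppole_grid(m, "OD", "GCL")
#' grid_matrix(extract_central(g8), "P1", "OD", "GCL")[1, 1] # 33
#' @export
extract_central <- function(grids) {
  check_grid_tbl(grids)
  if (grid_size(grids) != 8L) {
    stop("extract_central() requires 8x8 grids", call. = FALSE)
  }
  grids |>
    dplyr::filter(.data$row %in% 3:6, .data$col %in% 3:6) |>
    dplyr::mutate(row = .data$row - 2L, col = .data$col - 2L)
}

#' Normalize grid orientation to patient space
#'
#' Hemi-macula queries require anatomical (patient-space) columns. Under the
#' default `"standard"` display convention posterior-pole maps are fundus
#' view with image-right = the patient's anatomical right for both eyes, so
#' normalization is the identity on values. Exports that mirror left eyes
#' (`"mirrored_os"`) have OS columns reversed on ingest. Grids already in
#' patient space are returned unchanged.
#'
#' @param grids Grid tibble.
#' @param display_convention `"standard"` or `"mirrored_os"`.
#' @return Grid tibble with `orientation = "patient_space"`.
#' @export
to_patient_space <- function(grids,
                             display_convention = c("standard", "mirrored_os")) {
  display_convention <- match.arg(display_convention)
  check_grid_tbl(grids)
  if (all(grids$orientation == "patient_space")) return(grids)
  n <- grid_size(grids)
  out <- grids
  if (display_convention == "mirrored_os") {
    flip <- out$orientation == "display" & out$eye == "OS"
    out$col[flip] <- n + 1L - out$col[flip]
  }
  out$orientation <- "patient_space"
  out
}

#' Anatomical hemi-macula side of each sector
#'
#' For a patient-space 4x4 grid, columns 3-4 form the patient's right
#' hemi-macula and columns 1-2 the left; the two halves partition the 16
#' sectors. The right hemi-maculae of both eyes project to the right
#' retrochiasmal pathway (homonymous organization).
#'
#' @param grids Patient-space grid tibble (any square size; the split is at
#'   the vertical meridian).
#' @return `grids` with an added `hemi` column (`"left"`/`"right"`).
#' @export
add_hemi <- function(grids) {
  check_grid_tbl(grids)
  if (!all(grids$orientation == "patient_space")) {
    stop("hemi-macula geometry requires patient_space orientation; ",
         "call to_patient_space() first", call. = FALSE)
  }
  n <- grid_size(grids)
  dplyr::mutate(grids,
                hemi = ifelse(.data$col > n / 2, "right", "left"))
}

#' Sector values of one hemi-macula
#'
#' @param grids Patient-space 4x4 grid tibble.
#' @param side `"right"` or `"left"` (anatomical).
#' @return Tibble of the 8 sectors per eye/layer on that side.
#' @export
hemi_sectors <- function(grids, side = c("right", "left")) {
  side <- match.arg(side)
  check_grid_tbl(grids)
  if (grid_size(grids) != 4L) {
    stop("hemi_sectors() is defined on central 4x4 grids", call. = FALSE)
  }
  grids |>
    add_hemi() |>
    dplyr::filter(.data$hemi == side)
}

#' Retinal name of a hemi-macula
#'
#' Maps (eye, anatomical side) to the retinal label: the right hemi-macula is
#' the temporal half of the right eye (OD) but the nasal half of the left eye
#' (OS), and conversely for the left side.
#'
#' @param eye Character vector of `"OD"`/`"OS"`.
#' @param side Character vector of `"right"`/`"left"`.
#' @return Character vector of `"temporal"`/`"nasal"`.
#' @examples
#' hemi_label("OD", "right") # temporal
#' hemi_label("OS", "right") # nasal
#' @export
hemi_label <- function(eye, side) {
  stopifnot(all(eye %in% hm_eyes()), all(side %in% c("right", "left")))
  ifelse((eye == "OD") == (side == "right"), "temporal", "nasal")
}
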