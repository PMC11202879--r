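# Synthetic cohort generator: control-like Gaussian sector thicknesses,
# diffuse ON thinning in affected eyes, and lesion-driven homonymous
# hemi-macular thinning with contralateral (crossed-fiber) dominance.

#' Simulation parameters for a synthetic OCT cohort
#'
#' Defaults encode the study conditions the analysis assumes: 52 MS patients
#' and 27 healthy controls; 30.7% of patients with a history of optic
#' neuritis (ON); a 60% prevalence of lateralized retrochiasmal MRI lesions
#' (reported MRI series span 30-90%); a 53:47 crossed:uncrossed fiber split
#' at the chiasm, making the deficit larger in the eye contralateral to the
#' lesion; and a visual-field (VF) test whose patient-level sensitivity and
#' false-positive rate for retrochiasmal lesions are 0.14 and 0.38.
#'
#' A lesioned patient loses thickness from the hemi-macula on the lesion
#' side in both eyes: `2 * lesion_effect * crossed_fraction` micrometers in
#' the contralateral eye and `2 * lesion_effect * (1 - crossed_fraction)` in
#' the ipsilateral eye, so the across-eye mean deficit equals
#' `lesion_effect`. ON thinning is diffuse (all sectors) in the single
#' affected eye.
#'
#' @param n_patients,n_controls Cohort sizes.
#' @param p_on_history Probability a patient has an ON history (one random
#'   eye affected).
#' @param p_lesion Probability of a lateralized retrochiasmal lesion.
#' @param p_side_right Probability a lesion affects the right pathway.
#' @param base_mean Named list of 4x4 matrices (um), central sector means
#'   per layer; see [default_base_mean()].
#' @param base_sd Between-eye sector SD in um (Gaussian, sector-independent).
#' @param on_effect Named vector, diffuse ON thinning per layer (um).
#' @param lesion_effect Named vector, mean hemi-macular deficit per layer
#'   (um).
#' @param crossed_fraction Fraction of chiasmal fibers that cross (0-1).
#' @param vf_sens,vf_false_pos VF positivity probabilities given lesion /
#'   no lesion.
#' @param p_vf_unreliable Per-eye probability of an unreliable VF (fixation
#'   losses >= 33%).
#' @param age_patients,age_controls `c(mean, sd)` of age in years.
#' @param seed Integer seed; cohorts are bit-reproducible given `seed`.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_patients = 52, n_controls = 27,
                       p_on_history = 0.307, p_lesion = 0.60,
                       p_side_right = 0.5,
                       base_mean = default_base_mean(),
                       base_sd = 4.0,
                       on_effect = c(GCL = 8.0, IPL = 6.0),
                       lesion_effect = c(GCL = 10.0, IPL = 8.0),
                       crossed_fraction = 0.53,
                       vf_sens = 0.14, vf_false_pos = 0.38,
                       p_vf_unreliable = 0.05,
                       age_patients = c(35.07, 12.73),
                       age_controls = c(31.85, 10.97),
                       seed = NULL) {
  p <- list(n_patients = n_patients, n_controls = n_controls,
            p_on_history = p_on_history, p_lesion = p_lesion,
            p_side_right = p_side_right, base_mean = base_mean,
            base_sd = base_sd, on_effect = on_effect,
            lesion_effect = lesion_effect,
            crossed_fraction = crossed_fraction,
            vf_sens = vf_sens, vf_false_pos = vf_false_pos,
            p_vf_unreliable = p_vf_unreliable,
            age_patients = age_patients, age_controls = age_controls,
            seed = seed)
  probs <- c(p_on_history, p_lesion, p_side_right, vf_sens, vf_false_pos,
             p_vf_unreliable)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (crossed_fraction <= 0 || crossed_fraction >= 1) {
    stop("crossed_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (any(c(on_effect, lesion_effect) < 0) || base_sd < 0) {
    stop("effects and base_sd must be non-negative", call. = FALSE)
  }
  stopifnot(n_patients >= 1, n_controls >= 2,
            all(hm_layers() %in% names(base_mean)),
            all(vapply(base_mean, function(m) all(dim(m) == c(4, 4)), TRUE)))
  class(p) <- "sim_params"
  p
}

#' Default central sector means
#'
#' Center-weighted 4x4 sector-mean matrices in micrometers: thickest over
#' the perifoveal ring where ganglion cells are densest, thinner toward the
#' grid corners; GCL spans 30-52 um and IPL 28-44 um, in the range Spectralis
#' segmentation reports for healthy adults.
#'
#' @return Named list of 4x4 matrices for `GCL` and `IPL`.
#' @export
default_base_mean <- function() {
  shape <- matrix(c(0, 1, 1, 0,
                    1, 2, 2, 1,
                    1, 2, 2, 1,
                    0, 1, 1, 0), 4, 4, byrow = TRUE)
  list(
    GCL = 30 + shape * 11,  # 30, 41, 52
    IPL = 28 + shape * 8    # 28, 36, 44
  )
}

# replicate the 4x4 central block outward to a full 8x8 posterior-pole grid
pad_to_8 <- function(m4) {
  idx <- pmin(pmax(1:8 - 2L, 1L), 4L)
  m4[idx, idx]
}

#' Simulate a synthetic MS/control OCT cohort
#'
#' Generates full 8x8 posterior-pole GCL and IPL grids (display orientation,
#' standard fundus-view convention) for every eye, per-eye labels (ON
#' history, VF defect and reliability indices, MRI lesion side), and the
#' generating truth. Sector thicknesses are independent Gaussians around the
#' layer's base means; ON and lesion deficits are subtracted as described in
#' [sim_params()]; values are clamped to the physical range [0, 200] um.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (overrides `params$seed`); required for
#'   reproducibility.
#' @return An `hm_cohort` list: `grids` (grid tibble, all eyes), `labels`
#'   (per-eye tibble: `patient_id`, `group`, `eye`, `age`, `on_history`,
#'   `vf_defect`, `fixation_loss_pct`, `false_pos_pct`, `false_neg_pct`,
#'   `mri_lesion`), `truth` (`patient_id`, `lesion_side`, `on_eye`), and
#'   `params`.
#' @examples
#' coh <- simulate_cohort(sim_params(n_patients = 6, n_controls = 3), seed = 1)
#' dplyr::count(coh$labels, group)
#' @export
simulate_cohort <- function(params = sim_params(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  withr::with_seed(as.integer(seed), generate_cohort(params))
}

generate_cohort <- function(params) {
  np <- params$n_patients
  nc <- params$n_controls
  pts <- tibble::tibble(
    patient_id = c(sprintf("MS%04d", seq_len(np)),
                   sprintf("HC%04d", seq_len(nc))),
    group = rep(c("MS", "control"), c(np, nc))
  )
  is_ms <- pts$group == "MS"
  lesion <- is_ms & stats::runif(np + nc) < params$p_lesion
  side_right <- stats::runif(np + nc) < params$p_side_right
  pts$lesion_side <- ifelse(lesion, ifelse(side_right, "right", "left"),
                            "none")
  on_hist <- is_ms & stats::runif(np + nc) < params$p_on_history
  on_od <- stats::runif(np + nc) < 0.5
  pts$on_eye <- ifelse(on_hist, ifelse(on_od, "OD", "OS"), NA_character_)
  pts$age <- pmax(18, stats::rnorm(
    np + nc,
    ifelse(is_ms, params$age_patients[1], params$age_controls[1]),
    ifelse(is_ms, params$age_patients[2], params$age_controls[2])
  ))
  # patient-level VF verdict: detects a lesion with prob vf_sens, false
  # alarms (non-retrochiasmal or spurious field loss) with prob vf_false_pos
  pts$vf_defect <- is_ms & ifelse(
    lesion,
    stats::runif(np + nc) < params$vf_sens,
    stats::runif(np + nc) < params$vf_false_pos
  )

  eyes <- tidyr::expand_grid(pts, eye = hm_eyes())
  n_eyes <- nrow(eyes)
  eyes$on_history <- !is.na(eyes$on_eye) & eyes$eye == eyes$on_eye
  unreliable <- stats::runif(n_eyes) < params$p_vf_unreliable
  eyes$fixation_loss_pct <- ifelse(unreliable, stats::runif(n_eyes, 35, 80),
                                   stats::runif(n_eyes, 0, 25))
  eyes$false_pos_pct <- stats::runif(n_eyes, 0, 25)
  eyes$false_neg_pct <- stats::runif(n_eyes, 0, 25)

  # deficit scaling: crossed fibers dominate the contralateral eye
  ipsi <- (eyes$eye == "OD") == (eyes$lesion_side == "right")
  eyes$lesion_scale <- ifelse(
    eyes$lesion_side == "none", 0,
    ifelse(ipsi, 2 * (1 - params$crossed_fraction),
           2 * params$crossed_fraction)
  )

  grids <- purrr::map(hm_layers(), function(layer) {
    base8 <- pad_to_8(params$base_mean[[layer]])
    base_v <- rep(as.vector(t(base8)), n_eyes)
    rows <- rep(rep(1:8, each = 8), n_eyes)
    cols <- rep(rep(1:8, times = 8), n_eyes)
    i <- rep(seq_len(n_eyes), each = 64)
    in_lesion_hemi <-
      (eyes$lesion_side[i] == "right" & cols > 4) |
      (eyes$lesion_side[i] == "left" & cols <= 4)
    thickness <- base_v +
      stats::rnorm(n_eyes * 64, 0, params$base_sd) -
      eyes$on_history[i] * params$on_effect[[layer]] -
      in_lesion_hemi * eyes$lesion_scale[i] * params$lesion_effect[[layer]]
    tibble::tibble(
      patient_id = eyes$patient_id[i],
      group = eyes$group[i],
      eye = eyes$eye[i],
      layer = layer,
      row = rows,
      col = cols,
      thickness_um = pmin(pmax(thickness, 0), 200),
      orientation = "display"
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$patient_id, .data$eye, .data$layer,
                   .data$row, .data$col)

  labels <- eyes |>
    dplyr::mutate(
      vf_defect = ifelse(.data$group == "MS", .data$vf_defect, FALSE),
      mri_lesion = ifelse(.data$group == "MS", .data$lesion_side,
                          NA_character_)
    ) |>
    dplyr::select("patient_id", "group", "eye", "age", "on_history",
                  "vf_defect", "fixation_loss_pct", "false_pos_pct",
                  "false_neg_pct", "mri_lesion")

  structure(
    list(
      grids = grids,
      labels = labels,
      truth = dplyr::select(pts, "patient_id", "lesion_side", "on_eye"),
      params = params
    ),
    class = "hm_cohort"
  )
}

#' @export
print.hm_cohort <- function(x, ...) {
  n_ms <- sum(x$labels$group == "MS") / 2
  n_hc <- sum(x$labels$group == "control") / 2
  n_lesion <- sum(x$truth$lesion_side != "none")
  cat("Synthetic OCT cohort: ", n_ms, " MS patients (", n_lesion,
      " with retrochiasmal lesion), ", n_hc, " controls\n", sep = "")
  cat("Grids: ", nrow(x$grids), " sector rows (8x8, GCL + IPL, both eyes)\n",
      sep = "")
  invisible(x)
}

#' Check generator rates against their own anchors
#'
#' Simulates a large cohort and summarizes the empirical rates the generator
#' is calibrated to: ON-history fraction, lesion prevalence, patient-level
#' VF sensitivity and specificity against lesion truth, mean hemi-macular
#' deficits in contralateral and ipsilateral eyes (measured on non-ON eyes
#' of lesioned patients against the known base means), and the implied
#' crossed-fiber fraction `contra / (contra + ipsi)`.
#'
#' @param n Number of simulated patients (controls scaled proportionally).
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return Tibble with columns `metric`, `value`.
#' @export
calibration_check <- function(n = 10000, params = sim_params(), seed = 1) {
  params$n_patients <- n
  params$n_controls <- max(2, round(n * 27 / 52))
  coh <- simulate_cohort(params, seed = seed)
  pt <- dplyr::distinct(coh$labels, .data$patient_id, .data$group,
                        .data$mri_lesion) |>
    dplyr::filter(.data$group == "MS") |>
    dplyr::left_join(coh$truth, by = "patient_id")
  on_frac <- mean(!is.na(pt$on_eye))
  lesion <- pt$lesion_side != "none"
  vf <- dplyr::summarise(
    dplyr::filter(coh$labels, .data$group == "MS"),
    vf = .data$vf_defect[1], .by = "patient_id"
  )$vf
  vf_sens <- mean(vf[lesion])
  vf_spec <- mean(!vf[!lesion])

  # hemi deficits: lesion-side hemi of non-ON eyes of lesioned patients
  base_tbl <- purrr::map(hm_layers(), function(layer) {
    m <- pad_to_8(params$base_mean[[layer]])
    tibble::tibble(layer = layer, row = rep(1:8, each = 8),
                   col = rep(1:8, times = 8), base_um = as.vector(t(m)))
  }) |> purrr::list_rbind()
  defic <- coh$grids |>
    dplyr::inner_join(dplyr::filter(coh$truth, .data$lesion_side != "none"),
                      by = "patient_id") |>
    dplyr::filter(is.na(.data$on_eye) | .data$eye != .data$on_eye) |>
    dplyr::filter((.data$lesion_side == "right") == (.data$col > 4)) |>
    dplyr::left_join(base_tbl, by = c("layer", "row", "col")) |>
    dplyr::mutate(
      relation = ifelse((.data$eye == "OD") == (.data$lesion_side == "right"),
                        "ipsilateral", "contralateral"),
      deficit = .data$base_um - .data$thickness_um
    ) |>
    dplyr::summarise(deficit = mean(.data$deficit),
                     .by = c("relation", "layer"))
  contra <- defic$deficit[defic$relation == "contralateral"]
  ipsi <- defic$deficit[defic$relation == "ipsilateral"]
  tibble::tibble(
    metric = c("on_fraction", "lesion_prevalence", "vf_sensitivity",
               "vf_specificity",
               paste0("contra_deficit_", defic$layer[defic$relation ==
                                                       "contralateral"]),
               paste0("ipsi_deficit_", defic$layer[defic$relation ==
                                                     "ipsilateral"]),
               "crossed_fraction_hat"),
    value = c(on_frac, mean(lesion), vf_sens, vf_spec, contra, ipsi,
              sum(contra) / (sum(contra) + sum(ipsi)))
  )
}
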