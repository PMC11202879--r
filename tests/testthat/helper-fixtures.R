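# Shared fixtures: hand-built grids/labels and the laterality mirror used by
# the symmetry tests.

# one complete eye (both layers) built from a single matrix
eye_grids <- function(values, eye, patient_id, group = "MS",
                      orientation = "display") {
  dplyr::bind_rows(
    ppole_grid(values, eye, "GCL", patient_id, group, orientation),
    ppole_grid(values, eye, "IPL", patient_id, group, orientation)
  )
}

# minimal labels row per eye
make_labels <- function(patient_id, group = "MS", on_od = FALSE,
                        on_os = FALSE, mri_lesion = "none",
                        vf_defect = FALSE) {
  tibble::tibble(
    patient_id = patient_id,
    group = group,
    eye = c("OD", "OS"),
    age = 35,
    on_history = c(on_od, on_os),
    vf_defect = vf_defect,
    fixation_loss_pct = 5, false_pos_pct = 5, false_neg_pct = 5,
    mri_lesion = mri_lesion
  )
}

# a patient whose 4x4 patient-space deviations are controlled per hemi:
# both layers get `dev` on the given anatomical side, 0 elsewhere
hemi_deficit_matrix <- function(side, dev, base = 40) {
  m <- matrix(base, 4, 4)
  cols <- if (side == "right") 3:4 else 1:2
  m[, cols] <- base + dev
  m
}

# Reflect a cohort across the vertical meridian: flip grid columns, swap
# OD/OS labels, and swap the MRI lesion side. A correctly lateralized
# analysis must be equivariant under this relabelling.
mirror_cohort <- function(cohort) {
  grids <- cohort$grids
  n <- max(grids$col)
  grids$col <- n + 1L - grids$col
  grids$eye <- ifelse(grids$eye == "OD", "OS", "OD")
  labels <- cohort$labels
  labels$eye <- ifelse(labels$eye == "OD", "OS", "OD")
  swap_side <- function(x) {
    dplyr::case_when(x == "right" ~ "left", x == "left" ~ "right",
                     .default = x)
  }
  labels$mri_lesion <- swap_side(labels$mri_lesion)
  out <- list(grids = grids, labels = labels)
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    truth$lesion_side <- swap_side(truth$lesion_side)
    truth$on_eye <- ifelse(truth$on_eye == "OD", "OS", "OD")
    out$truth <- truth
  }
  out
}
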