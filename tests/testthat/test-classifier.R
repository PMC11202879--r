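# reference with known sigma for threshold arithmetic
flat_ref <- function(mean = 40, sd = 2) {
  ctrl <- dplyr::bind_rows(
    eye_grids(matrix(mean - sd, 4, 4), "OD", "HCa", "control",
              "patient_space"),
    eye_grids(matrix(mean + sd, 4, 4), "OD", "HCb", "control",
              "patient_space")
  )
  fit_sector_reference(ctrl) # mean = mean, sd = sd * sqrt(2)
}

adjusted_eye <- function(m, eye = "OD", id = "MS1", ref = flat_ref()) {
  baseline_adjust(eye_grids(m, eye, id, "MS", "patient_space"), ref)
}

test_that("sector flags apply the -k sigma rule", {
  ref <- flat_ref(40, 2) # sd_um = 2 * sqrt(2)
  s <- unique(ref$sd_um)

  none <- flag_sectors(adjusted_eye(matrix(40, 4, 4)), ref, k = 2)
  expect_false(any(none$flagged))

  deep <- flag_sectors(adjusted_eye(matrix(40 - 3 * s, 4, 4)), ref, k = 2)
  expect_true(all(deep$flagged))

  # boundary is inclusive: deviation exactly -k sigma flags
  at <- flag_sectors(adjusted_eye(matrix(40 - 2 * s, 4, 4)), ref, k = 2)
  expect_true(all(at$flagged))

  # random deviations against an elementwise comparison oracle
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(runif(16, 30, 50), 4, 4)
    fl <- flag_sectors(adjusted_eye(m), ref, k = 2) |>
      dplyr::filter(layer == "GCL")
    oracle <- (m - 40) <= -2 * s
    got <- matrix(FALSE, 4, 4)
    got[cbind(fl$row, fl$col)] <- fl$flagged
    expect_equal(got, oracle, ignore_attr = TRUE)
  }
})

test_that("degenerate zero-sigma reference flags negative deviations with a warning", {
  ref0 <- fit_sector_reference(dplyr::bind_rows(
    eye_grids(matrix(40, 4, 4), "OD", "HCa", "control", "patient_space"),
    eye_grids(matrix(40, 4, 4), "OD", "HCb", "control", "patient_space")
  ))
  adj <- baseline_adjust(
    eye_grids(matrix(39, 4, 4), "OD", "MS1", "MS", "patient_space"), ref0)
  expect_warning(fl <- flag_sectors(adj, ref0, k = 2), "degenerate")
  expect_true(all(fl$flagged))
  adj0 <- baseline_adjust(
    eye_grids(matrix(40, 4, 4), "OD", "MS1", "MS", "patient_space"), ref0)
  expect_silent(fl0 <- flag_sectors(adj0, ref0, k = 2))
  expect_false(any(fl0$flagged))
})

test_that("hemi atrophy counts flags per side with the m threshold", {
  ref <- flat_ref(40, 2)
  s <- unique(ref$sd_um)

  # exactly m flagged sectors on the right side
  for (m_thr in c(1, 4, 8)) {
    vals <- matrix(40, 4, 4)
    right_cells <- cbind(rep(1:4, 2), rep(3:4, each = 4))[seq_len(m_thr), ,
                                                          drop = FALSE]
    vals[right_cells] <- 40 - 3 * s
    h <- hemi_atrophy(flag_sectors(adjusted_eye(vals), ref, 2), m = m_thr)
    expect_true(all(h$atrophy[h$side == "right"]))
    expect_false(any(h$atrophy[h$side == "left"]))
    # one fewer flag than m is negative
    if (m_thr < 8) {
      h2 <- hemi_atrophy(flag_sectors(adjusted_eye(vals), ref, 2),
                         m = m_thr + 1)
      expect_false(any(h2$atrophy))
    }
  }

  # random flags match a counting oracle over the hemi partition
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(sample(c(30, 45), 16, replace = TRUE), 4, 4)
    fl <- flag_sectors(adjusted_eye(m), ref, 2)
    h <- hemi_atrophy(fl, m = 3) |> dplyr::filter(layer == "GCL")
    for (sd_ in c("left", "right")) {
      cols <- if (sd_ == "right") 3:4 else 1:2
      expect_equal(h$atrophy[h$side == sd_],
                   sum((m[, cols] - 40) <= -2 * s) >= 3)
    }
  }
})

test_that("hemi-maculae with fewer than 6 present sectors are unevaluable", {
  ref <- flat_ref()
  m <- matrix(40, 4, 4)
  m[1:3, 1] <- NA # 3 missing sectors in the left hemi
  h <- hemi_atrophy(flag_sectors(adjusted_eye(m), ref, 2), m = 4)
  expect_true(all(is.na(h$atrophy[h$side == "left"])))
  expect_false(any(is.na(h$atrophy[h$side == "right"])))
})

test_that("patient calls require homonymous atrophy in both eyes", {
  ref <- flat_ref(40, 2)
  deficit <- -20

  both_eyes <- function(od_side, os_side, layers = c("GCL", "IPL")) {
    mk <- function(side) {
      if (is.null(side)) matrix(40, 4, 4) else hemi_deficit_matrix(side,
                                                                   deficit)
    }
    g <- dplyr::bind_rows(
      eye_grids(mk(od_side), "OD", "MS1", "MS", "patient_space"),
      eye_grids(mk(os_side), "OS", "MS1", "MS", "patient_space")
    )
    if (!setequal(layers, c("GCL", "IPL"))) {
      # restrict the deficit to one layer, healthy map for the other
      g <- dplyr::bind_rows(
        dplyr::filter(g, layer %in% layers),
        dplyr::filter(dplyr::mutate(g, thickness_um = 40), !layer %in% layers)
      )
    }
    patient_calls(hemi_atrophy(flag_sectors(baseline_adjust(g, ref), ref, 2),
                               m = 4))
  }

  # one-eye atrophy is not homonymous: no call
  one_eye <- both_eyes("right", NULL)
  expect_equal(one_eye$call[one_eye$layer == "combined"], "none")
  expect_false(one_eye$positive[one_eye$layer == "combined"])

  # right hemi-atrophy in both eyes, GCL only: GCL right, IPL none,
  # combined right (a single altered layer suffices)
  gcl_only <- both_eyes("right", "right", layers = "GCL")
  expect_equal(gcl_only$call[gcl_only$layer == "GCL"], "right")
  expect_equal(gcl_only$call[gcl_only$layer == "IPL"], "none")
  expect_equal(gcl_only$call[gcl_only$layer == "combined"], "right")
  expect_true(gcl_only$positive[gcl_only$layer == "combined"])

  # left-sided homonymous atrophy
  left <- both_eyes("left", "left")
  expect_equal(left$call[left$layer == "combined"], "left")

  # both sides atrophic in both eyes: bilateral, positive
  bil <- patient_calls(hemi_atrophy(flag_sectors(baseline_adjust(
    dplyr::bind_rows(
      eye_grids(matrix(40 + deficit, 4, 4), "OD", "MS1", "MS",
                "patient_space"),
      eye_grids(matrix(40 + deficit, 4, 4), "OS", "MS1", "MS",
                "patient_space")
    ), ref), ref, 2), m = 4))
  expect_equal(bil$call[bil$layer == "combined"], "bilateral")
  expect_true(all(bil$positive))
})

test_that("a patient with one eye missing abstains", {
  ref <- flat_ref()
  g <- eye_grids(hemi_deficit_matrix("right", -20), "OD", "MS1", "MS",
                 "patient_space")
  calls <- patient_calls(hemi_atrophy(flag_sectors(baseline_adjust(g, ref),
                                                   ref, 2), m = 4))
  expect_true(all(is.na(calls$call)))
  expect_true(all(is.na(calls$positive)))
})

test_that("eye-level calls classify relation and lesion-side atrophy", {
  ref <- flat_ref(40, 2)
  g <- dplyr::bind_rows(
    eye_grids(matrix(40, 4, 4), "OD", "MS1", "MS", "patient_space"),
    eye_grids(hemi_deficit_matrix("right", -20), "OS", "MS1", "MS",
              "patient_space")
  )
  labels <- make_labels("MS1", mri_lesion = "right")
  h <- hemi_atrophy(flag_sectors(baseline_adjust(g, ref), ref, 2), m = 4)
  ec <- eye_level_calls(h, labels)

  # OD is ipsilateral to a right-pathway lesion, OS contralateral
  expect_equal(ec$relation[ec$eye == "OD"][1], "ipsilateral")
  expect_equal(ec$relation[ec$eye == "OS"][1], "contralateral")
  # only the contralateral eye carries right-hemi atrophy here
  expect_true(all(ec$positive[ec$eye == "OS"]))
  expect_false(any(ec$positive[ec$eye == "OD"]))

  # no relation without a lateralized MRI lesion
  expect_equal(nrow(eye_level_calls(h, make_labels("MS1",
                                                   mri_lesion = "none"))), 0)
})

test_that("flag counts and sensitivity are monotone in k and m", {
  coh <- simulate_cohort(sim_params(n_patients = 24, n_controls = 10),
                         seed = 302)
  central <- extract_central(to_patient_space(coh$grids))
  ref <- fit_sector_reference(central)
  adj <- baseline_adjust(central, ref)
  truth_pos <- coh$truth$lesion_side != "none"
  names(truth_pos) <- coh$truth$patient_id

  sens_at <- function(k, m) {
    calls <- patient_calls(hemi_atrophy(flag_sectors(adj, ref, k), m)) |>
      dplyr::filter(layer == "combined", group == "MS") |>
      dplyr::arrange(patient_id)
    mean(calls$positive[truth_pos[calls$patient_id]])
  }

  n_flags <- vapply(c(0.5, 1, 2, 3), function(k) {
    sum(flag_sectors(adj, ref, k)$flagged)
  }, numeric(1))
  expect_true(all(diff(n_flags) <= 0))

  sens_k <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3), sens_at, numeric(1), m = 4)
  expect_true(all(diff(sens_k) <= 0))
  sens_m <- vapply(1:8, function(m) sens_at(2, m), numeric(1))
  expect_true(all(diff(sens_m) <= 0))
})
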