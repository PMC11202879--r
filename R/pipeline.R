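# End-to-end orchestration: VF reliability filtering, configuration, and the
# four diagnostic comparisons (OCT vs MRI at patient level, VF vs MRI,
# OCT vs VF, OCT vs MRI at eye level).

#' Visual-field reliability filter
#'
#' A VF test is reliable when fixation losses, false positives and false
#' negatives are all strictly below 33%. Unreliable or missing records are
#' excluded from VF comparisons.
#'
#' @param fixation_loss_pct,false_pos_pct,false_neg_pct Numeric vectors of
#'   percentages in `[0, 100]`.
#' @return Logical vector (`NA` where any index is missing).
#' @examples
#' validate_vf(10, 5, 5)   # TRUE
#' validate_vf(33, 5, 5)   # FALSE: the threshold is strict
#' @export
validate_vf <- function(fixation_loss_pct, false_pos_pct, false_neg_pct) {
  pct <- cbind(fixation_loss_pct, false_pos_pct, false_neg_pct)
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("VF reliability indices must be percentages in [0, 100]",
         call. = FALSE)
  }
  fixation_loss_pct < 33 & false_pos_pct < 33 & false_neg_pct < 33
}

#' Pipeline configuration
#'
#' All analysis knobs in one validated list, echoed into every result
#' bundle.
#'
#' @param k Atrophy threshold in control SDs (see [flag_sectors()]).
#' @param m Sectors-per-hemi threshold (see [hemi_atrophy()]).
#' @param on_reference,on_scope ON-offset options (see [fit_on_offset()]).
#' @param display_convention Grid ingest convention (see
#'   [to_patient_space()]).
#' @param mcnemar_method McNemar variant (see [mcnemar_test()]).
#' @param layers Layers to analyze, subset of `c("GCL", "IPL")`.
#' @param vf_aggregation Patient-level VF positivity: `"as_recorded"` /
#'   `"any_eye"` (positive if either eye is), or `"both_eyes"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k = 2, m = 4,
                            on_reference = c("controls", "non_on_patients"),
                            on_scope = c("eye", "patient"),
                            display_convention = c("standard", "mirrored_os"),
                            mcnemar_method = c("auto", "exact", "chisq",
                                               "chisq_cc"),
                            layers = c("GCL", "IPL"),
                            vf_aggregation = c("as_recorded", "any_eye",
                                               "both_eyes")) {
  stopifnot(k > 0, m >= 1, m <= 8, all(layers %in% hm_layers()),
            length(layers) >= 1)
  cfg <- list(
    k = k, m = as.integer(m),
    on_reference = match.arg(on_reference),
    on_scope = match.arg(on_scope),
    display_convention = match.arg(display_convention),
    mcnemar_method = match.arg(mcnemar_method),
    layers = layers,
    vf_aggregation = match.arg(vf_aggregation)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

# one report row: diagnostic stats + McNemar on the same paired calls
comparison_row <- function(index, reference, comparison, layer, variant,
                           level, relation, method) {
  tab <- build_table(index, reference)
  st <- diag_stats(tab)
  # a fully concordant table (fp = fn = 0) legitimately gives exact p = 1;
  # the discordant counts are already visible in the report row
  mc <- suppressWarnings(
    mcnemar_test(index[!is.na(index) & !is.na(reference)],
                 reference[!is.na(index) & !is.na(reference)],
                 method = method)
  )
  tibble::tibble(
    comparison = comparison, layer = layer, variant = variant,
    level = level, relation = relation,
    n = tab$n, n_dropped = tab$n_dropped,
    tp = tab$tp, fn = tab$fn, fp = tab$fp, tn = tab$tn,
    sensitivity = st$sensitivity, specificity = st$specificity,
    ppv = st$ppv, npv = st$npv,
    mcnemar_method = mc$method, mcnemar_p = mc$p_value
  )
}

#' Run the full diagnostic-accuracy analysis
#'
#' Normalizes orientation, extracts the central 4x4 grids, fits the control
#' reference and ON offset, classifies hemi-macular atrophy on raw
#' (baseline-adjusted only) and ON-corrected maps, and evaluates the four
#' comparisons: OCT vs MRI per layer at patient level, VF vs MRI, OCT vs VF,
#' and OCT vs MRI at eye level split by ipsilateral/contralateral eyes. All
#' tables are over MS patients; controls only inform the reference. The run
#' is deterministic given cohort and config.
#'
#' Eye-level tables: reference-positive eyes are those of MRI-lesioned
#' patients with the stated relation (index call = atrophy of the lesion-side
#' hemi-macula); eyes of MRI-negative patients serve as reference-negatives
#' (index call = atrophy of either hemi-macula).
#'
#' @param cohort An `hm_cohort`, or a list with `grids` and `labels` tibbles
#'   in the package schemas.
#' @param config A [pipeline_config()].
#' @return An `hm_eval` object: `report` (one row per comparison),
#'   `exclusions`, `calls` (patient-level calls per variant), `reference`,
#'   `offset`, `config`. See [tidy.hm_eval()].
#' @export
run_all <- function(cohort, config = pipeline_config()) {
  grids <- cohort$grids
  labels <- cohort$labels
  check_grid_tbl(grids)

  ps <- to_patient_space(grids, config$display_convention)
  central <- if (grid_size(ps) == 8L) extract_central(ps) else ps
  ref <- fit_sector_reference(central)
  base <- baseline_adjust(central, ref)
  if (any(labels$on_history[labels$group == "MS"])) {
    offset <- fit_on_offset(central, labels,
                            on_reference = config$on_reference,
                            on_scope = config$on_scope)
    corrected <- apply_on_correction(base, offset, labels)
  } else {
    # nothing to compensate: the ON-corrected analysis equals the raw one
    offset <- NULL
    corrected <- base
  }

  variants <- list(raw = base, corrected = corrected)
  hemi <- purrr::map(variants, function(v) {
    hemi_atrophy(flag_sectors(v, ref, k = config$k), m = config$m)
  })
  pcalls <- purrr::map(hemi, patient_calls)
  ecalls <- purrr::map(hemi, function(h) eye_level_calls(h, labels))

  ms <- labels |>
    dplyr::filter(.data$group == "MS") |>
    dplyr::mutate(vf_valid = validate_vf(.data$fixation_loss_pct,
                                         .data$false_pos_pct,
                                         .data$false_neg_pct))
  pt <- ms |>
    dplyr::summarise(
      mri_pos = ifelse(is.na(.data$mri_lesion[1]), NA,
                       .data$mri_lesion[1] %in% c("right", "left")),
      vf_pos = switch(config$vf_aggregation,
                      both_eyes = all(.data$vf_defect),
                      any(.data$vf_defect)),
      vf_valid = all(.data$vf_valid %in% TRUE),
      .by = "patient_id"
    ) |>
    dplyr::mutate(vf_pos = ifelse(.data$vf_valid, .data$vf_pos, NA)) |>
    dplyr::arrange(.data$patient_id)

  exclusions <- dplyr::bind_rows(
    tibble::tibble(
      unit = "patient", id = pt$patient_id[is.na(pt$mri_pos)],
      reason = "missing MRI lesion status"
    ),
    tibble::tibble(
      unit = "patient", id = pt$patient_id[!pt$vf_valid],
      reason = "unreliable visual field (>= 33% on a reliability index)"
    )
  )

  report <- list()
  for (variant in names(variants)) {
    pc <- pcalls[[variant]] |> dplyr::filter(.data$group == "MS")
    for (layer in config$layers) {
      oct_pos <- pc |>
        dplyr::filter(.data$layer == !!layer) |>
        dplyr::arrange(.data$patient_id)
      stopifnot(identical(oct_pos$patient_id, pt$patient_id))
      if (anyNA(oct_pos$positive)) {
        exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
          unit = "patient",
          id = oct_pos$patient_id[is.na(oct_pos$positive)],
          reason = paste0("unevaluable ", layer, " hemi-macula (", variant,
                          ")")
        ))
      }
      lab <- paste0(ifelse(variant == "corrected", "Corrected ", ""), layer)
      report <- c(report, list(
        comparison_row(oct_pos$positive, pt$mri_pos,
                       paste(lab, "vs MRI"), layer, variant,
                       "patient", NA_character_, config$mcnemar_method),
        comparison_row(oct_pos$positive, pt$vf_pos,
                       paste(lab, "vs VF"), layer, variant,
                       "patient", NA_character_, config$mcnemar_method)
      ))
    }
  }
  report <- c(report, list(
    comparison_row(pt$vf_pos, pt$mri_pos, "VF vs MRI", NA_character_,
                   NA_character_, "patient", NA_character_,
                   config$mcnemar_method)
  ))

  # eye level: lesion-side hemi calls for eyes of lesioned patients, any-side
  # calls for eyes of MRI-negative patients as the reference-negative pool
  neg_ids <- pt$patient_id[pt$mri_pos %in% FALSE]
  for (variant in names(variants)) {
    any_side <- hemi[[variant]] |>
      dplyr::filter(.data$patient_id %in% neg_ids) |>
      dplyr::summarise(positive = any(.data$atrophy),
                       .by = c("patient_id", "eye", "layer"))
    for (layer in config$layers) {
      neg <- dplyr::filter(any_side, .data$layer == !!layer)
      for (rel in c("ipsilateral", "contralateral")) {
        pos <- ecalls[[variant]] |>
          dplyr::filter(.data$layer == !!layer, .data$relation == rel)
        lab <- paste0(ifelse(variant == "corrected", "Corrected ", ""),
                      layer, " vs MRI (", rel, " lesion)")
        report <- c(report, list(
          comparison_row(c(pos$positive, neg$positive),
                         rep(c(TRUE, FALSE), c(nrow(pos), nrow(neg))),
                         lab, layer, variant, "eye", rel,
                         config$mcnemar_method)
        ))
      }
    }
  }

  structure(
    list(
      report = purrr::list_rbind(report),
      exclusions = dplyr::distinct(exclusions),
      calls = pcalls,
      reference = ref,
      offset = offset,
      config = config
    ),
    class = "hm_eval"
  )
}

#' @export
print.hm_eval <- function(x, ...) {
  cat("Hemi-macular OCT diagnostic evaluation (k = ", x$config$k,
      ", m = ", x$config$m, ")\n", sep = "")
  print(dplyr::select(x$report, "comparison", "n", "sensitivity",
                      "specificity", "ppv", "npv", "mcnemar_p"), n = Inf)
  if (nrow(x$exclusions) > 0) {
    cat(nrow(x$exclusions), "exclusion(s); see $exclusions\n")
  }
  invisible(x)
}

#' Tidy and summarize an evaluation
#'
#' `tidy()` returns the report table (one row per comparison, with cell
#' counts, the four accuracy statistics, and the McNemar p-value);
#' `glance()` returns a one-row summary of the run.
#'
#' @param x An `hm_eval` from [run_all()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hm_eval <- function(x, ...) {
  x$report
}

#' @rdname tidy.hm_eval
#' @export
glance.hm_eval <- function(x, ...) {
  tibble::tibble(
    n_comparisons = nrow(x$report),
    n_exclusions = nrow(x$exclusions),
    k = x$config$k,
    m = x$config$m,
    on_reference = x$config$on_reference,
    on_scope = x$config$on_scope
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
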