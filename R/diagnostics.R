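# Paired diagnostic-accuracy machinery: 2x2 contingency tables,
# sensitivity/specificity/PPV/NPV, McNemar tests, and reconstruction of
# candidate integer tables from rounded published statistics.

#' Build a paired 2x2 contingency table
#'
#' Cross-tabulates an index test against a reference standard over paired
#' binary calls. Pairs with a missing member are dropped and counted.
#'
#' @param index,reference Equal-length logical vectors (`NA` allowed).
#' @param index_name,reference_name Labels carried into reports.
#' @return A one-row `contingency_table` tibble with `tp`, `fn`, `fp`, `tn`,
#'   `n`, `n_dropped`, `index_name`, `reference_name`. Cell meanings:
#'   `tp` index+/ref+, `fn` index-/ref+, `fp` index+/ref-, `tn` index-/ref-.
#' @examples
#' build_table(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
#' @export
build_table <- function(index, reference, index_name = "index",
                        reference_name = "reference") {
  stopifnot(is.logical(index), is.logical(reference),
            length(index) == length(reference))
  if (length(index) == 0) stop("empty paired input", call. = FALSE)
  keep <- !is.na(index) & !is.na(reference)
  n_dropped <- sum(!keep)
  index <- index[keep]
  reference <- reference[keep]
  if (length(index) == 0) {
    stop("no complete pairs after dropping missing calls", call. = FALSE)
  }
  out <- tibble::tibble(
    tp = sum(index & reference),
    fn = sum(!index & reference),
    fp = sum(index & !reference),
    tn = sum(!index & !reference),
    n = length(index),
    n_dropped = n_dropped,
    index_name = index_name,
    reference_name = reference_name
  )
  class(out) <- c("contingency_table", class(out))
  out
}

#' Diagnostic accuracy statistics of a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)`. A statistic
#' with a zero denominator is undefined and reported as `NA`, never silently
#' as zero.
#'
#' @param tab A [build_table()] result, or any data frame with columns `tp`,
#'   `fn`, `fp`, `tn` (vectorized over rows).
#' @return Tibble with columns `sensitivity`, `specificity`, `ppv`, `npv`
#'   appended to the cell counts.
#' @export
diag_stats <- function(tab) {
  stopifnot(all(c("tp", "fn", "fp", "tn") %in% names(tab)))
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(
    tibble::as_tibble(tab),
    sensitivity = ratio(.data$tp, .data$tp + .data$fn),
    specificity = ratio(.data$tn, .data$tn + .data$fp),
    ppv = ratio(.data$tp, .data$tp + .data$fp),
    npv = ratio(.data$tn, .data$tn + .data$fn)
  )
}

#' McNemar test on paired binary calls
#'
#' Tests marginal homogeneity of two binary classifications of the same
#' subjects using the discordant counts b (index+/reference-) and c
#' (index-/reference+). Variants: `"exact"` binomial, `p = min(1, 2 P(X <=
#' min(b, c)))` with `X ~ Binomial(b + c, 1/2)`; `"chisq"`, statistic
#' `(b - c)^2 / (b + c)` on 1 df; `"chisq_cc"` with continuity correction
#' `(|b - c| - 1)^2 / (b + c)`. The default `"auto"` uses the exact test when
#' `b + c < 25` and the uncorrected chi-square otherwise.
#'
#' @param index,reference Paired logical vectors (`NA` pairs dropped), or
#'   pass discordant counts directly via `b` and `c`.
#' @param method `"auto"`, `"exact"`, `"chisq"`, or `"chisq_cc"`.
#' @param b,c Discordant counts, alternative to `index`/`reference`.
#' @return Tibble `b`, `c`, `method`, `statistic` (`NA` for exact),
#'   `p_value`.
#' @examples
#' mcnemar_test(b = 5, c = 15, method = "chisq") # statistic 5
#' @export
mcnemar_test <- function(index = NULL, reference = NULL,
                         method = c("auto", "exact", "chisq", "chisq_cc"),
                         b = NULL, c = NULL) {
  method <- match.arg(method)
  if (is.null(b) != is.null(c)) {
    stop("supply both `b` and `c`, or neither", call. = FALSE)
  }
  if (is.null(b)) {
    keep <- !is.na(index) & !is.na(reference)
    index <- index[keep]
    reference <- reference[keep]
    b <- sum(index & !reference)
    c <- sum(!index & reference)
  }
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  nd <- b + c
  if (method == "auto") method <- if (nd < 25) "exact" else "chisq"
  if (method == "exact") {
    if (nd == 0) {
      warning("no discordant pairs; exact McNemar p = 1", call. = FALSE)
      p <- 1
    } else {
      p <- min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
    }
    statistic <- NA_real_
  } else {
    if (nd == 0) {
      stop("chi-square McNemar undefined with no discordant pairs",
           call. = FALSE)
    }
    statistic <- if (method == "chisq") {
      (b - c)^2 / nd
    } else {
      (abs(b - c) - 1)^2 / nd
    }
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(b = as.integer(b), c = as.integer(c), method = method,
                 statistic = statistic, p_value = p)
}

#' Round half-up to a number of decimals
#'
#' Table formatting in clinical reports conventionally rounds halves up
#' (0.005 -> 0.01), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Reconstruct integer 2x2 tables from rounded statistics
#'
#' Published diagnostic tables often report only sensitivity, specificity,
#' PPV and NPV rounded to two decimals, without cell counts. This audit
#' utility enumerates every non-negative integer table with `tp + fn + fp +
#' tn = total_n` whose four statistics round (half-up) to the given values,
#' returning possibly none (mutually inconsistent statistics) or many
#' (under-determined). An `NA` input statistic matches exactly the tables
#' where that statistic is undefined (zero denominator).
#'
#' @param sensitivity,specificity,ppv,npv Target statistics rounded to
#'   `digits` decimals (`NA` = undefined).
#' @param total_n Total table count, >= 1.
#' @param digits Decimals of the published rounding; default 2.
#' @return Tibble of candidate tables (`tp`, `fn`, `fp`, `tn` plus their
#'   exact statistics); zero rows when no table is consistent.
#' @export
reconstruct_tables <- function(sensitivity, specificity, ppv, npv, total_n,
                               digits = 2) {
  stopifnot(total_n >= 1, total_n == round(total_n))
  grid <- tidyr::expand_grid(tp = 0:total_n, fn = 0:total_n, fp = 0:total_n) |>
    dplyr::filter(.data$tp + .data$fn + .data$fp <= total_n) |>
    dplyr::mutate(tn = total_n - .data$tp - .data$fn - .data$fp)
  stats <- diag_stats(grid)
  match_stat <- function(exact, target) {
    if (is.na(target)) is.na(exact)
    else !is.na(exact) &
      abs(round_half_up(exact, digits) - target) < 10^(-digits) / 2e6
  }
  stats |>
    dplyr::filter(
      match_stat(.data$sensitivity, !!sensitivity),
      match_stat(.data$specificity, !!specificity),
      match_stat(.data$ppv, !!ppv),
      match_stat(.data$npv, !!npv)
    )
}
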