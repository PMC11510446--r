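#' Assemble the exposure-potency-effect translation table
#'
#' Joins steady-state exposure metrics, normalised potency, plasma binding
#' and simulated treatment effects into the long analysis table: one row per
#' drug x regimen x endpoint x assay format x exposure metric, carrying the
#' potency multiple (fold nEC50) computed with the format's binding mode.
#'
#' @param exposures Exposure table from [simulate_exposures()] (columns
#'   `drug`, `label`, `dose_mg`, `cavg_pm`, `cmax_pm`, `cmin_pm`).
#' @param potency Potency table (`drug`, `format`, `ec50_pm`) including the
#'   reference peptide rows.
#' @param binding Plasma binding table (`drug`, `funb_p`).
#' @param effects Treatment-effect table (`drug`, `label`, `endpoint`,
#'   `median_change`, `cred_low`, `cred_high`, `weeks`).
#' @param formats Format definition table; default [assay_formats()],
#'   subsettable to evaluate fewer formats.
#' @param metrics Exposure metrics to translate; subset of
#'   `c("cavg", "cmax", "cmin")`.
#' @param reference Reference peptide name for potency normalisation.
#' @return A tibble ordered by drug then ascending dose with columns `drug`,
#'   `label`, `dose_mg`, `endpoint`, `median_change`, `cred_low`,
#'   `cred_high`, `weeks`, `format`, `metric`, `fold`.
#' @export
build_translation_table <- function(exposures, potency, binding, effects,
                                    formats = assay_formats(),
                                    metrics = c("cavg", "cmax", "cmin"),
                                    reference = "GLP-1(7-36)NH2") {
  metrics <- match.arg(metrics, c("cavg", "cmax", "cmin"), several.ok = TRUE)
  if (nrow(effects) == 0) {
    warning("empty treatment-effect table: translation table is empty")
    return(tibble::tibble(
      drug = character(), label = character(), dose_mg = numeric(),
      endpoint = character(), median_change = numeric(),
      cred_low = numeric(), cred_high = numeric(), weeks = numeric(),
      format = character(), metric = character(), fold = numeric()
    ))
  }
  npot <- normalize_ec50(potency, reference = reference)

  # contract checks: report offending keys rather than dropping rows
  miss_exp <- dplyr::anti_join(
    dplyr::distinct(effects, .data$drug, .data$label),
    exposures, by = c("drug", "label")
  )
  if (nrow(miss_exp) > 0)
    stop("no exposure metrics for: ",
         paste(paste(miss_exp$drug, miss_exp$label), collapse = "; "))
  drugs_needed <- unique(effects$drug)
  miss_pot <- setdiff(
    as.vector(outer(drugs_needed, formats$format, paste, sep = " / ")),
    paste(npot$drug, npot$format, sep = " / ")
  )
  if (length(miss_pot) > 0)
    stop("missing potency record(s) for drug / format: ",
         paste(miss_pot, collapse = "; "))
  free_fmt <- formats$format[formats$binding_mode != "total_total"]
  miss_bind <- setdiff(drugs_needed, binding$drug)
  if (length(free_fmt) > 0 && length(miss_bind) > 0)
    stop("missing funb_p for drug(s) ", paste(miss_bind, collapse = ", "),
         " with free-mode format(s) ", paste(free_fmt, collapse = ", "),
         " requested")

  long_exp <- exposures |>
    dplyr::select("drug", "label", "dose_mg", "cavg_pm", "cmax_pm", "cmin_pm") |>
    tidyr::pivot_longer(
      cols = c("cavg_pm", "cmax_pm", "cmin_pm"),
      names_to = "metric", values_to = "cp_pm"
    ) |>
    dplyr::mutate(metric = sub("_pm$", "", .data$metric)) |>
    dplyr::filter(.data$metric %in% metrics)

  effects |>
    dplyr::inner_join(long_exp, by = c("drug", "label"),
                      relationship = "many-to-many") |>
    dplyr::cross_join(dplyr::select(formats, "format", "albumin_pct",
                                    "binding_mode")) |>
    dplyr::left_join(dplyr::select(npot, "drug", "format", "nec50"),
                     by = c("drug", "format")) |>
    dplyr::left_join(binding, by = "drug") |>
    dplyr::mutate(
      df = ifelse(.data$binding_mode == "free_free_diluted",
                  dilution_factor(pmax(.data$albumin_pct, 1e-12)), 44),
      fold = purrr::pmap_dbl(
        list(.data$cp_pm, .data$nec50, .data$funb_p, .data$binding_mode,
             .data$df),
        function(cp, n, fu, mode, df) fold_nec50(cp, n, fu, mode, df)
      )
    ) |>
    dplyr::select("drug", "label", "dose_mg", "endpoint", "median_change",
                  "cred_low", "cred_high", "weeks", "format", "metric",
                  "fold") |>
    dplyr::arrange(.data$drug, .data$dose_mg, .data$endpoint, .data$format,
                   .data$metric)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' The coefficient is the Pearson correlation of the average (tie-corrected)
#' ranks; the two-sided p-value uses the t approximation with n - 2 degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A one-row tibble with `r`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  tibble::tibble(r = r, p = p, n = n)
}

#' Correlate potency multiples with treatment effects
#'
#' For every assay format x exposure metric x endpoint, computes the Spearman
#' correlation between the potency multiple and the median treatment effect,
#' pooling all drugs and dose levels.
#'
#' @param translation Table from [build_translation_table()].
#' @return A tibble with `format`, `metric`, `endpoint`, `r`, `p`, `n`.
#' @export
correlate_formats <- function(translation) {
  translation |>
    dplyr::group_by(.data$format, .data$metric, .data$endpoint) |>
    dplyr::summarise(
      spearman_cor(.data$fold, .data$median_change),
      .groups = "drop"
    )
}

#' Rank assay formats by correlation strength
#'
#' Orders format x metric combinations by descending correlation magnitude
#' (strongest endpoint) and flags those meeting the inclusion criteria for
#' the subsequent regression stage: correlation magnitude above
#' `r_threshold` for at least one endpoint, with `p < p_threshold`.
#' Treatment effects are reductions, so strong association is negative; by
#' default the threshold applies to |r| (`signed = FALSE`).
#'
#' @param correlations Table from [correlate_formats()].
#' @param r_threshold Correlation threshold (default 0.75).
#' @param p_threshold p-value threshold (default 0.01).
#' @param signed If `TRUE`, require `r > r_threshold` on the signed scale
#'   instead of `|r| > r_threshold`.
#' @return `correlations` with added `strength` (max |r| across endpoints
#'   for the format x metric) and `included` (logical), ordered by
#'   descending strength.
#' @export
rank_assays <- function(correlations, r_threshold = 0.75, p_threshold = 0.01,
                        signed = FALSE) {
  if (nrow(correlations) == 0) return(dplyr::mutate(correlations,
                                                    strength = numeric(0),
                                                    included = logical(0)))
  meets_r <- if (signed) correlations$r > r_threshold else
    abs(correlations$r) > r_threshold
  correlations |>
    dplyr::mutate(.meets = meets_r & .data$p < p_threshold) |>
    dplyr::group_by(.data$format, .data$metric) |>
    dplyr::mutate(
      strength = max(abs(.data$r)),
      included = any(.data$.meets)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".meets") |>
    dplyr::arrange(dplyr::desc(.data$strength), .data$format, .data$metric,
                   .data$endpoint)
}
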