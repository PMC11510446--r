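#' The five in vitro assay formats
#'
#' Returns the assay formats used to measure GLP-1 receptor agonist potency:
#' an over-expressing CHO cell line run with no serum albumin, with 0.1%
#' BSA, with 0.1% ovalbumin, or with a physiological 4.4% human serum
#' albumin, plus an EndoC-betaH1 line (endogenous receptor levels) run with
#' 0.1% BSA. Each format carries the binding-correction mode used when
#' relating plasma exposure to its potency scale:
#'
#' * `free_free_diluted` — free plasma concentration against free potency in
#'   the diluted-albumin buffer (the albumin in the buffer is plasma albumin
#'   diluted by `4.4 / albumin_pct`).
#' * `free_uncorrected` — free plasma concentration against the measured
#'   potency with no in vitro binding correction (no albumin, or ovalbumin
#'   for which no binding correction is applied).
#' * `total_total` — total plasma concentration against potency measured at
#'   physiological albumin (total:total).
#'
#' @return A tibble with columns `format`, `cell_system`, `albumin_species`,
#'   `albumin_pct`, `binding_mode`.
#' @export
assay_formats <- function() {
  tibble::tribble(
    ~format,          ~cell_system, ~albumin_species, ~albumin_pct, ~binding_mode,
    "CHO 0% SA",      "CHO",        "none",           0,            "free_uncorrected",
    "CHO 0.1% BSA",   "CHO",        "BSA",            0.1,          "free_free_diluted",
    "CHO 0.1% OA",    "CHO",        "OA",             0.1,          "free_uncorrected",
    "CHO 4.4% HSA",   "CHO",        "HSA",            4.4,          "total_total",
    "EndoC 0.1% BSA", "EndoC",      "BSA",            0.1,          "free_free_diluted"
  )
}

#' Dilution factor from assay albumin concentration
#'
#' Relates the physiological serum-albumin concentration (4.4% w/v) to the
#' albumin concentration in the assay buffer. The paper formats with 0.1%
#' albumin give the default DF of 4.4 / 0.1 = 44.
#'
#' @param albumin_pct Assay buffer albumin concentration, % w/v (> 0).
#' @param plasma_albumin_pct Physiological albumin concentration, % w/v.
#' @return The dilution factor (>= 1 for sub-physiological buffers).
#' @export
dilution_factor <- function(albumin_pct, plasma_albumin_pct = 4.4) {
  if (any(albumin_pct <= 0)) stop("albumin_pct must be positive")
  plasma_albumin_pct / albumin_pct
}

#' Unbound fraction in diluted serum albumin
#'
#' Converts the unbound fraction in undiluted plasma into the unbound
#' fraction expected in an assay buffer where serum albumin is diluted by a
#' factor `df`, under the standard single-site dilution relationship
#' `funb_diluted = df * funb_p / (1 + (df - 1) * funb_p)`.
#'
#' @param funb_p Unbound fraction in plasma, in (0, 1].
#' @param df Dilution factor (>= 1). Default 44 (= 4.4% / 0.1%).
#' @return Unbound fraction in the diluted condition, in (0, 1].
#' @export
unbound_fraction_diluted <- function(funb_p, df = 44) {
  if (any(funb_p <= 0 | funb_p > 1)) stop("funb_p must lie in (0, 1]")
  if (any(df < 1)) stop("dilution factor must be >= 1")
  df * funb_p / (1 + (df - 1) * funb_p)
}

#' Normalise drug potency by the reference peptide
#'
#' Divides each drug's EC50 by the EC50 of the endogenous reference peptide
#' GLP-1(7-36)NH2 measured in the same assay format, yielding the
#' dimensionless normalised potency nEC50.
#'
#' @param potency Potency table with columns `drug`, `format`, `ec50_pm`.
#' @param reference Name of the reference peptide row (default
#'   `"GLP-1(7-36)NH2"`).
#' @return The non-reference rows of `potency` with an added `nec50` column.
#' @export
normalize_ec50 <- function(potency, reference = "GLP-1(7-36)NH2") {
  stopifnot(all(c("drug", "format", "ec50_pm") %in% names(potency)))
  if (any(potency$ec50_pm <= 0)) stop("EC50 values must be positive")
  ref <- potency |>
    dplyr::filter(.data$drug == reference) |>
    dplyr::select("format", ref_ec50_pm = "ec50_pm")
  missing_fmt <- setdiff(unique(potency$format), ref$format)
  if (length(missing_fmt) > 0)
    stop("no reference potency for format(s): ",
         paste(missing_fmt, collapse = ", "))
  potency |>
    dplyr::filter(.data$drug != reference) |>
    dplyr::left_join(ref, by = "format") |>
    dplyr::mutate(nec50 = .data$ec50_pm / .data$ref_ec50_pm) |>
    dplyr::select(-"ref_ec50_pm")
}

#' Potency multiple of a plasma exposure
#'
#' Expresses a steady-state plasma concentration as a multiple of the
#' normalised potency nEC50, with the free-fraction correction appropriate
#' to the assay format's binding mode:
#'
#' * `free_free_diluted`: `Cp * funb_p / (nec50 * funb(diluted))`, the
#'   free plasma concentration against the free in vitro potency, with the
#'   in vitro free fraction derived via [unbound_fraction_diluted()].
#' * `free_uncorrected`: `Cp * funb_p / nec50`.
#' * `total_total`: `Cp / nec50` (both sides at physiological albumin).
#'
#' @param cp_pm Plasma concentration at steady state (pM).
#' @param nec50 Normalised potency (dimensionless, > 0).
#' @param funb_p Unbound fraction in plasma; required for the free modes.
#' @param mode Binding-correction mode (see [assay_formats()]).
#' @param df Dilution factor for `free_free_diluted` (default 44).
#' @return The dimensionless potency multiple ("fold nEC50").
#' @export
fold_nec50 <- function(cp_pm, nec50,
                       funb_p = NULL,
                       mode = c("free_free_diluted", "free_uncorrected",
                                "total_total"),
                       df = 44) {
  mode <- match.arg(mode)
  if (any(cp_pm <= 0)) stop("plasma concentration must be positive")
  if (any(nec50 <= 0)) stop("nEC50 must be positive")
  if (mode == "total_total") return(cp_pm / nec50)
  if (is.null(funb_p) || any(is.na(funb_p)))
    stop("funb_p is required for binding mode '", mode, "'")
  if (any(funb_p <= 0 | funb_p > 1)) stop("funb_p must lie in (0, 1]")
  if (mode == "free_uncorrected") return(cp_pm * funb_p / nec50)
  cp_pm * funb_p / (nec50 * unbound_fraction_diluted(funb_p, df))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of the 4PL model
#' `response = bottom + (top - bottom) / (1 + (ec50 / conc)^hill)` to
#' percent-activation data from a cAMP accumulation assay. The EC50 is the
#' inflection concentration, at which the response is `(bottom + top) / 2`.
#' Starting values take bottom/top from the data extrema, the EC50 from the
#' tested concentration nearest the half-range response, and hill = 1; the
#' EC50 is constrained within the tested concentration range widened 100x on
#' either side.
#'
#' @param conc_pm Tested concentrations (pM), at least 5 distinct values.
#' @param response Percent activation at each concentration.
#' @param noise_floor Minimum dynamic range (`top - bottom`) below which the
#'   EC50 is flagged indeterminate. Default 5 (% activation).
#' @return An object of class `pl4_fit` with elements `bottom`, `top`,
#'   `ec50_pm`, `hill`, `rmse`, `converged`, `indeterminate`.
#' @export
fit_4pl <- function(conc_pm, response, noise_floor = 5) {
  if (length(conc_pm) != length(response)) stop("input lengths differ")
  if (length(unique(conc_pm)) < 5) stop("need at least 5 distinct concentrations")
  if (any(conc_pm <= 0)) stop("concentrations must be positive")
  if (any(!is.finite(response))) stop("responses must be finite")
  dat <- data.frame(conc = conc_pm, resp = response)
  bot0 <- min(response); top0 <- max(response)
  half <- (bot0 + top0) / 2
  ec0 <- conc_pm[which.min(abs(response - half))]
  lower <- c(bottom = -Inf, top = -Inf, lec50 = log(min(conc_pm) / 100),
             hill = 1e-3)
  upper <- c(bottom = Inf, top = Inf, lec50 = log(max(conc_pm) * 100),
             hill = 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) / (1 + (exp(lec50) / conc)^hill),
      data = dat,
      start = list(bottom = bot0, top = top0, lec50 = log(ec0), hill = 1),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(bottom = NA_real_, top = NA_real_, ec50_pm = NA_real_,
           hill = NA_real_, rmse = NA_real_, converged = FALSE,
           indeterminate = TRUE),
      class = "pl4_fit"
    ))
  }
  cf <- stats::coef(fit)
  indet <- (cf[["top"]] - cf[["bottom"]]) < noise_floor
  structure(
    list(
      bottom = cf[["bottom"]], top = cf[["top"]],
      ec50_pm = exp(cf[["lec50"]]), hill = cf[["hill"]],
      rmse = sqrt(mean(stats::resid(fit)^2)),
      converged = TRUE, indeterminate = indet
    ),
    class = "pl4_fit"
  )
}

#' Evaluate a 4PL curve
#'
#' @param object A `pl4_fit`.
#' @param conc_pm Concentrations (pM) at which to predict.
#' @param ... Unused.
#' @return Predicted percent activation.
#' @export
predict.pl4_fit <- function(object, conc_pm, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (object$ec50_pm / conc_pm)^object$hill)
}

#' @export
print.pl4_fit <- function(x, ...) {
  cat("4PL concentration-response fit\n")
  cat(sprintf("  EC50: %.4g pM (hill %.3g)\n", x$ec50_pm, x$hill))
  cat(sprintf("  bottom %.3g, top %.3g, RMSE %.3g\n", x$bottom, x$top, x$rmse))
  if (x$indeterminate) cat("  WARNING: dynamic range below noise floor; EC50 indeterminate\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.pl4_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "ec50_pm", "hill"),
    estimate = c(x$bottom, x$top, x$ec50_pm, x$hill)
  )
}

#' @exportS3Method generics::glance
glance.pl4_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, converged = x$converged,
                 indeterminate = x$indeterminate)
}
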