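#' Validate study input tables
#'
#' Schema, unit and invariant checks for the five input tables consumed by
#' the pipeline. All violations are collected and returned (fail-fast
#' listing), not raised one at a time.
#'
#' @param study A list with tibbles `drugs`, `regimens`, `potency`,
#'   `binding`, `effects` (any subset; missing components are skipped).
#' @return A tibble of violations: `table`, `row`, `problem`. Zero rows
#'   means all checks passed.
#' @export
validate_inputs <- function(study) {
  v <- list()
  add <- function(tab, rows, problem) {
    if (length(rows) > 0)
      v[[length(v) + 1]] <<- tibble::tibble(table = tab, row = rows,
                                            problem = problem)
  }
  need_cols <- function(tab, df, cols) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0) {
      add(tab, 0L, paste("missing column(s):", paste(missing, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  if (!is.null(study$drugs)) {
    d <- study$drugs
    if (need_cols("drugs", d, c("name", "mw_g_per_mol", "funb_p",
                                "model_family", "cl_l_per_h", "vc_l",
                                "ka_per_h", "f_bioavail"))) {
      add("drugs", which(d$mw_g_per_mol <= 0), "mw_g_per_mol must be positive")
      add("drugs", which(d$funb_p <= 0 | d$funb_p > 1),
          "funb_p must lie in (0, 1]")
      add("drugs", which(d$cl_l_per_h <= 0), "cl_l_per_h must be positive")
      add("drugs", which(d$vc_l <= 0), "vc_l must be positive")
      add("drugs", which(!d$model_family %in%
                           c("one_cpt_oral", "one_cpt_bolus", "two_cpt_oral")),
          "unknown model_family")
    }
  }
  if (!is.null(study$regimens)) {
    r <- study$regimens
    if (need_cols("regimens", r, c("drug", "label", "dose_mg", "tau_h"))) {
      add("regimens", which(r$dose_mg <= 0), "dose_mg must be positive")
      add("regimens", which(r$tau_h <= 0), "tau_h must be positive")
    }
  }
  if (!is.null(study$potency)) {
    p <- study$potency
    if (need_cols("potency", p, c("drug", "format", "ec50_pm"))) {
      add("potency", which(p$ec50_pm <= 0), "ec50_pm must be positive")
      if ("sd_pm" %in% names(p))
        add("potency", which(!is.na(p$sd_pm) & p$sd_pm < 0),
            "sd_pm must be non-negative")
    }
  }
  if (!is.null(study$binding)) {
    b <- study$binding
    if (need_cols("binding", b, c("drug", "funb_p"))) {
      add("binding", which(b$funb_p <= 0 | b$funb_p > 1),
          "funb_p must lie in (0, 1]")
    }
  }
  if (!is.null(study$effects)) {
    e <- study$effects
    if (need_cols("effects", e, c("drug", "label", "endpoint",
                                  "median_change", "cred_low", "cred_high"))) {
      add("effects", which(!(e$cred_low <= e$median_change &
                               e$median_change <= e$cred_high)),
          "credible range must bracket the median")
    }
  }
  if (length(v) == 0) {
    tibble::tibble(table = character(), row = integer(), problem = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Run the full in vitro to in vivo translation pipeline
#'
#' Executes the sequential analysis: steady-state PK simulation; potency
#' normalisation and free-fraction-corrected potency multiples per assay
#' format; Spearman correlation of multiples against treatment effects and
#' rank-ordering of formats under the inclusion criteria; weighted
#' exposure-response regression (linear/power/sigmoid, AICc selection) on
#' the included formats using Cavg as the effect-driving exposure metric;
#' and inverse prediction of the potency multiples at the target responses
#' with 95% functional bounds.
#'
#' @param study A list with `drugs`, `regimens`, `potency`, `binding`,
#'   `effects` tibbles (e.g. from [generate_study()] or [read_study()]).
#' @param formats Assay format table (default [assay_formats()]).
#' @param metrics Exposure metrics translated (default all three; the
#'   regression stage uses `regression_metric`).
#' @param regression_metric Metric driving the regression (default
#'   `"cavg"`).
#' @param r_threshold,p_threshold Inclusion criteria for the regression
#'   stage (defaults 0.75 and 0.01, applied to |r|).
#' @param families Candidate effect-model families.
#' @param targets Named target responses inverted per endpoint; names are
#'   endpoint codes, values negative changes vs placebo. Default
#'   -1.5 %point HbA1c and -5% body weight.
#' @param out_dir Optional directory: when given, all intermediate tables
#'   are written as CSV, fit reports as JSON, and a run log is written.
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic given the inputs).
#' @return A list of class `ivivc_result`: `exposures`, `translation`,
#'   `correlations`, `ranking`, `fits` (per format x endpoint: fit list,
#'   comparison table, selection), `inversions` (tibble), `validation`.
#' @export
run_pipeline <- function(study,
                         formats = assay_formats(),
                         metrics = c("cavg", "cmax", "cmin"),
                         regression_metric = "cavg",
                         r_threshold = 0.75, p_threshold = 0.01,
                         families = c("linear", "power", "sigmoid"),
                         targets = c(hba1c_pctpoint = -1.5,
                                     bodyweight_pct = -5),
                         out_dir = NULL, seed = NULL) {
  validation <- validate_inputs(study)
  if (nrow(validation) > 0) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s", validation$table, validation$problem),
               collapse = "\n"))
  }
  exposures <- simulate_exposures(study$drugs, study$regimens)
  translation <- build_translation_table(exposures, study$potency,
                                         study$binding, study$effects,
                                         formats = formats, metrics = metrics)
  correlations <- correlate_formats(translation)
  ranking <- rank_assays(correlations, r_threshold, p_threshold)
  included <- ranking |>
    dplyr::filter(.data$included, .data$metric == regression_metric) |>
    dplyr::distinct(.data$format)

  fits <- list()
  inversions <- tibble::tibble()
  if (nrow(included) == 0) {
    message("no assay format met the inclusion criteria; regression skipped")
  } else {
    for (fmt in included$format) {
      for (ep in unique(translation$endpoint)) {
        dat <- translation |>
          dplyr::filter(.data$format == fmt, .data$endpoint == ep,
                        .data$metric == regression_metric)
        w <- dose_level_weights(dat$drug)
        cand <- lapply(families, function(fam) {
          fit_effect_model(dat$fold, abs(dat$median_change), w, family = fam)
        })
        cand <- cand[vapply(cand, function(f) f$converged, logical(1))]
        cmp <- compare_models(cand)
        key <- paste(fmt, ep, sep = " / ")
        fits[[key]] <- list(format = fmt, endpoint = ep,
                            fits = cand, comparison = cmp$table,
                            selected = cmp$selected)
        if (ep %in% names(targets)) {
          inv <- invert_at_response(cmp$selected, targets[[ep]])
          inversions <- dplyr::bind_rows(
            inversions,
            dplyr::mutate(inv, format = fmt, endpoint = ep,
                          family = cmp$selected$family, .before = 1)
          )
        }
      }
    }
  }
  res <- structure(
    list(exposures = exposures, translation = translation,
         correlations = correlations, ranking = ranking,
         included = included, fits = fits, inversions = inversions,
         validation = validation, seed = seed,
         regression_metric = regression_metric),
    class = "ivivc_result"
  )
  if (!is.null(out_dir)) write_result_bundle(res, out_dir)
  res
}

#' @export
print.ivivc_result <- function(x, ...) {
  cat("In vitro -> in vivo translation result\n")
  cat(sprintf("  %d drug x regimen exposures, %d translation rows\n",
              nrow(x$exposures), nrow(x$translation)))
  top <- dplyr::distinct(x$ranking, .data$format, .data$metric,
                         .data$strength, .data$included)
  cat("  format ranking (by max |r| across endpoints):\n")
  for (i in seq_len(min(5, nrow(top)))) {
    cat(sprintf("    %-16s %-5s |r| = %.3f%s\n", top$format[i],
                top$metric[i], top$strength[i],
                if (top$included[i]) "  [included]" else ""))
  }
  if (nrow(x$inversions) > 0) {
    cat("  inverse predictions:\n")
    for (i in seq_len(nrow(x$inversions))) {
      r <- x$inversions[i, ]
      cat(sprintf("    %s, %s at %g: multiple %.3g [%.3g, %s]\n",
                  r$format, r$endpoint, r$target, r$median, r$lower,
                  if (r$upper_determinable) sprintf("%.3g", r$upper) else "n.d."))
    }
  }
  invisible(x)
}

write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$exposures, file.path(out_dir, "exposures.csv"))
  readr::write_csv(res$translation, file.path(out_dir, "translation.csv"))
  readr::write_csv(res$correlations, file.path(out_dir, "correlations.csv"))
  readr::write_csv(res$ranking, file.path(out_dir, "ranking.csv"))
  if (nrow(res$inversions) > 0)
    readr::write_csv(res$inversions, file.path(out_dir, "inversions.csv"))
  fit_report <- lapply(res$fits, function(entry) {
    list(
      format = entry$format, endpoint = entry$endpoint,
      comparison = entry$comparison,
      selected = list(
        family = entry$selected$family,
        coef = as.list(entry$selected$coef),
        ci = apply(entry$selected$ci, 1, as.list),
        vcov = unclass(entry$selected$vcov),
        aicc = entry$selected$aicc, rmse = entry$selected$rmse,
        n = entry$selected$n, k = entry$selected$k
      )
    )
  })
  jsonlite::write_json(fit_report, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- c(
    sprintf("seed: %s", res$seed %||% "none"),
    sprintf("package: glp1ivivc %s",
            as.character(utils::packageVersion("glp1ivivc"))),
    sprintf("regression_metric: %s", res$regression_metric)
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Read a study directory of CSV inputs
#'
#' Reads the five input tables from `dir` using the pipeline's CSV schemas:
#' `drugs.csv`, `regimens.csv`, `potency.csv`, `binding.csv`,
#' `effects.csv`.
#'
#' @param dir Directory containing the CSV files.
#' @return A study list consumable by [run_pipeline()].
#' @export
read_study <- function(dir) {
  read1 <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path)
    readr::read_csv(path, show_col_types = FALSE)
  }
  list(
    drugs = read1("drugs.csv"), regimens = read1("regimens.csv"),
    potency = read1("potency.csv"), binding = read1("binding.csv"),
    effects = read1("effects.csv")
  )
}

#' Write a study's input tables to a directory
#'
#' @param study A study list (e.g. from [generate_study()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$drugs, file.path(dir, "drugs.csv"))
  readr::write_csv(study$regimens, file.path(dir, "regimens.csv"))
  readr::write_csv(study$potency, file.path(dir, "potency.csv"))
  readr::write_csv(study$binding, file.path(dir, "binding.csv"))
  readr::write_csv(study$effects, file.path(dir, "effects.csv"))
  invisible(dir)
}
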