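#' Configuration for the synthetic study generator
#'
#' Defines the statistical structure of a synthetic GLP-1 receptor agonist
#' study: a drug panel spanning short-acting (half-life ~2-3 h, BID/QD
#' dosing) to long-acting (~5 days, QW) compounds, assay-format-specific
#' potency distortions (albumin binding shifts for low unbound-fraction
#' drugs, a receptor-density shift for the endogenous-receptor cell line),
#' and treatment effects drawn from monotone power laws of the true potency
#' multiple with endpoint-specific parameters (the body-weight curve
#' right-shifted relative to HbA1c) plus multiplicative lognormal noise.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_drugs Number of drugs in the panel (default 6).
#' @param doses_per_drug Dose levels per drug (default 5, geometric grid).
#' @param halflife_short_h,halflife_mid_h,halflife_long_h Half-life ranges
#'   (h) for the short-acting, intermediate and long-acting classes.
#' @param vc_range_l Central volume range (L).
#' @param true_potency_range_pm Range of true (undistorted) drug EC50 (pM).
#' @param ref_ec50_pm True EC50 of the reference peptide (pM).
#' @param funb_lipidated_range Unbound plasma fraction range for
#'   albumin-binding (lipidated-like) drugs; non-binding drugs have
#'   funb_p = 1.
#' @param top_fold_range Range of the largest true potency multiple reached
#'   by each drug's dose grid.
#' @param dose_span Ratio of a drug's highest to lowest dose (default 10,
#'   a one-decade maintenance-dose grid); with the default top-fold range
#'   the panel's multiples span roughly 1-10^4.
#' @param assay_cv Baseline lognormal coefficient of variation of measured
#'   EC50s, used for any format without an entry in `format_noise_cv`.
#' @param format_noise_cv Named per-format lognormal CVs of the measured
#'   EC50 around its systematic value. The defaults encode how faithfully
#'   each format reports the effect-driving potency: small for the
#'   albumin-free format, moderate for ovalbumin, and large for the
#'   albumin-supplemented and endogenous-receptor formats, whose potencies
#'   are additionally distorted drug-by-drug (species-specific binding,
#'   receptor reserve and coupling differences). This per-drug scatter is
#'   what degrades the pooled rank correlation of the distorted formats.
#' @param endoc_shift Multiplicative EC50 shift for the endogenous-receptor
#'   (EndoC) format, reflecting lower receptor density (default 50).
#' @param effect_law Per-endpoint power-law parameters `a`, `b` of the
#'   median effect magnitude vs true fold; defaults give about a 1.5 %point
#'   HbA1c reduction at ~114-fold and a 5% body-weight reduction at
#'   ~280-fold, so body weight is right-shifted vs HbA1c.
#' @param effect_cv Lognormal CV of the simulated median effects.
#' @param cred_halfwidth Half-width factor of the reported 90% credible
#'   range, as a fraction of the median.
#' @param weeks Trial duration attached to the effects (weeks).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 42L,
                             n_drugs = 6L,
                             doses_per_drug = 5L,
                             halflife_short_h = c(2, 3),
                             halflife_mid_h = c(10, 16),
                             halflife_long_h = c(96, 168),
                             vc_range_l = c(6, 14),
                             true_potency_range_pm = c(0.5, 50),
                             ref_ec50_pm = 1.8,
                             funb_lipidated_range = c(0.005, 0.05),
                             top_fold_range = c(30, 1e4),
                             dose_span = 10,
                             assay_cv = 0.2,
                             format_noise_cv = c(
                               "CHO 0% SA" = 0.15,
                               "CHO 0.1% OA" = 0.3,
                               "CHO 0.1% BSA" = 1.5,
                               "CHO 4.4% HSA" = 1.5,
                               "EndoC 0.1% BSA" = 2.5
                             ),
                             endoc_shift = 50,
                             effect_law = list(
                               hba1c_pctpoint = c(a = 0.11, b = 0.55),
                               bodyweight_pct = c(a = 0.055, b = 0.80)
                             ),
                             effect_cv = 0.1,
                             cred_halfwidth = 0.25,
                             weeks = 52) {
  stopifnot(n_drugs >= 4, doses_per_drug >= 2)
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic drug panel
#'
#' Samples drugs across pharmacokinetic classes (short-acting BID/QD,
#' intermediate QD, long-acting QW), with clearance derived from the
#' sampled half-life and central volume (`CL = ln(2)/t_half * Vc`), plasma
#' binding split between non-binding (funb_p = 1) and albumin-bound
#' lipidated-like drugs, and geometric dose grids placed so each drug's
#' true potency multiples span a `dose_span` range up to its sampled top
#' fold.
#' One long-acting drug gets two-compartment kinetics and one a
#' dose-dependent bioavailability lookup.
#'
#' @param config A [generator_config()].
#' @return A list with tibbles `drugs` (PK specification), `regimens`,
#'   `binding`, and `truth` (per-drug true EC50 and normalised potency).
#' @export
generate_drug_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_drugs
  classes <- rep(c("short", "long", "mid"), length.out = n)
  t12 <- vapply(classes, function(cl) {
    r <- switch(cl, short = config$halflife_short_h,
                mid = config$halflife_mid_h, long = config$halflife_long_h)
    stats::runif(1, r[1], r[2])
  }, numeric(1))
  vc <- stats::runif(n, config$vc_range_l[1], config$vc_range_l[2])
  cl_lh <- log(2) / t12 * vc
  ka <- ifelse(classes == "long", stats::runif(n, 0.01, 0.05),
               stats::runif(n, 0.3, 1.0))
  mw <- stats::runif(n, 3300, 4800)
  lipidated <- classes != "short" & (seq_len(n) %% 2 == 0)
  funb <- ifelse(
    lipidated,
    exp(stats::runif(n, log(config$funb_lipidated_range[1]),
                     log(config$funb_lipidated_range[2]))),
    1
  )
  true_ec50 <- exp(stats::runif(n, log(config$true_potency_range_pm[1]),
                                log(config$true_potency_range_pm[2])))
  nec50_true <- true_ec50 / config$ref_ec50_pm
  fbio <- stats::runif(n, 0.5, 0.9)
  sched <- vapply(seq_len(n), function(i) {
    switch(classes[i],
           short = if (i %% 2 == 0) "QD" else "BID",
           mid = "QD", long = "QW")
  }, character(1))
  tau <- c(BID = 12, QD = 24, QW = 168)[sched]
  family <- rep("one_cpt_oral", n)
  long_idx <- which(classes == "long")
  if (length(long_idx) >= 1) family[long_idx[1]] <- "two_cpt_oral"
  vp <- ifelse(family == "two_cpt_oral", vc * 1.5, NA_real_)
  q <- ifelse(family == "two_cpt_oral", cl_lh * 0.8, NA_real_)
  # one drug with dose-dependent bioavailability (lookup resolved later)
  flookup_idx <- if (length(long_idx) >= 2) long_idx[2] else n

  names <- sprintf("SYN-%02d", seq_len(n))
  top_fold <- exp(stats::runif(n, log(config$top_fold_range[1]),
                               log(config$top_fold_range[2])))

  # dose that yields a given true fold, via Cavg = F*D/(CL*tau) and
  # fold = Cavg_pM * funb / nec50_true
  dose_for_fold <- function(i, fold) {
    cavg_pm <- fold * nec50_true[i] / funb[i]
    cavg_ng_ml <- molar_to_mass(cavg_pm, mw[i])
    cavg_ng_ml * 1000 * cl_lh[i] * tau[i] / (fbio[i] * 1e6)
  }
  regimens <- purrr::map_dfr(seq_len(n), function(i) {
    folds <- top_fold[i] / config$dose_span^(
      rev(seq_len(config$doses_per_drug) - 1) /
        max(config$doses_per_drug - 1, 1))
    doses <- signif(dose_for_fold(i, folds), 4)
    tibble::tibble(
      drug = names[i],
      label = sprintf("%s-%d", sched[i], seq_along(doses)),
      dose_mg = doses, tau_h = unname(tau[i]), route = "s.c."
    )
  })

  f_bio_str <- vapply(seq_len(n), function(i) {
    if (i == flookup_idx) {
      dr <- regimens$dose_mg[regimens$drug == names[i]]
      fs <- fbio[i] * seq(1.05, 0.95, length.out = length(dr))
      paste(sprintf("%g:%.4f", dr, fs), collapse = ";")
    } else {
      sprintf("%.4f", fbio[i])
    }
  }, character(1))

  drugs <- tibble::tibble(
    name = names, mw_g_per_mol = mw, funb_p = funb, model_family = family,
    cl_l_per_h = cl_lh, vc_l = vc, vp_l = vp, q_l_per_h = q, ka_per_h = ka,
    f_bioavail = f_bio_str, tlag_h = 0
  )
  list(
    drugs = drugs,
    regimens = regimens,
    binding = tibble::tibble(drug = names, funb_p = funb),
    truth = tibble::tibble(
      drug = names, class = classes, t12_h = t12, lipidated = lipidated,
      true_ec50_pm = true_ec50, nec50_true = nec50_true
    )
  )
}

#' Generate assay-format potency measurements
#'
#' Distorts each drug's true EC50 per assay format: measured potency is the
#' true potency divided by the free fraction in the assay buffer (so EC50
#' rises with albumin concentration for albumin-bound drugs and is
#' unchanged for non-binding ones), multiplied by the receptor-density
#' shift for the EndoC format and by multiplicative lognormal assay noise.
#' Reference peptide records are included for every format.
#'
#' @param config A [generator_config()].
#' @param panel Output of [generate_drug_panel()].
#' @return A potency tibble: `drug`, `cell_system`, `albumin_species`,
#'   `albumin_pct`, `format`, `ec50_pm`, `sd_pm`.
#' @export
generate_assay_potencies <- function(config, panel) {
  set.seed(config$seed + 1L)
  fmts <- assay_formats()
  truth <- dplyr::left_join(panel$truth, panel$binding, by = "drug")
  rows <- tidyr::crossing(
    dplyr::select(truth, "drug", "true_ec50_pm", "funb_p"),
    fmts
  )
  ref <- tidyr::crossing(
    tibble::tibble(drug = "GLP-1(7-36)NH2",
                   true_ec50_pm = config$ref_ec50_pm, funb_p = 1),
    fmts
  )
  all_rows <- dplyr::bind_rows(rows, ref)
  shift_albumin <- function(funb_p, albumin_pct) {
    ifelse(albumin_pct <= 0, 1,
           1 / unbound_fraction_diluted(funb_p,
                                        pmax(dilution_factor(pmax(albumin_pct, 1e-9)), 1)))
  }
  cv_of <- function(fmt) {
    unname(ifelse(fmt %in% names(config$format_noise_cv),
                  config$format_noise_cv[fmt], config$assay_cv))
  }
  all_rows <- all_rows |>
    dplyr::mutate(cv = cv_of(.data$format))
  all_rows |>
    dplyr::mutate(
      shift = shift_albumin(.data$funb_p, .data$albumin_pct) *
        ifelse(.data$cell_system == "EndoC", config$endoc_shift, 1),
      noise = purrr::map_dbl(.data$cv, function(cv) rlnorm_cv(1, cv)),
      ec50_pm = .data$true_ec50_pm * .data$shift * .data$noise,
      sd_pm = .data$ec50_pm * .data$cv
    ) |>
    dplyr::select("drug", "cell_system", "albumin_species", "albumin_pct",
                  "format", "ec50_pm", "sd_pm")
}

#' Generate simulated treatment effects
#'
#' Computes true potency multiples by running the PK engine on the panel
#' (steady-state Cavg, free-fraction corrected, normalised by the TRUE
#' undistorted potency) and draws median treatment effects from the
#' endpoint-specific power laws with multiplicative lognormal noise.
#' Credible ranges are deterministic transforms of the median.
#'
#' @param config A [generator_config()].
#' @param panel Output of [generate_drug_panel()].
#' @return A list with `effects` (tibble: `drug`, `label`, `endpoint`,
#'   `median_change`, `cred_low`, `cred_high`, `weeks`) and `true_folds`
#'   (tibble with the generating multiple per drug x regimen).
#' @export
generate_treatment_effects <- function(config, panel) {
  set.seed(config$seed + 2L)
  expo <- simulate_exposures(panel$drugs, panel$regimens)
  truth <- dplyr::left_join(panel$truth, panel$binding, by = "drug")
  folds <- expo |>
    dplyr::left_join(dplyr::select(truth, "drug", "nec50_true", "funb_p"),
                     by = "drug") |>
    dplyr::mutate(true_fold = .data$cavg_pm * .data$funb_p / .data$nec50_true)
  effects <- purrr::map_dfr(names(config$effect_law), function(ep) {
    par <- config$effect_law[[ep]]
    mag <- par[["a"]] * folds$true_fold^par[["b"]] *
      rlnorm_cv(nrow(folds), config$effect_cv)
    med <- -mag
    tibble::tibble(
      drug = folds$drug, label = folds$label, endpoint = ep,
      median_change = med,
      cred_low = med * (1 + config$cred_halfwidth),
      cred_high = med * (1 - config$cred_halfwidth),
      weeks = config$weeks
    )
  })
  list(effects = effects,
       true_folds = dplyr::select(folds, "drug", "label", "dose_mg",
                                  "cavg_pm", "true_fold"))
}

#' Generate a complete synthetic study
#'
#' Runs the three generator stages and returns every table the analysis
#' pipeline consumes, plus the generating truth (true potencies, true
#' multiples, effect-law parameters and the true multiple at any target
#' response, for parameter-recovery checks).
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_study`: `drugs`, `regimens`,
#'   `potency`, `binding`, `effects`, `truth` (list with `panel`,
#'   `true_folds`, `effect_law`, and `true_multiple(target, endpoint)`).
#' @export
generate_study <- function(config = generator_config()) {
  panel <- generate_drug_panel(config)
  potency <- generate_assay_potencies(config, panel)
  eff <- generate_treatment_effects(config, panel)
  true_multiple <- function(target, endpoint) {
    par <- config$effect_law[[endpoint]]
    (abs(target) / par[["a"]])^(1 / par[["b"]])
  }
  structure(
    list(
      drugs = panel$drugs, regimens = panel$regimens, potency = potency,
      binding = panel$binding, effects = eff$effects,
      truth = list(panel = panel$truth, true_folds = eff$true_folds,
                   effect_law = config$effect_law,
                   true_multiple = true_multiple),
      config = config
    ),
    class = "synthetic_study"
  )
}

#' In vitro potency of approved GLP-1 receptor agonists (fixture)
#'
#' The measured EC50 (pM, with standard deviation) of five approved GLP-1
#' receptor agonists and the endogenous reference peptide GLP-1(7-36)NH2 in
#' the five assay formats of [assay_formats()]. The EndoC standard
#' deviation for lixisenatide was not available and is `NA`.
#'
#' @return A tibble: `drug`, `cell_system`, `albumin_species`,
#'   `albumin_pct`, `format`, `ec50_pm`, `sd_pm`.
#' @export
approved_glp1ra_potency <- function() {
  wide <- tibble::tribble(
    ~drug, ~`CHO 0% SA`, ~`CHO 0.1% BSA`, ~`CHO 0.1% OA`, ~`CHO 4.4% HSA`, ~`EndoC 0.1% BSA`,
    "Dulaglutide",    "39.4 (15.3)",  "16 (11.7)",   "31.8 (9.10)", "50.6 (13)",    "2440 (2100)",
    "Semaglutide",    "0.915 (0.36)", "31 (22.4)",   "3.45 (1.60)", "3400 (2200)",  "7380 (3200)",
    "Liraglutide",    "1.2 (0.55)",   "1.56 (2.22)", "14.3 (5.90)", "475 (329)",    "257 (150)",
    "Exenatide",      "2.14 (0.64)",  "2.32 (0.68)", "1.99 (1.00)", "3.15 (1.83)",  "366 (180)",
    "Lixisenatide",   "1.31 (0.04)",  "3.16 (0.39)", "3.1 (2.54)",  "5.79 (0.74)",  "100 (NA)",
    "GLP-1(7-36)NH2", "1.77 (0.55)",  "3.09 (1.00)", "5.32 (1.48)", "4.53 (2.71)",  "136 (110)"
  )
  long <- wide |>
    tidyr::pivot_longer(-"drug", names_to = "format", values_to = "cell") |>
    dplyr::mutate(
      ec50_pm = as.numeric(sub(" \\(.*", "", .data$cell)),
      sd_pm = suppressWarnings(
        as.numeric(sub(".*\\((.*)\\)", "\\1", .data$cell))
      )
    ) |>
    dplyr::select(-"cell")
  long |>
    dplyr::left_join(assay_formats(), by = "format") |>
    dplyr::select("drug", "cell_system", "albumin_species", "albumin_pct",
                  "format", "ec50_pm", "sd_pm")
}
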