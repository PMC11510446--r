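noiseless_config <- function(seed = 42L) {
  generator_config(
    seed = seed,
    format_noise_cv = c("CHO 0% SA" = 0, "CHO 0.1% OA" = 0,
                        "CHO 0.1% BSA" = 0, "CHO 4.4% HSA" = 0,
                        "EndoC 0.1% BSA" = 0),
    effect_cv = 0
  )
}

test_that("generation is byte-identical under a fixed seed", {
  s1 <- generate_study(generator_config(seed = 7L))
  s2 <- generate_study(generator_config(seed = 7L))
  d1 <- tempfile(); d2 <- tempfile()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  s3 <- generate_study(generator_config(seed = 8L))
  expect_false(identical(s1$drugs, s3$drugs))
})

test_that("sampled elimination rate is consistent with the half-life", {
  p <- generate_drug_panel(generator_config(seed = 7L))
  ke <- p$drugs$cl_l_per_h / p$drugs$vc_l
  expect_equal(ke, log(2) / p$truth$t12_h, tolerance = 1e-12)
})

test_that("short-acting QD drug has larger peak-trough than long-acting QW", {
  st <- generate_study(generator_config(seed = 42L))
  expo <- simulate_exposures(st$drugs, st$regimens)
  expo <- dplyr::left_join(expo, st$truth$panel, by = "drug")
  pt_short <- max(expo$peak_trough[expo$class == "short"])
  pt_long <- min(expo$peak_trough[expo$class == "long"])
  expect_gt(pt_short, pt_long)
})

test_that("assay distortions follow the binding and receptor-density structure", {
  cfg <- noiseless_config()
  panel <- generate_drug_panel(cfg)
  pot <- generate_assay_potencies(cfg, panel)
  wide <- tidyr::pivot_wider(
    dplyr::select(pot, "drug", "format", "ec50_pm"),
    names_from = "format", values_from = "ec50_pm"
  ) |>
    dplyr::left_join(panel$binding, by = "drug")
  unbound <- dplyr::filter(wide, funb_p == 1, drug != "GLP-1(7-36)NH2")
  bound <- dplyr::filter(wide, funb_p < 0.1)
  expect_gt(nrow(unbound), 0)
  expect_gt(nrow(bound), 0)
  # non-binding drugs: same EC50 with and without physiological albumin
  expect_equal(unbound$`CHO 4.4% HSA`, unbound$`CHO 0% SA`, tolerance = 1e-12)
  # strongly bound drugs: large potency loss at physiological albumin
  expect_true(all(bound$`CHO 4.4% HSA` / bound$`CHO 0% SA` > 10))
  # shift increases monotonically with albumin concentration for bound drugs
  expect_true(all(bound$`CHO 0% SA` < bound$`CHO 0.1% BSA`))
  expect_true(all(bound$`CHO 0.1% BSA` < bound$`CHO 4.4% HSA`))
  # endogenous receptor line is right-shifted for every drug
  expect_true(all(wide$`EndoC 0.1% BSA` > wide$`CHO 0.1% BSA`))
  # reference peptide rows exist in all five formats
  ref <- dplyr::filter(pot, drug == "GLP-1(7-36)NH2")
  expect_equal(sort(ref$format), sort(assay_formats()$format))
})

test_that("with default noise the binding shift still dominates for bound drugs", {
  st <- generate_study(generator_config(seed = 42L))
  wide <- tidyr::pivot_wider(
    dplyr::select(st$potency, "drug", "format", "ec50_pm"),
    names_from = "format", values_from = "ec50_pm"
  ) |>
    dplyr::left_join(st$binding, by = "drug")
  bound <- dplyr::filter(wide, funb_p < 0.05)
  unbound <- dplyr::filter(wide, funb_p == 1)
  expect_gt(min(bound$`CHO 4.4% HSA` / bound$`CHO 0% SA`),
            max(unbound$`CHO 4.4% HSA` / unbound$`CHO 0% SA`))
})

test_that("noiseless effects lie exactly on the generating power law", {
  cfg <- noiseless_config()
  st <- generate_study(cfg)
  folds <- st$truth$true_folds
  eff <- dplyr::filter(st$effects, endpoint == "hba1c_pctpoint") |>
    dplyr::left_join(folds, by = c("drug", "label"))
  par <- cfg$effect_law$hba1c_pctpoint
  expect_equal(eff$median_change, -par[["a"]] * eff$true_fold^par[["b"]],
               tolerance = 1e-12)
  # regression on the noiseless 0% SA folds recovers the generator exactly
  expo <- simulate_exposures(st$drugs, st$regimens)
  tr <- build_translation_table(expo, st$potency, st$binding, st$effects,
                                metrics = "cavg")
  dat <- dplyr::filter(tr, format == "CHO 0% SA",
                       endpoint == "hba1c_pctpoint")
  fit <- fit_effect_model(dat$fold, abs(dat$median_change),
                          dose_level_weights(dat$drug), family = "power")
  expect_lt(abs(fit$coef[["a"]] - par[["a"]]) / par[["a"]], 1e-6)
  expect_lt(abs(fit$coef[["b"]] - par[["b"]]) / par[["b"]], 1e-6)
})

test_that("body-weight response is right-shifted relative to HbA1c", {
  cfg <- generator_config()
  x_hba1c <- (1.5 / cfg$effect_law$hba1c_pctpoint[["a"]])^
    (1 / cfg$effect_law$hba1c_pctpoint[["b"]])
  bw_at_that_fold <- cfg$effect_law$bodyweight_pct[["a"]] *
    x_hba1c^cfg$effect_law$bodyweight_pct[["b"]]
  expect_lt(bw_at_that_fold, 5)
  st <- generate_study(cfg)
  wide <- tidyr::pivot_wider(st$effects, names_from = "endpoint",
                             values_from = c("median_change", "cred_low",
                                             "cred_high"))
  # per regimen, % body-weight reduction is smaller than needed for -5%
  # whenever HbA1c reduction is around -1.5
  near <- dplyr::filter(wide, dplyr::between(median_change_hba1c_pctpoint,
                                             -1.8, -1.2))
  if (nrow(near) > 0) {
    expect_true(all(near$median_change_bodyweight_pct > -5))
  }
})

test_that("generated tables satisfy the consuming modules' invariants", {
  st <- generate_study(generator_config(seed = 11L))
  expect_equal(nrow(validate_inputs(st)), 0)
  expect_true(all(st$effects$cred_low <= st$effects$median_change))
  expect_true(all(st$effects$median_change <= st$effects$cred_high))
})

test_that("full pipeline recovers the generating multiple within 15%", {
  st <- generate_study(generator_config(seed = 42L))
  res <- run_pipeline(st)
  inv <- dplyr::filter(res$inversions, format == "CHO 0% SA",
                       endpoint == "hba1c_pctpoint")
  truth <- st$truth$true_multiple(-1.5, "hba1c_pctpoint")
  expect_lt(abs(inv$median - truth) / truth, 0.15)
})

test_that("measured potency fixture matches the published values", {
  tab <- approved_glp1ra_potency()
  expect_equal(nrow(tab), 30)
  expect_equal(tab$ec50_pm[tab$drug == "Semaglutide" &
                             tab$format == "CHO 0% SA"], 0.915)
  expect_equal(tab$sd_pm[tab$drug == "Semaglutide" &
                           tab$format == "CHO 0% SA"], 0.36)
  expect_equal(tab$ec50_pm[tab$drug == "GLP-1(7-36)NH2" &
                             tab$format == "CHO 0.1% BSA"], 3.09)
  expect_true(is.na(tab$sd_pm[tab$drug == "Lixisenatide" &
                                tab$format == "EndoC 0.1% BSA"]))
  # shipped CSV fixture is the same table
  csv <- readr::read_csv(system.file("extdata", "approved_glp1ra_potency.csv",
                                     package = "glp1ivivc"),
                         show_col_types = FALSE)
  expect_equal(as.data.frame(csv), as.data.frame(tab))
})
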