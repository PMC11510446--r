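# one-compartment bolus with mw chosen so concentrations come out in round pM
bolus_model <- function(cl = 1, vc = 10, mw = 1000) {
  pk_model("one_cpt_bolus", cl = cl, vc = vc, mw = mw)
}

test_that("bolus steady state follows the closed-form accumulation factor", {
  # dose such that C(0+) after a single dose is 100 pM (mw 1000, vc 10 L)
  m <- bolus_model()
  ke <- 1 / 10
  tau <- 24
  dose <- 1e-3  # mg -> 100 ng/mL / 1000 g/mol = 100 pM... scaled below
  c0_single <- mass_to_molar(dose * 1e6 / 10 / 1000, 1000)
  expect_equal(c0_single, 100)
  prof <- simulate_steady_state(m, dose, tau)
  met <- exposure_metrics(prof)
  expect_equal(met$cmax, c0_single / (1 - exp(-ke * tau)), tolerance = 1e-10)
  # whole interval is a single exponential
  expect_equal(prof$conc, met$cmax * exp(-ke * prof$time_h), tolerance = 1e-10)
})

test_that("very fast absorption converges to the bolus profile", {
  ke <- 2 / 10
  bol <- pk_model("one_cpt_bolus", cl = 2, vc = 10, mw = 4000)
  oral <- pk_model("one_cpt_oral", cl = 2, vc = 10, ka = 1000 * ke, mw = 4000)
  pb <- simulate_steady_state(bol, 1, 24)
  po <- simulate_steady_state(oral, 1, 24)
  # skip t = 0: at steady state the oral profile starts at the pre-absorption
  # trough and catches the bolus curve within the absorption half-life
  keep <- -1
  expect_lt(max(abs(po$conc[keep] - pb$conc[keep])) / max(pb$conc), 0.01)
  mb <- exposure_metrics(pb); mo <- exposure_metrics(po)
  expect_equal(mo$cavg, mb$cavg, tolerance = 0.01)
  expect_equal(mo$cmax, mb$cmax, tolerance = 0.01)
})

test_that("numeric ODE superposition agrees with the closed form", {
  set.seed(11)
  for (i in 1:10) {
    cl <- runif(1, 0.5, 5); vc <- runif(1, 5, 20)
    ka <- runif(1, 0.05, 1); tau <- sample(c(12, 24, 168), 1)
    m <- pk_model("one_cpt_oral", cl = cl, vc = vc, ka = ka, mw = 4000)
    pa <- simulate_steady_state(m, 1, tau, points_per_interval = 64)
    pn <- simulate_steady_state(m, 1, tau, points_per_interval = 64,
                                method = "numeric")
    expect_lt(max(abs(pa$conc - pn$conc)) / max(pa$conc), 0.005)
  }
})

test_that("two-compartment model agrees with its numeric oracle and is dose-linear", {
  m <- pk_model("two_cpt_oral", cl = 1, vc = 8, vp = 12, q = 0.8, ka = 0.03,
                mw = 4000)
  pa <- simulate_steady_state(m, 2, 168, points_per_interval = 64)
  pn <- simulate_steady_state(m, 2, 168, points_per_interval = 64,
                              method = "numeric")
  expect_lt(max(abs(pa$conc - pn$conc)) / max(pa$conc), 0.005)
  p2 <- simulate_steady_state(m, 4, 168, points_per_interval = 64)
  expect_equal(p2$conc, 2 * pa$conc, tolerance = 1e-12)
})

test_that("peak-trough ratio for bolus dosing equals exp(ke * tau)", {
  # t1/2 = 3 h, tau = 24 h -> ratio 2^8 = 256
  ke <- log(2) / 3
  m <- pk_model("one_cpt_bolus", cl = ke * 10, vc = 10, mw = 1000)
  met <- exposure_metrics(simulate_steady_state(m, 1, 24))
  expect_equal(met$peak_trough, 256, tolerance = 1e-9)
})

test_that("degenerate constant profile gives ratio 1 and Cavg = Cmax = Cmin", {
  prof <- tibble::tibble(time_h = seq(0, 24, length.out = 100),
                         conc = rep(50, 100))
  met <- exposure_metrics(prof, 24)
  expect_equal(met$cavg, 50)
  expect_equal(met$cmax, met$cmin)
  expect_equal(met$peak_trough, 1)
})

test_that("trapezoidal Cavg matches the analytic F*D/(CL*tau) identity", {
  m <- pk_model("one_cpt_oral", cl = 1.3, vc = 9, ka = 0.4, f = 0.65,
                mw = 4200)
  for (npts in c(200, 512)) {
    met <- exposure_metrics(
      simulate_steady_state(m, 0.8, 24, points_per_interval = npts))
    expected <- mass_to_molar(0.65 * 0.8 * 1e6 / (1.3 * 24) / 1000, 4200)
    expect_lt(abs(met$cavg - expected) / expected, 0.005)
  }
})

test_that("exposures are exactly dose-linear for linear kinetics", {
  m <- pk_model("one_cpt_oral", cl = 2, vc = 12, ka = 0.6, mw = 3800)
  m1 <- exposure_metrics(simulate_steady_state(m, 1, 24))
  m2 <- exposure_metrics(simulate_steady_state(m, 2, 24))
  expect_equal(m2$cavg, 2 * m1$cavg, tolerance = 1e-12)
  expect_equal(m2$cmax, 2 * m1$cmax, tolerance = 1e-12)
  expect_equal(m2$cmin, 2 * m1$cmin, tolerance = 1e-12)
})

test_that("long half-life accumulates and peak-trough falls with t1/2 / tau", {
  # t1/2 = 7 days dosed QD: steady-state Cavg > 5x first-interval Cavg
  t12 <- 7 * 24
  m <- pk_model("one_cpt_bolus", cl = log(2) / t12 * 10, vc = 10, mw = 1000)
  ss <- exposure_metrics(simulate_steady_state(m, 1, 24))
  terms <- glp1ivivc:::pk_exponential_terms(m, 1)
  tg <- seq(0, 24, length.out = 513)
  first <- tibble::tibble(
    time_h = tg,
    conc = mass_to_molar(terms$coef * exp(-terms$rate * tg), 1000)
  )
  expect_gt(ss$cavg / exposure_metrics(first, 24)$cavg, 5)

  ratios <- vapply(c(3, 12, 48, 168), function(t12) {
    m <- pk_model("one_cpt_bolus", cl = log(2) / t12 * 10, vc = 10, mw = 1000)
    exposure_metrics(simulate_steady_state(m, 1, 24))$peak_trough
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("Cmin <= Cavg <= Cmax across random parameter sets", {
  set.seed(21)
  for (i in 1:20) {
    m <- pk_model("one_cpt_oral", cl = runif(1, 0.5, 5),
                  vc = runif(1, 5, 20), ka = runif(1, 0.02, 1), mw = 4000)
    met <- exposure_metrics(simulate_steady_state(m, 1, 24,
                                                  points_per_interval = 64))
    expect_lte(met$cmin, met$cavg)
    expect_lte(met$cavg, met$cmax)
  }
})

test_that("flip-flop degeneracy ka = ke is resolved, matching nearby kinetics", {
  ke <- 0.2
  m_eq <- pk_model("one_cpt_oral", cl = ke * 10, vc = 10, ka = ke, mw = 4000)
  m_near <- pk_model("one_cpt_oral", cl = ke * 10, vc = 10, ka = ke * 1.001,
                     mw = 4000)
  p_eq <- simulate_steady_state(m_eq, 1, 24)
  p_near <- simulate_steady_state(m_near, 1, 24)
  expect_true(all(is.finite(p_eq$conc)))
  expect_lt(max(abs(p_eq$conc - p_near$conc)) / max(p_eq$conc), 0.01)
})

test_that("absorption lag circularly shifts the steady-state profile", {
  base <- pk_model("one_cpt_oral", cl = 1, vc = 10, ka = 0.5, mw = 4000)
  lagged <- pk_model("one_cpt_oral", cl = 1, vc = 10, ka = 0.5, tlag = 6,
                     mw = 4000)
  pb <- exposure_metrics(simulate_steady_state(base, 1, 24))
  pl <- exposure_metrics(simulate_steady_state(lagged, 1, 24))
  expect_equal(pl$cmax, pb$cmax, tolerance = 1e-6)
  expect_equal(pl$cavg, pb$cavg, tolerance = 1e-3)
})

test_that("mass-molar conversion and round trip are exact", {
  expect_equal(mass_to_molar(1, 1000), 1000)
  expect_equal(mass_to_molar(4.113, 4113), 1000)
  x <- c(0.37, 12.1, 980)
  expect_equal(molar_to_mass(mass_to_molar(x, 4113), 4113), x)
  expect_error(mass_to_molar(1, -5), "positive")
})

test_that("dose-dependent bioavailability interpolates and extrapolates flat", {
  ftab <- data.frame(dose = c(1, 2, 4), f = c(0.6, 0.5, 0.4))
  m <- pk_model("one_cpt_oral", cl = 1, vc = 10, ka = 0.5, f = ftab, mw = 4000)
  expect_equal(bioavailable_fraction(m, 1.5), 0.55)
  expect_equal(bioavailable_fraction(m, 0.1), 0.6)   # below table: constant
  expect_equal(bioavailable_fraction(m, 10), 0.4)    # above table: constant
  expect_equal(glp1ivivc:::parse_bioavailability("1:0.6;2:0.5;4:0.4"), ftab)
  expect_equal(glp1ivivc:::parse_bioavailability("0.75"), 0.75)
})

test_that("invalid model parameters are rejected", {
  expect_error(pk_model("one_cpt_bolus", cl = -1, vc = 10), "positive")
  expect_error(pk_model("one_cpt_oral", cl = 1, vc = 10), "ka")
  expect_error(pk_model("one_cpt_bolus", cl = 1, vc = 10, f = 1.2), "F must")
  expect_error(pk_model("two_cpt_oral", cl = 1, vc = 10, ka = 0.5), "vp and q")
})
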