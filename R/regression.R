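#' Dose-level weights for exposure-response fitting
#'
#' Residuals are weighted by the number of dose levels contributed by each
#' drug, so a drug tested at many doses does not dominate the fit: every
#' point from a drug with `m` dose levels receives weight `1/m`.
#'
#' @param drug Character vector identifying the drug behind each point.
#' @return Numeric weights, one per point.
#' @export
dose_level_weights <- function(drug) {
  m <- table(drug)
  as.numeric(1 / m[as.character(drug)])
}

effect_fun <- function(family) {
  switch(family,
    linear  = function(x, p) p[["a"]] * x,
    power   = function(x, p) p[["a"]] * x^p[["b"]],
    sigmoid = function(x, p) {
      s <- x^p[["c"]] / (x^p[["c"]] + p[["d"]]^p[["c"]])
      p[["a"]] + (p[["b"]] - p[["a"]]) * s
    }
  )
}

effect_grad <- function(family) {
  switch(family,
    linear  = function(x, p) cbind(a = x),
    power   = function(x, p) {
      xb <- x^p[["b"]]
      cbind(a = xb, b = p[["a"]] * xb * log(x))
    },
    sigmoid = function(x, p) {
      a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]; d <- p[["d"]]
      s <- x^cc / (x^cc + d^cc)
      cbind(
        a = 1 - s,
        b = s,
        c = (b - a) * s * (1 - s) * log(x / d),
        d = -(b - a) * s * (1 - s) * cc / d
      )
    }
  )
}

#' Fit an exposure-response model
#'
#' Weighted least squares fit of one of three candidate drug-effect models
#' relating the potency multiple `x` (fold nEC50) to the magnitude of the
#' treatment-effect reduction `y`:
#' linear `y = a*x`, power `y = a*x^b`, or sigmoid
#' `y = a + (b - a) * x^c / (x^c + d^c)`.
#' Fitting is on reduction magnitudes (positive y); effects supplied on the
#' change-vs-placebo scale (all non-positive) are negated internally and
#' reported predictions can be negated back by the caller.
#'
#' The weighted sum of squares `sum(w * (y - f(x))^2)` is minimised; the
#' nonlinear families use Levenberg-Marquardt with five deterministic
#' initialisations (a log-log regression seed and perturbations of it), the
#' best weighted SSR winning and ties going to the first. The parameter
#' covariance is the Jacobian-based Wald covariance at the optimum and
#' AICc = n*log(SSR_w/n) + 2k + 2k(k+1)/(n-k-1).
#'
#' @param x Potency multiples (> 0).
#' @param y Effect magnitudes (positive reductions), or non-positive changes
#'   vs placebo which are negated.
#' @param weights Per-point weights (> 0); default all 1. See
#'   [dose_level_weights()].
#' @param family One of `"linear"`, `"power"`, `"sigmoid"`.
#' @return An object of class `effect_fit`: `family`, `coef`, `vcov`,
#'   `ssr_w`, `rmse`, `aicc`, `n`, `k`, `ci` (95% per-parameter bounds),
#'   `converged`, plus the data used.
#' @export
fit_effect_model <- function(x, y, weights = NULL,
                             family = c("linear", "power", "sigmoid")) {
  family <- match.arg(family)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x <= 0)) stop("potency multiples must be positive")
  if (all(y <= 0) && any(y < 0)) y <- -y
  if (any(y < 0)) stop("y must be all reduction magnitudes or all changes <= 0")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (any(weights <= 0)) stop("weights must be positive")
  n <- length(x)
  k <- switch(family, linear = 1L, power = 2L, sigmoid = 4L)
  if (n < k + 2) stop("need at least k + 2 points")

  if (family == "linear") {
    a <- sum(weights * x * y) / sum(weights * x^2)
    p <- c(a = a)
    converged <- TRUE
  } else {
    # log-log WLS seed for the power family (also seeds the sigmoid scale)
    pos <- y > 0
    ll <- stats::lm(log(y[pos]) ~ log(x[pos]), weights = weights[pos])
    a0 <- exp(stats::coef(ll)[[1]]); b0 <- stats::coef(ll)[[2]]
    starts <- if (family == "power") {
      list(
        c(a = a0, b = b0),
        c(a = a0 * 1.5, b = b0),
        c(a = a0 / 1.5, b = b0),
        c(a = a0, b = b0 * 1.25),
        c(a = a0, b = max(b0 * 0.8, 1e-3))
      )
    } else {
      ymax <- max(y); xmid <- stats::median(x)
      list(
        c(a = max(min(y), 1e-6), b = ymax * 1.2, c = 1, d = xmid),
        c(a = 1e-3, b = ymax * 2, c = 0.7, d = xmid * 2),
        c(a = 1e-3, b = ymax * 1.1, c = 1.5, d = xmid / 2),
        c(a = max(min(y) * 0.5, 1e-6), b = ymax * 3, c = 0.5, d = xmid * 5),
        c(a = 1e-2, b = ymax * 1.5, c = 2, d = xmid)
      )
    }
    lower <- switch(family,
      power = c(a = 1e-12, b = 1e-6),
      sigmoid = c(a = 0, b = 1e-12, c = 1e-6, d = 1e-12)
    )
    f <- effect_fun(family)
    best <- NULL
    dat <- data.frame(x = x, y = y, w = weights)
    form <- switch(family,
      power = y ~ a * x^b,
      sigmoid = y ~ a + (b - a) * x^c / (x^c + d^c)
    )
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = dat, start = as.list(st),
                          weights = dat$w, lower = lower,
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      ssr <- sum(weights * stats::resid(fit)^2)
      if (is.null(best) || ssr < best$ssr - 1e-12 * best$ssr) {
        best <- list(fit = fit, ssr = ssr)
      }
    }
    if (is.null(best)) {
      return(structure(
        list(family = family, coef = NULL, vcov = NULL, ssr_w = NA_real_,
             rmse = NA_real_, aicc = NA_real_, n = n, k = k, ci = NULL,
             converged = FALSE, x = x, y = y, weights = weights),
        class = "effect_fit"
      ))
    }
    p <- stats::coef(best$fit)
    converged <- TRUE
  }

  f <- effect_fun(family)
  res <- y - f(x, as.list(p))
  ssr_w <- sum(weights * res^2)
  sigma2 <- ssr_w / (n - k)
  J <- effect_grad(family)(x, as.list(p))
  JtWJ <- crossprod(J * sqrt(weights))
  vcov <- tryCatch(sigma2 * solve(JtWJ), error = function(e) {
    matrix(NA_real_, k, k, dimnames = list(names(p), names(p)))
  })
  se <- sqrt(diag(vcov))
  tcrit <- stats::qt(0.975, df = n - k)
  ci <- cbind(lower = unname(p) - tcrit * se, upper = unname(p) + tcrit * se)
  rownames(ci) <- names(p)
  aicc <- if (n > k + 1) {
    n * log(ssr_w / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  } else {
    stop("AICc undefined: need n > k + 1")
  }
  structure(
    list(family = family, coef = p, vcov = vcov, ssr_w = ssr_w,
         rmse = sqrt(ssr_w / n), aicc = aicc, n = n, k = k, ci = ci,
         se = se, converged = converged, x = x, y = y, weights = weights),
    class = "effect_fit"
  )
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("%s exposure-response fit (n = %d)\n", x$family, x$n))
  if (!x$converged) {
    cat("  NOT CONVERGED\n")
    return(invisible(x))
  }
  for (nm in names(x$coef)) {
    cat(sprintf("  %s = %.4g  [%.4g, %.4g]\n", nm, x$coef[[nm]],
                x$ci[nm, "lower"], x$ci[nm, "upper"]))
  }
  cat(sprintf("  weighted RMSE %.4g, AICc %.4g\n", x$rmse, x$aicc))
  invisible(x)
}

#' Predict the effect magnitude from a fitted model
#'
#' @param object An `effect_fit`.
#' @param x Potency multiples.
#' @param ... Unused.
#' @return Predicted reduction magnitudes.
#' @export
predict.effect_fit <- function(object, x, ...) {
  effect_fun(object$family)(x, as.list(object$coef))
}

#' @exportS3Method generics::tidy
tidy.effect_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), conf.low = numeric(),
                          conf.high = numeric()))
  }
  tibble::tibble(
    term = names(x$coef),
    estimate = unname(x$coef),
    std.error = unname(x$se),
    conf.low = x$ci[, "lower"],
    conf.high = x$ci[, "upper"]
  )
}

#' @exportS3Method generics::glance
glance.effect_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, n = x$n, k = x$k, ssr_w = x$ssr_w, rmse = x$rmse,
    aicc = x$aicc, converged = x$converged
  )
}

#' Compare candidate exposure-response fits by AICc
#'
#' Among fits of the same data, selects the admissible fit with the lowest
#' AICc. A fit is admissible when every parameter's 95% confidence interval
#' has finite width and excludes a sign change (parameter precision
#' criterion: an interval spanning zero indicates an unidentifiable
#' parameter / over-fitting). Ties in AICc are broken by fewer parameters,
#' then first listed. If no fit is admissible the lowest-AICc fit is
#' returned with a warning.
#'
#' @param fits A list of `effect_fit` objects on identical data.
#' @return A list with `selected` (the chosen `effect_fit`), `table`
#'   (tibble: family, k, aicc, delta_aicc, rmse, admissible, max_ci_width).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  adm <- vapply(fits, fit_admissible, logical(1))
  tab <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble::tibble(
      family = f$family, k = f$k,
      aicc = f$aicc, rmse = f$rmse,
      admissible = adm[i],
      max_ci_width = if (f$converged) max(f$ci[, "upper"] - f$ci[, "lower"])
                     else NA_real_
    )
  }) |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc, na.rm = TRUE)) |>
    dplyr::relocate("delta_aicc", .after = "aicc")
  pool <- if (any(adm)) which(adm) else seq_along(fits)
  if (!any(adm)) warning("no admissible fit; returning best AICc overall")
  aiccs <- vapply(fits[pool], function(f) f$aicc, numeric(1))
  ks <- vapply(fits[pool], function(f) f$k, numeric(1))
  ord <- order(round(aiccs, 10), ks, seq_along(pool))
  list(selected = fits[[pool[ord[1]]]], table = tab)
}

fit_admissible <- function(fit) {
  if (!fit$converged) return(FALSE)
  if (any(!is.finite(fit$ci))) return(FALSE)
  lo <- fit$ci[, "lower"]; hi <- fit$ci[, "upper"]
  all(lo * hi > 0)  # same sign at both ends: no sign change inside the CI
}

#' Functional prediction bounds for a fitted exposure-response curve
#'
#' Non-simultaneous delta-method confidence bounds on the fitted curve:
#' `f(x) +/- t(n-k, (1+level)/2) * sqrt(g' V g)` with `g` the parameter
#' gradient of `f` at `x` and `V` the parameter covariance.
#'
#' @param fit A converged `effect_fit` with valid covariance.
#' @param x Potency multiples at which to evaluate.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `x`, `fit`, `lwr`, `upr` (reduction magnitudes).
#' @export
predict_bounds <- function(fit, x, level = 0.95) {
  stopifnot(inherits(fit, "effect_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (any(!is.finite(fit$vcov))) stop("singular covariance: bounds unavailable")
  p <- as.list(fit$coef)
  fx <- effect_fun(fit$family)(x, p)
  G <- effect_grad(fit$family)(x, p)
  sef <- sqrt(pmax(rowSums((G %*% fit$vcov) * G), 0))
  tcrit <- stats::qt((1 + level) / 2, df = fit$n - fit$k)
  tibble::tibble(x = x, fit = fx, lwr = fx - tcrit * sef,
                 upr = fx + tcrit * sef)
}

#' Invert a fitted exposure-response model at a target response
#'
#' Finds the potency multiple whose predicted effect equals the target
#' (e.g. a -1.5 %point HbA1c or -5% body-weight change), with a 95%
#' functional-bound interval: the lower bound on the multiple comes from
#' inverting the upper effect-bound curve (optimistic potency), the upper
#' bound from inverting the lower curve. When the lower effect-bound curve
#' never attains the target magnitude on the admissible range, the upper
#' bound on the multiple is reported as not determinable.
#'
#' @param fit A converged `effect_fit`.
#' @param y_target Target response (negative change vs placebo, or positive
#'   reduction magnitude).
#' @param level Confidence level for the bounds (default 0.95).
#' @param x_range Admissible multiple range searched for roots, default
#'   `c(1e-3, 1e7)`.
#' @return A one-row tibble: `target`, `median`, `lower`, `upper`,
#'   `upper_determinable`.
#' @export
invert_at_response <- function(fit, y_target, level = 0.95,
                               x_range = c(1e-3, 1e7)) {
  stopifnot(inherits(fit, "effect_fit"))
  if (!fit$converged) stop("fit did not converge")
  m <- abs(y_target)
  p <- as.list(fit$coef)
  f <- function(x) effect_fun(fit$family)(x, p)
  if (m < f(x_range[1]) || m > f(x_range[2]))
    stop("target response unattainable by the median curve on the admissible range")
  median_x <- if (fit$family == "power") {
    (m / p$a)^(1 / p$b)
  } else if (fit$family == "linear") {
    m / p$a
  } else {
    invert_curve(f, m, x_range)
  }
  bound <- function(which) {
    g <- function(x) {
      b <- predict_bounds(fit, x, level = level)
      if (which == "upr") b$upr else b$lwr
    }
    invert_curve(g, m, x_range)
  }
  lower_x <- tryCatch(bound("upr"), error = function(e) NA_real_)
  upper_x <- tryCatch(bound("lwr"), error = function(e) NA_real_)
  # lower effect-bound curve plateauing below target => upper n.d.
  upper_det <- is.finite(upper_x)
  tibble::tibble(
    target = y_target, median = median_x, lower = lower_x,
    upper = if (upper_det) upper_x else NA_real_,
    upper_determinable = upper_det
  )
}

# monotone root search on a log-x grid + uniroot refinement
invert_curve <- function(g, m, x_range) {
  grid <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = 512))
  vals <- vapply(grid, g, numeric(1)) - m
  sgn <- sign(vals)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                   (sgn[-1] != 0 | sgn[-length(sgn)] != 0))
  if (all(vals < 0)) stop("curve never attains the target on the range")
  if (all(vals > 0)) stop("curve exceeds the target on the whole range")
  if (length(cross) == 0) {
    i <- which(vals == 0)[1]
    return(grid[i])
  }
  i <- cross[1]
  stats::uniroot(function(x) g(x) - m, lower = grid[i], upper = grid[i + 1],
                 tol = .Machine$double.eps^0.75)$root
}
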