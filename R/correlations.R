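new_correlation_model <- function(kind, constant_name, coefficients,
                                  r_squared, points, intercept) {
  structure(list(kind = kind, constant_name = constant_name,
                 coefficients = coefficients, r_squared = r_squared,
                 points = points, intercept = intercept),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  form <- switch(x$kind,
    inverse_concentration = "ln k = a + b * (1/C)",
    linear_flow = "k = a + b * Q")
  cat(sprintf("Correlation model [%s]%s: %s\n", x$kind,
              if (is.na(x$constant_name)) "" else
                sprintf(" for %s", x$constant_name), form))
  cat(sprintf("  a = %.6g, b = %.6g  (R^2 = %.4f, %d points%s)\n",
              x$coefficients[["a"]], x$coefficients[["b"]], x$r_squared,
              nrow(x$points),
              if (x$intercept) "" else ", zero intercept"))
  invisible(x)
}

#' Correlate a kinetic constant with drug concentration
#'
#' Fits the Arrhenius-type relation `ln k = a + b * (1/C)` between a
#' mechanism's kinetic constant and the initial drug load `C` (% w/w) by
#' ordinary least squares on the log scale. The classical one-parameter form
#' (`ln k = b/C`, no intercept) is available with `intercept = FALSE`; the
#' default keeps the intercept, which is required for the relation to pass
#' through typical fitted constants.
#'
#' @param C Numeric vector of drug loads (% w/w); at least 2 distinct,
#'   positive values.
#' @param k Matching kinetic-constant values; strictly positive (the fit is
#'   on `ln k`).
#' @param constant_name Optional name of the constant being correlated
#'   (e.g. `"k_b"`).
#' @param intercept Keep the intercept term (default `TRUE`).
#' @return A `correlation_model` with `coefficients` `a` (intercept, 0 when
#'   suppressed) and `b` (slope on `1/C`), and the R^2 of the log-scale
#'   regression.
#' @examples
#' fit_concentration_correlation(c(10, 20, 30), c(1.5, 2.5, 3.4), "k_b")
#' @export
fit_concentration_correlation <- function(C, k, constant_name = NA_character_,
                                          intercept = TRUE) {
  C <- as.numeric(C); k <- as.numeric(k)
  if (length(C) < 2L || length(C) != length(k)) {
    stop("need at least 2 matched (C, k) points", call. = FALSE)
  }
  if (any(!is.finite(C)) || any(C <= 0) || anyDuplicated(C)) {
    stop("`C` values must be positive and distinct", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` values must be strictly positive", call. = FALSE)
  }
  x <- 1 / C
  y <- log(k)
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x - 1)
  a <- if (intercept) unname(stats::coef(fit)[1L]) else 0
  b <- unname(stats::coef(fit)[["x"]])
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  new_correlation_model("inverse_concentration", constant_name,
                        c(a = a, b = b), r2,
                        data.frame(x = C, k = k), intercept)
}

#' Correlate a kinetic constant with flow rate
#'
#' Fits the linear relation `k = a + b * Q` between a mechanism's kinetic
#' constant and the release-medium flow rate `Q` (mL/s). The one-parameter
#' proportional form (`k = b * Q`, no intercept) is available with
#' `intercept = FALSE`; the default keeps the intercept, which is required
#' when the constant is nonzero under static conditions (`Q = 0`).
#'
#' @param Q Numeric vector of flow rates (mL/s); at least 2 distinct values.
#' @param k Matching kinetic-constant values.
#' @inheritParams fit_concentration_correlation
#' @return A `correlation_model` with `coefficients` `a` and `b` and the
#'   R^2 of the regression.
#' @examples
#' fit_flow_correlation(c(0, 7.5, 23.5), c(1.7, 2.5, 3.9), "k_b")
#' @export
fit_flow_correlation <- function(Q, k, constant_name = NA_character_,
                                 intercept = TRUE) {
  Q <- as.numeric(Q); k <- as.numeric(k)
  if (length(Q) < 2L || length(Q) != length(k)) {
    stop("need at least 2 matched (Q, k) points", call. = FALSE)
  }
  if (any(!is.finite(Q)) || anyDuplicated(Q)) {
    stop("`Q` values must be finite and distinct", call. = FALSE)
  }
  if (any(!is.finite(k))) stop("`k` values must be finite", call. = FALSE)
  fit <- if (intercept) stats::lm(k ~ Q) else stats::lm(k ~ Q - 1)
  a <- if (intercept) unname(stats::coef(fit)[1L]) else 0
  b <- unname(stats::coef(fit)[["Q"]])
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((k - mean(k))^2)
  new_correlation_model("linear_flow", constant_name, c(a = a, b = b), r2,
                        data.frame(x = Q, k = k), intercept)
}

#' Predict a kinetic constant from a correlation model
#'
#' Evaluates the fitted correlation at a new factor level, on the proper
#' scale: `exp(a + b/x)` for concentration correlations, `a + b*x` for flow
#' correlations. Extrapolating far beyond the training range triggers a
#' warning (not an error).
#'
#' @param model A `correlation_model`.
#' @param x New factor value(s): drug load (% w/w) or flow rate (mL/s).
#' @param band Allowed extrapolation band as a fraction of the training
#'   range beyond each end (default 0.5).
#' @return Predicted constant value(s).
#' @examples
#' m <- fit_concentration_correlation(c(10, 20, 30), c(1.5, 2.5, 3.4))
#' predict_constant(m, 15)
#' @export
predict_constant <- function(model, x, band = 0.5) {
  stopifnot(inherits(model, "correlation_model"))
  rng <- range(model$points$x)
  span <- max(diff(rng), .Machine$double.eps)
  if (any(x < rng[1L] - band * span | x > rng[2L] + band * span)) {
    warning(sprintf(
      "predicting at %s outside the trained range [%g, %g] (+/- %g%%)",
      paste(signif(x[x < rng[1L] - band * span | x > rng[2L] + band * span],
                   4), collapse = ", "),
      rng[1L], rng[2L], 100 * band), call. = FALSE)
  }
  a <- model$coefficients[["a"]]
  b <- model$coefficients[["b"]]
  switch(model$kind,
    inverse_concentration = {
      if (any(x <= 0)) stop("concentration must be > 0", call. = FALSE)
      exp(a + b / x)
    },
    linear_flow = a + b * x,
    stop("unknown correlation kind", call. = FALSE))
}

#' Predict a full release profile at an unseen condition
#'
#' Assembles composite-model parameters for a new factor level (drug load
#' or flow rate) and simulates the release curve. Kinetic constants come
#' from per-constant correlation models; mechanism weights are linearly
#' interpolated in the varied factor between the supplied conditions and
#' renormalised to sum to 1 (outside the tabulated range the nearest
#' condition's weights are used).
#'
#' @param models Named list of `correlation_model`s with entries `k_b`,
#'   `D_e` and either `k_os` or `delta_pi` (the latter converted through
#'   `gamma`).
#' @param weights Data frame with columns `x` (the varied factor level) and
#'   `mu_burst`, `mu_diffusion`, `mu_osmosis`; at least 2 rows.
#' @param x New factor level.
#' @param times Time grid for the simulated profile, hours.
#' @param gamma Osmotic conversion factor used when `models$delta_pi` is
#'   supplied.
#' @param thickness Film thickness, m.
#' @param label Label for the returned profile.
#' @param band Extrapolation band passed to [predict_constant()].
#' @return A [release_profile()]; attribute `"params"` carries the
#'   assembled [composite_params()].
#' @examples
#' tab <- builtin_conditions()
#' conc <- tab[tab$flow == 7.5, ]
#' models <- list(
#'   k_b  = fit_concentration_correlation(conc$drug_load, conc$k_b, "k_b"),
#'   D_e  = fit_concentration_correlation(conc$drug_load, conc$D_e, "D_e"),
#'   k_os = fit_concentration_correlation(conc$drug_load, conc$k_os, "k_os"))
#' w <- data.frame(x = conc$drug_load, mu_burst = conc$mu_burst,
#'                 mu_diffusion = conc$mu_diffusion,
#'                 mu_osmosis = conc$mu_osmosis)
#' predict_release_profile(models, w, x = 15, times = seq(0, 100, 5))
#' @export
predict_release_profile <- function(models, weights, x,
                                    times = seq(0, 100, length.out = 101L),
                                    gamma = osmotic_gamma(),
                                    thickness = 0.002, label = NULL,
                                    band = 0.5) {
  need <- c("mu_burst", "mu_diffusion", "mu_osmosis", "x")
  if (!is.data.frame(weights) || !all(need %in% names(weights)) ||
      nrow(weights) < 2L) {
    stop("`weights` must be a data frame with columns x, mu_burst, ",
         "mu_diffusion, mu_osmosis and at least 2 rows", call. = FALSE)
  }
  for (nm in c("k_b", "D_e")) {
    if (!inherits(models[[nm]], "correlation_model")) {
      stop(sprintf("`models$%s` must be a correlation_model", nm),
           call. = FALSE)
    }
  }
  if (!inherits(models[["k_os"]], "correlation_model") &&
      !inherits(models[["delta_pi"]], "correlation_model")) {
    stop("`models` must contain a correlation_model for `k_os` or `delta_pi`",
         call. = FALSE)
  }
  ord <- order(weights$x)
  interp <- function(col) {
    stats::approx(weights$x[ord], weights[[col]][ord], xout = x,
                  rule = 2)$y
  }
  mu <- c(interp("mu_burst"), interp("mu_diffusion"), interp("mu_osmosis"))
  mu <- pmin(pmax(mu, 0), 1)
  if (sum(mu) <= 0) stop("interpolated weights are degenerate", call. = FALSE)
  mu <- mu / sum(mu)
  k_b <- predict_constant(models$k_b, x, band)
  D_e <- predict_constant(models$D_e, x, band)
  k_os <- if (inherits(models[["k_os"]], "correlation_model")) {
    predict_constant(models$k_os, x, band)
  } else {
    osmotic_slope(NULL, predict_constant(models$delta_pi, x, band),
                  gamma = gamma)
  }
  params <- composite_params(mu, k_b = k_b, D_e = D_e,
                             k_os = max(k_os, 0))
  out <- composite_release(params, times, thickness = thickness,
                           label = label)
  attr(out, "params") <- params
  out
}
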