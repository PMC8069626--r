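tab1 <- builtin_conditions()
conc_set <- tab1[tab1$flow == 7.5, ]
flow_set <- tab1[tab1$drug_load == 20, ]

test_that("concentration correlation reproduces closed-form least squares", {
  m <- fit_concentration_correlation(conc_set$drug_load, conc_set$k_b, "k_b")
  oracle <- hand_lm(1 / conc_set$drug_load, log(conc_set$k_b))
  expect_equal(m$coefficients, oracle, tolerance = 1e-12)
  # prediction at a training load agrees with the hand-evaluated line
  expect_equal(predict_constant(m, 20), exp(oracle["a"] + oracle["b"] / 20),
               ignore_attr = TRUE)
  # within the fit residual of the three-point regression at C = 20
  resid <- abs(log(conc_set$k_b) - (oracle["a"] + oracle["b"] /
                                      conc_set$drug_load))
  expect_lt(abs(log(predict_constant(m, 20)) - log(2.5)), max(resid) + 1e-12)
  # interior prediction by hand
  expect_equal(predict_constant(m, 15), exp(oracle["a"] + oracle["b"] / 15),
               ignore_attr = TRUE)
})

test_that("two points give exact interpolation and scaling shifts the intercept", {
  m <- fit_concentration_correlation(c(10, 30), c(1.5, 3.4))
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict_constant(m, 10), 1.5, tolerance = 1e-12)
  expect_equal(predict_constant(m, 30), 3.4, tolerance = 1e-12)
  m1 <- fit_concentration_correlation(c(10, 20, 30), c(1.5, 2.5, 3.4))
  m2 <- fit_concentration_correlation(c(10, 20, 30), 7 * c(1.5, 2.5, 3.4))
  expect_equal(m2$coefficients[["b"]], m1$coefficients[["b"]])
  expect_equal(m2$coefficients[["a"]], m1$coefficients[["a"]] + log(7))
})

test_that("flow correlation is linear with a positive trend for the burst constant", {
  m <- fit_flow_correlation(flow_set$flow, flow_set$k_b, "k_b")
  expect_gt(m$coefficients[["b"]], 0)
  oracle <- hand_lm(flow_set$flow, flow_set$k_b)
  expect_equal(m$coefficients, oracle, tolerance = 1e-12)
  expect_equal(predict_constant(m, flow_set$flow),
               unname(oracle["a"] + oracle["b"] * flow_set$flow))
})

test_that("exactly linear and log-linear inputs are recovered exactly", {
  C <- c(5, 10, 20, 40)
  k <- exp(2 - 5 / C)
  m <- fit_concentration_correlation(C, k)
  expect_equal(m$coefficients, c(a = 2, b = -5), tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  Q <- c(0, 5, 10, 25)
  m2 <- fit_flow_correlation(Q, 0.3 + 0.1 * Q)
  expect_equal(m2$coefficients, c(a = 0.3, b = 0.1), tolerance = 1e-12)
})

test_that("zero-intercept variants fit the classical one-parameter forms", {
  C <- c(10, 20, 30)
  k <- c(1.5, 2.5, 3.4)
  m <- fit_concentration_correlation(C, k, intercept = FALSE)
  expect_identical(m$coefficients[["a"]], 0)
  x <- 1 / C
  y <- log(k)
  expect_equal(m$coefficients[["b"]], sum(x * y) / sum(x^2))
  mf <- fit_flow_correlation(c(5, 10), c(1, 2.2), intercept = FALSE)
  expect_identical(mf$coefficients[["a"]], 0)
})

test_that("predictions stay positive and extrapolation warns", {
  m <- fit_concentration_correlation(c(10, 20, 30), c(1.5, 2.5, 3.4))
  expect_true(all(suppressWarnings(predict_constant(m, c(1, 5, 50, 200))) > 0))
  expect_warning(predict_constant(m, 200), "outside")
  expect_silent(predict_constant(m, 25))
  expect_error(fit_concentration_correlation(c(10, 20), c(-1, 2)),
               "positive")
  expect_error(fit_flow_correlation(7.5, 2.5), "at least 2")
})

test_that("profile prediction at a training knot reproduces the forward simulation", {
  # two-point correlations interpolate the knots exactly, so the predicted
  # profile at a training load must coincide with the direct simulation
  sub <- conc_set[conc_set$drug_load %in% c(10, 20), ]
  models <- list(
    k_b = fit_concentration_correlation(sub$drug_load, sub$k_b, "k_b"),
    D_e = fit_concentration_correlation(sub$drug_load, sub$D_e, "D_e"),
    k_os = fit_concentration_correlation(sub$drug_load, sub$k_os, "k_os"))
  w <- data.frame(x = sub$drug_load, mu_burst = sub$mu_burst,
                  mu_diffusion = sub$mu_diffusion,
                  mu_osmosis = sub$mu_osmosis)
  times <- seq(0, 100, by = 5)
  pred <- predict_release_profile(models, w, x = 20, times = times)
  direct <- composite_release(condition_params("PU-20DE-Q7.5"), times)
  expect_lt(max(abs(pred$fractions - direct$fractions)), 1e-9)
})

test_that("interpolated weights are a valid simplex and bracket the reserved case", {
  models <- list(
    k_b = fit_concentration_correlation(conc_set$drug_load, conc_set$k_b),
    D_e = fit_concentration_correlation(conc_set$drug_load, conc_set$D_e),
    k_os = fit_concentration_correlation(conc_set$drug_load, conc_set$k_os))
  w <- data.frame(x = conc_set$drug_load, mu_burst = conc_set$mu_burst,
                  mu_diffusion = conc_set$mu_diffusion,
                  mu_osmosis = conc_set$mu_osmosis)
  times <- seq(0, 24, by = 1)
  pred15 <- predict_release_profile(models, w, x = 15, times = times)
  p <- attr(pred15, "params")
  expect_equal(sum(p$mu), 1, tolerance = 1e-9)
  expect_true(all(p$mu >= 0 & p$mu <= 1))
  # reserved case lies between its bracketing conditions early on
  lo <- composite_release(condition_params("PU-10DE-Q7.5"), times)$fractions
  hi <- composite_release(condition_params("PU-20DE-Q7.5"), times)$fractions
  mid <- pred15$fractions
  expect_true(all(mid[-1] >= pmin(lo, hi)[-1] - 1e-9))
  expect_true(all(mid[-1] <= pmax(lo, hi)[-1] + 1e-9))
  # missing constant model is an input error
  expect_error(predict_release_profile(models[c("k_b", "D_e")], w, x = 15),
               "k_os")
})
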