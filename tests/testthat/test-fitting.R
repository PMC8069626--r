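test_that("rmse and r_squared match hand arithmetic", {
  expect_identical(rmse(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(rmse(c(0, 1), c(1, 0)), 1)          # sqrt((1 + 1)/2)
  expect_equal(rmse(c(0, 1), c(1, 0)), rmse(c(1, 0), c(0, 1)))
  expect_error(rmse(1:3, 1:2), "equal")

  expect_equal(r_squared(c(0.1, 0.4, 0.5, 0.8), c(0.1, 0.4, 0.5, 0.8)), 1)
  obs <- c(0.1, 0.4, 0.5, 0.8)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  # hand computation: SSres = 0.0175, SStot = 0.25
  expect_equal(r_squared(obs, c(0.15, 0.35, 0.55, 0.7)), 1 - 0.0175 / 0.25)
  expect_error(r_squared(c(0.3, 0.3), c(0.1, 0.2)), "zero-variance")
})

test_that("multistart grid is deterministic, feasible, and combinatorially right", {
  s <- fit_settings()
  g1 <- multistart_grid(s)
  g2 <- multistart_grid(s)
  expect_identical(g1, g2)
  # resolution 2 over 3 weights: choose(4, 2) = 6 lattice points + centroid
  w <- unique(g1[, c("mu_burst", "mu_diffusion", "mu_osmosis")])
  expect_equal(nrow(w), 6 + 1)
  # resolution 3 contains the centroid already: choose(5, 2) = 10 points
  w3 <- unique(multistart_grid(fit_settings(resolution = 3))[, 1:3])
  expect_equal(nrow(w3), 10)
  # every start satisfies the simplex and bound constraints
  expect_true(all(abs(rowSums(g1[, 1:3]) - 1) < 1e-12))
  expect_true(all(g1$k_b >= s$k_b_bounds[1] & g1$k_b <= s$k_b_bounds[2]))
  expect_true(all(g1$D_e >= s$D_e_bounds[1] & g1$D_e <= s$D_e_bounds[2]))
  expect_true(all(g1$k_os >= s$k_os_bounds[1] & g1$k_os <= s$k_os_bounds[2]))
  # random extra starts are reproducible from the seed
  r1 <- multistart_grid(fit_settings(n_random = 3, seed = 9))
  r2 <- multistart_grid(fit_settings(n_random = 3, seed = 9))
  expect_identical(r1, r2)
})

test_that("a noiseless synthetic profile is recovered to fractions of a percent", {
  truth <- condition_params("PU-20DE-Q0")
  prof <- generate_profile(truth, noise_sd = 0)
  fit <- fit_release(prof)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$k_b / truth$k_b - 1), 1e-3)
  expect_lt(abs(fit$params$D_e / truth$D_e - 1), 1e-3)
  expect_lt(abs(fit$params$k_os / truth$k_os - 1), 1e-3)
  expect_lt(max(abs(fit$params$mu - truth$mu)), 1e-4)
  expect_equal(sum(fit$contributions), 100, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-6)
  # the returned optimum is at least as good as every start it explored
  expect_true(all(fit$objective <= fit$starts$objective_initial + 1e-12))
})

test_that("a pure burst profile collapses onto the burst vertex", {
  t <- seq(0, 20, length.out = 41)
  prof <- release_profile(t, burst_fraction(2.5, t))
  fit <- fit_release(prof)
  expect_gt(fit$contributions[["burst"]], 99.99)
  expect_lt(fit$rmse, 1e-6)
  expect_lt(abs(fit$params$k_b - 2.5), 1e-3)
})

test_that("refitting the model's own predictions is idempotent", {
  fit <- fit_release(generate_profile("PU-20DE-Q7.5", noise_sd = 0))
  refit <- fit_release(predict(fit))
  expect_lt(abs(refit$params$k_b / fit$params$k_b - 1), 1e-5)
  expect_lt(abs(refit$params$D_e / fit$params$D_e - 1), 1e-5)
  expect_lt(abs(refit$params$k_os / fit$params$k_os - 1), 1e-5)
  expect_lt(max(abs(refit$params$mu - fit$params$mu)), 1e-6)
})

test_that("degenerate and invalid inputs are rejected with clear errors", {
  expect_error(fit_release(release_profile(0:4, c(0, 0.2, 0.3, 0.4, 0.5))),
               "at least 6")
  expect_error(fit_release(release_profile(0:9, rep(0, 10))),
               "zero variance")
  expect_error(fit_release(release_profile(0:9, c(0, rep(1.5, 9)))),
               "1.2")
})

test_that("noisy recovery of the kinetic constants is information-efficient", {
  # Relative errors of the constrained least-squares fit are compared with
  # the Cramer-Rao bound of the generating conditions: the median over
  # seeds should sit within sampling slack of the bound, which is the
  # strongest guarantee the noise level and sampling grid admit.
  cond <- "PU-10DE-Q7.5"
  truth <- condition_params(cond)
  times <- seq(0, 100, length.out = 101)
  noise_sd <- 0.01

  # independent information bound: numeric Jacobian in the reduced
  # parameterisation (mu1, mu2, kb, De, kos), mu3 eliminated
  th <- c(truth$mu[[1]], truth$mu[[2]], truth$k_b, truth$D_e, truth$k_os)
  model <- function(p) {
    (1 - p[1] - p[2]) * osmotic_fraction(p[5], times) +
      p[1] * burst_fraction(p[3], times) +
      p[2] * diffusion_fraction(p[4], 0.002, times)
  }
  f0 <- model(th)
  J <- vapply(seq_along(th), function(j) {
    h <- 1e-6 * abs(th[j])
    p <- th
    p[j] <- p[j] + h
    (model(p) - f0) / h
  }, numeric(length(times)))
  rel_se <- sqrt(diag(noise_sd^2 * solve(crossprod(J %*% diag(th)))))
  crlb_median <- 0.6745 * rel_se   # median |N(0, se)| = 0.6745 se

  kb_err <- de_err <- numeric(20)
  for (s in 1:20) {
    fit <- fit_release(generate_profile(cond, noise_sd = noise_sd, seed = s))
    kb_err[s] <- abs(fit$params$k_b / truth$k_b - 1)
    de_err[s] <- abs(fit$params$D_e / truth$D_e - 1)
  }
  expect_lt(median(kb_err), 1.6 * crlb_median[3])
  expect_lt(median(de_err), 1.6 * crlb_median[4])
  # coarse absolute caps implied by the information bound for this condition
  expect_lt(median(kb_err), 0.20)
  expect_lt(median(de_err), 0.25)
})
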