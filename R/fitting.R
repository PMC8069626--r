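#' Root-mean-squared error between observed and predicted fractions
#'
#' @param observed,predicted Numeric vectors of equal nonzero length.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @examples
#' rmse(c(0, 1), c(1, 0))   # 1
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal nonzero length",
         call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about
#' the observed mean.
#'
#' @inheritParams rmse
#' @return Scalar `R^2`; 1 for a perfect prediction, 0 when predicting the
#'   observed mean everywhere. Errors when the observed values have zero
#'   variance (the metric is undefined there).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal nonzero length",
         call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined for zero-variance observations", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Settings for composite-model fitting
#'
#' @param resolution Simplex-lattice resolution for the mechanism-weight
#'   starting points; resolution `m` yields `choose(m + 2, 2)` weight
#'   combinations (default 2, i.e. the three vertices and three edge
#'   midpoints), plus the centroid.
#' @param n_kinetic Number of log-spaced starting tuples for the kinetic
#'   constants, taken at interior points of the bounds (default 2).
#' @param n_random Additional random simplex-weight starts (default 0).
#' @param seed Seed for the random starts; ignored when `n_random = 0`.
#' @param k_b_bounds,D_e_bounds,k_os_bounds Lower/upper bounds for the
#'   kinetic constants. Defaults are wide enough to contain all fitted
#'   values reported for this system.
#' @param thickness Film thickness for the diffusion term, m.
#' @param series_tol Diffusion-series truncation tolerance.
#' @param early_stop Stop the multistart early once a start reaches a sum of
#'   squared residuals at or below this value (an essentially perfect fit).
#' @param order_constraint Impose the identifiability constraint
#'   `k_b >= pi^2 * D_e / h^2` (default `TRUE`): the burst must relax at
#'   least as fast as the leading diffusion mode, otherwise the two
#'   saturating terms can swap roles under noise (label switching) and the
#'   mechanism assignment loses meaning.
#' @param sqp Control list for the SQP runs; see [sqp_control()]. Fitting
#'   uses a tighter KKT tolerance than the solver default so recovered
#'   parameters are accurate to well below 0.1%.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(resolution = 2L, n_kinetic = 2L, n_random = 0L,
                         seed = 1L,
                         k_b_bounds = c(1e-3, 100),
                         D_e_bounds = c(1e-12, 1e-5),
                         k_os_bounds = c(0, 1),
                         thickness = 0.002,
                         series_tol = 1e-12,
                         early_stop = 1e-14,
                         order_constraint = TRUE,
                         sqp = sqp_control(tol = 1e-10, max_iter = 250L)) {
  stopifnot(resolution >= 1, n_kinetic >= 1, n_random >= 0)
  check_bounds <- function(b, name, allow_zero = FALSE) {
    if (length(b) != 2L || anyNA(b) || b[1L] > b[2L] ||
        b[1L] < 0 || (!allow_zero && b[1L] <= 0)) {
      stop(sprintf("`%s` must be ordered positive bounds", name),
           call. = FALSE)
    }
  }
  check_bounds(k_b_bounds, "k_b_bounds")
  check_bounds(D_e_bounds, "D_e_bounds")
  check_bounds(k_os_bounds, "k_os_bounds", allow_zero = TRUE)
  if (!inherits(sqp, "sqp_control")) sqp <- do.call(sqp_control, sqp)
  structure(list(resolution = as.integer(resolution),
                 n_kinetic = as.integer(n_kinetic),
                 n_random = as.integer(n_random), seed = as.integer(seed),
                 k_b_bounds = k_b_bounds, D_e_bounds = D_e_bounds,
                 k_os_bounds = k_os_bounds, thickness = thickness,
                 series_tol = series_tol, early_stop = early_stop,
                 order_constraint = isTRUE(order_constraint), sqp = sqp),
            class = "fit_settings")
}

# All weight triples on the simplex lattice of a given resolution.
simplex_lattice <- function(resolution) {
  m <- as.integer(resolution)
  out <- list()
  for (i in 0:m) {
    for (j in 0:(m - i)) {
      out[[length(out) + 1L]] <- c(i, j, m - i - j) / m
    }
  }
  do.call(rbind, out)
}

#' Deterministic multistart grid for composite-model fitting
#'
#' Builds the starting points used by [fit_release()]: simplex-lattice
#' mechanism-weight combinations (plus the centroid, and optionally random
#' simplex draws) crossed with log-spaced kinetic-constant tuples taken at
#' interior points of the bounds. The grid is a deterministic function of
#' the settings (including the seed for any random starts).
#'
#' @param settings A [fit_settings()] object.
#' @return A data frame with columns `mu_burst`, `mu_diffusion`,
#'   `mu_osmosis`, `k_b`, `D_e`, `k_os`, one row per start. Every row
#'   satisfies the simplex and bound constraints.
#' @examples
#' nrow(multistart_grid(fit_settings()))   # (6 lattice + centroid) x 2
#' @export
multistart_grid <- function(settings = fit_settings()) {
  stopifnot(inherits(settings, "fit_settings"))
  w <- simplex_lattice(settings$resolution)
  centroid <- rep(1 / 3, 3)
  if (!any(apply(w, 1L, function(r) max(abs(r - centroid)) < 1e-12))) {
    w <- rbind(w, centroid)
  }
  if (settings$n_random > 0L) {
    rng <- local({
      set.seed(settings$seed)
      m <- matrix(stats::rexp(3L * settings$n_random), ncol = 3L)
      m / rowSums(m)
    })
    w <- rbind(w, rng)
  }
  log_interior <- function(bounds, n, floor_pos = 1e-4) {
    lo <- max(bounds[1L], floor_pos)
    hi <- max(bounds[2L], lo * 10)
    pts <- exp(seq(log(lo), log(hi), length.out = n + 2L))
    pts[seq_len(n) + 1L]
  }
  kb <- log_interior(settings$k_b_bounds, settings$n_kinetic)
  de <- log_interior(settings$D_e_bounds, settings$n_kinetic, 1e-13)
  kos <- log_interior(settings$k_os_bounds, settings$n_kinetic)
  starts <- do.call(rbind, lapply(seq_len(settings$n_kinetic), function(i) {
    cbind(w, kb[i], de[i], kos[i])
  }))
  colnames(starts) <- c("mu_burst", "mu_diffusion", "mu_osmosis",
                        "k_b", "D_e", "k_os")
  as.data.frame(starts)
}

# Residuals and analytic Jacobian of the composite model on the profile
# grid, in the internal parameterisation
# theta = (mu1, mu2, mu3, k_b, log10(D_e), k_os).
make_lsq_functions <- function(times, observed, thickness, series_tol) {
  h2 <- thickness^2
  model_parts <- function(theta) {
    k_b <- theta[4L]
    D_e <- 10^theta[5L]
    k_os <- theta[6L]
    F1 <- 1 - exp(-k_b * times)
    F2 <- diffusion_fraction(D_e, thickness, times, series_tol)
    F3 <- k_os * times
    list(F1 = F1, F2 = F2, F3 = F3, k_b = k_b, D_e = D_e, k_os = k_os)
  }
  objective <- function(theta) {
    p <- model_parts(theta)
    r <- theta[1L] * p$F1 + theta[2L] * p$F2 + theta[3L] * p$F3 - observed
    sum(r^2)
  }
  gradient <- function(theta) {
    p <- model_parts(theta)
    r <- theta[1L] * p$F1 + theta[2L] * p$F2 + theta[3L] * p$F3 - observed
    # dF2/dD_e via the same truncated odd-index series
    rate <- pi^2 * p$D_e / h2
    dF2 <- numeric(length(times))
    pos <- times > 0
    if (any(pos)) {
      tp <- times[pos]
      acc <- numeric(length(tp))
      for (n in 0:9999) {
        m <- 2 * n + 1
        term <- exp(-m^2 * rate * tp)
        acc <- acc + term
        if (max(term) < series_tol) break
      }
      dF2[pos] <- (8 * tp / h2) * acc
    }
    J <- cbind(p$F1, p$F2, p$F3,
               theta[1L] * times * exp(-p$k_b * times),
               theta[2L] * dF2 * p$D_e * log(10),
               theta[3L] * times)
    drop(2 * crossprod(J, r))
  }
  list(objective = objective, gradient = gradient)
}

#' Fit the composite release model to a profile
#'
#' Estimates the six composite-model parameters -- the simplex-constrained
#' mechanism weights `(mu1, mu2, mu3)` and the kinetic constants
#' `(k_b, D_e, k_os)` -- by minimising the unweighted sum of squared
#' residuals between the model and the observed cumulative fractions,
#' subject to `sum(mu) = 1`, `0 <= mu_i <= 1` and positivity bounds on the
#' constants. The constrained problem is solved by the package's SQP engine
#' ([solve_sqp()]) from a deterministic multistart grid
#' ([multistart_grid()]); the best start by final objective is returned.
#' `D_e` is optimised on a log10 scale internally (its admissible range
#' spans seven decades) and reported on the natural scale.
#'
#' @param profile A [release_profile()] with at least 6 points; fractions
#'   must lie in `[0, 1.2]` (cumulative data may overshoot 1 through
#'   observation noise, and the zero-order osmotic term itself can carry
#'   the composite slightly above 1 late in a long window).
#' @param geometry Optional [geometry_constants()] used to convert the
#'   fitted osmotic slope into a pressure gradient; when absent, the
#'   documented default conversion factor is used (see [osmotic_gamma()]).
#' @param settings A [fit_settings()] object.
#' @return An object of class `fit_result`: list with `params`
#'   (a [composite_params()]), `contributions` (named percentages summing
#'   to 100), `delta_pi` (atm, under the recorded `gamma`), `gamma`,
#'   `rmse`, `r_squared`, `objective` (sum of squared residuals),
#'   `converged`, `n_starts_used`, `starts` (per-start objective table),
#'   `thickness` and the input `profile`.
#' @examples
#' truth <- composite_params(c(0.313, 0.559, 0.128), 2.5, 1.62e-8, 0.01)
#' prof <- composite_release(truth, seq(0, 100, by = 2))
#' fit <- fit_release(prof)
#' fit
#' @export
fit_release <- function(profile, geometry = NULL, settings = fit_settings()) {
  stopifnot(inherits(profile, "release_profile"),
            inherits(settings, "fit_settings"))
  times <- profile$times
  obs <- profile$fractions
  if (length(times) < 6L) {
    stop("profile must have at least 6 points to fit 6 parameters",
         call. = FALSE)
  }
  if (any(obs < 0) || any(obs > 1.2)) {
    stop("fractions must lie in [0, 1.2]", call. = FALSE)
  }
  if (stats::sd(obs) == 0) {
    stop("degenerate profile: observed fractions have zero variance",
         call. = FALSE)
  }

  fns <- make_lsq_functions(times, obs, settings$thickness,
                            settings$series_tol)
  lb <- c(0, 0, 0, settings$k_b_bounds[1L], log10(settings$D_e_bounds[1L]),
          settings$k_os_bounds[1L])
  ub <- c(1, 1, 1, settings$k_b_bounds[2L], log10(settings$D_e_bounds[2L]),
          settings$k_os_bounds[2L])
  eq <- function(theta) sum(theta[1:3]) - 1
  eq_jac <- function(theta) matrix(c(1, 1, 1, 0, 0, 0), nrow = 1L)
  # label-switching guard: leading diffusion rate must not exceed k_b
  h2 <- settings$thickness^2
  ineq <- if (settings$order_constraint) {
    function(theta) pi^2 * 10^theta[5L] / h2 - theta[4L]
  }
  ineq_jac <- if (settings$order_constraint) {
    function(theta) matrix(c(0, 0, 0, -1,
                             pi^2 * 10^theta[5L] * log(10) / h2, 0),
                           nrow = 1L)
  }

  grid <- multistart_grid(settings)
  start_obj <- numeric(nrow(grid))
  results <- vector("list", nrow(grid))
  n_used <- 0L
  for (i in seq_len(nrow(grid))) {
    theta0 <- c(grid$mu_burst[i], grid$mu_diffusion[i], grid$mu_osmosis[i],
                grid$k_b[i], log10(grid$D_e[i]), grid$k_os[i])
    start_obj[i] <- fns$objective(theta0)
    pr <- optimization_problem(fns$objective, theta0,
                               gradient = fns$gradient,
                               eq = eq, eq_jacobian = eq_jac,
                               ineq = ineq, ineq_jacobian = ineq_jac,
                               lower = lb, upper = ub)
    results[[i]] <- solve_sqp(pr, settings$sqp)
    n_used <- n_used + 1L
    if (results[[i]]$objective <= settings$early_stop) break
  }
  ran <- seq_len(n_used)
  final_obj <- vapply(results[ran], `[[`, numeric(1), "objective")
  best_i <- ran[which.min(final_obj)]
  sol <- results[[best_i]]

  theta <- sol$x
  mu <- pmin(pmax(theta[1:3], 0), 1)
  mu <- mu / sum(mu)
  clamp <- function(v, b) min(max(v, b[1L]), b[2L])
  params <- composite_params(mu,
                             k_b = clamp(theta[4L], settings$k_b_bounds),
                             D_e = clamp(10^theta[5L], settings$D_e_bounds),
                             k_os = clamp(theta[6L], settings$k_os_bounds))
  gamma <- osmotic_gamma(geometry)
  pred <- composite_fractions(params, times, settings$thickness,
                              settings$series_tol)
  starts <- data.frame(start = ran,
                       objective_initial = start_obj[ran],
                       objective_final = final_obj,
                       converged = vapply(results[ran], `[[`, logical(1),
                                          "converged"))
  structure(list(params = params,
                 contributions = 100 * params$mu,
                 delta_pi = delta_pi_from_slope(NULL, params$k_os,
                                                gamma = gamma),
                 gamma = gamma,
                 rmse = rmse(obs, pred),
                 r_squared = r_squared(obs, pred),
                 objective = sol$objective,
                 converged = sol$converged ||
                   sol$objective <= settings$early_stop,
                 n_starts_used = n_used,
                 starts = starts,
                 thickness = settings$thickness,
                 series_tol = settings$series_tol,
                 profile = profile),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  lab <- if (is.na(x$profile$label)) "" else sprintf(" '%s'", x$profile$label)
  cat(sprintf("Composite release fit%s (%s, %d start%s)\n", lab,
              if (x$converged) "converged" else "NOT converged",
              x$n_starts_used, if (x$n_starts_used == 1L) "" else "s"))
  cat(sprintf("  Burst     %5.1f %%   k_b  = %.4g 1/h\n",
              x$contributions[["burst"]], x$params$k_b))
  cat(sprintf("  Diffusion %5.1f %%   D_e  = %.4g m^2/h\n",
              x$contributions[["diffusion"]], x$params$D_e))
  cat(sprintf("  Osmosis   %5.1f %%   k_os = %.4g 1/h  (delta_pi = %.4g atm at gamma = %g)\n",
              x$contributions[["osmosis"]], x$params$k_os, x$delta_pi,
              x$gamma))
  cat(sprintf("  RMSE = %.4g, R^2 = %.4f\n", x$rmse, x$r_squared))
  invisible(x)
}

#' Predicted release curve of a fitted model
#'
#' @param object A `fit_result`.
#' @param times Optional time grid; defaults to the fitted profile's grid.
#' @param ... Unused.
#' @return A [release_profile()] of model predictions.
#' @export
predict.fit_result <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$profile$times
  composite_release(object$params, times, thickness = object$thickness,
                    series_tol = object$series_tol,
                    label = object$profile$label)
}

#' Overlay a fitted composite model on the observed profile
#'
#' @param x A `fit_result`.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.fit_result <- function(x, ...) {
  obs <- x$profile
  grid <- seq(min(obs$times), max(obs$times), length.out = 200L)
  pred <- predict(x, grid)
  plot(obs$times, obs$fractions, xlab = "time (h)",
       ylab = "fraction released", ylim = range(0, obs$fractions,
                                                pred$fractions), ...)
  lines(pred$times, pred$fractions, lwd = 2)
  invisible(x)
}
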