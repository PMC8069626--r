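#' Built-in fitted parameter sets for the diclofenac/polyurethane system
#'
#' The five reference conditions for diclofenac epolamine release from 2 mm
#' polyurethane films: three drug loads (10, 20, 30 % w/w) at a flow rate of
#' 7.5 mL/s, and three flow rates (0, 7.5, 23.5 mL/s) at 20 % drug load.
#' Each condition carries the fitted mechanism contributions and kinetic
#' constants; the osmotic zero-order slope is derived from the tabulated
#' pressure gradient as `k_os = gamma * delta_pi`.
#'
#' @param gamma Osmotic conversion factor, 1/(h*atm); defaults to the
#'   documented package default (see [osmotic_gamma()]).
#' @return A data frame with one row per condition and columns `condition`,
#'   `drug_load` (% w/w), `flow` (mL/s), `mu_burst`, `mu_diffusion`,
#'   `mu_osmosis` (weights, each column of weights summing to 1 per row),
#'   `k_b` (1/h), `D_e` (m^2/h), `delta_pi` (atm) and `k_os` (1/h).
#' @examples
#' builtin_conditions()
#' @export
builtin_conditions <- function(gamma = osmotic_gamma()) {
  tab <- data.frame(
    condition = c("PU-10DE-Q7.5", "PU-20DE-Q7.5", "PU-30DE-Q7.5",
                  "PU-20DE-Q0", "PU-20DE-Q23.5"),
    drug_load = c(10, 20, 30, 20, 20),
    flow      = c(7.5, 7.5, 7.5, 0, 23.5),
    mu_burst     = c(23.2, 31.3, 36.0, 29.0, 31.9) / 100,
    mu_osmosis   = c(11.1, 12.8, 14.7,  9.0, 14.6) / 100,
    mu_diffusion = c(65.7, 55.9, 49.3, 62.0, 53.5) / 100,
    k_b      = c(1.5, 2.5, 3.4, 1.7, 3.9),
    D_e      = c(1.1e-8, 1.62e-8, 1.96e-8, 8.7e-9, 2.77e-8),
    delta_pi = c(0.005, 0.009, 0.014, 0.007, 0.012),
    stringsAsFactors = FALSE
  )
  tab$k_os <- osmotic_slope(NULL, tab$delta_pi, gamma = gamma)
  tab[, c("condition", "drug_load", "flow", "mu_burst", "mu_diffusion",
          "mu_osmosis", "k_b", "D_e", "delta_pi", "k_os")]
}

#' Composite parameters of a built-in condition
#'
#' @param condition Condition name, e.g. `"PU-20DE-Q7.5"` (see
#'   [builtin_conditions()] for the five available names).
#' @inheritParams builtin_conditions
#' @return A [composite_params()] object.
#' @examples
#' condition_params("PU-20DE-Q7.5")
#' @export
condition_params <- function(condition, gamma = osmotic_gamma()) {
  tab <- builtin_conditions(gamma)
  i <- match(condition, tab$condition)
  if (is.na(i)) {
    stop(sprintf("unknown condition '%s'; available: %s", condition,
                 paste(tab$condition, collapse = ", ")), call. = FALSE)
  }
  composite_params(c(tab$mu_burst[i], tab$mu_diffusion[i], tab$mu_osmosis[i]),
                   k_b = tab$k_b[i], D_e = tab$D_e[i], k_os = tab$k_os[i])
}

#' Generate a synthetic release profile
#'
#' Evaluates the composite forward model on a time grid and adds i.i.d.
#' Gaussian observation noise on the fraction scale, emulating cumulative
#' release measurements. Negative noisy values are clipped to 0 by default;
#' values slightly above 1 are left as-is, matching real cumulative-release
#' data.
#'
#' @param params A [composite_params()] object, or a condition name
#'   accepted by [condition_params()].
#' @param times Sampling grid, hours (default 0--100 h, 101 points: spans
#'   the burst, osmotic and diffusion-dominated regimes for the built-in
#'   parameter sets).
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   fraction units (default 0.01); 0 returns the exact forward model.
#' @param seed Optional integer seed; when supplied the output is a pure
#'   function of the arguments.
#' @param clip_negative Clip negative noisy values to 0 (default `TRUE`).
#' @param thickness Film thickness for the diffusion term, m.
#' @param label Label for the profile; defaults to the condition name when
#'   `params` is given by name.
#' @return A [release_profile()]; attribute `"truth"` records the
#'   generating parameters, seed and noise level.
#' @examples
#' p <- generate_profile("PU-20DE-Q7.5", noise_sd = 0.02, seed = 1)
#' attr(p, "truth")$params
#' @export
generate_profile <- function(params, times = seq(0, 100, length.out = 101L),
                             noise_sd = 0.01, seed = NULL,
                             clip_negative = TRUE, thickness = 0.002,
                             label = NULL) {
  if (is.character(params)) {
    if (is.null(label)) label <- params
    params <- condition_params(params)
  }
  stopifnot(inherits(params, "composite_params"))
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  f <- composite_fractions(params, times, thickness)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    f <- f + stats::rnorm(length(f), sd = noise_sd)
    if (clip_negative) f <- pmax(f, 0)
  }
  out <- release_profile(times, f, label = label)
  attr(out, "truth") <- list(params = params, seed = seed,
                             noise_sd = noise_sd, thickness = thickness)
  out
}
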