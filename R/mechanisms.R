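#' Burst-release fraction
#'
#' First-order approach to complete release of the loosely bound surface
#' drug: `F1(t) = 1 - exp(-k_b * t)`.
#'
#' @param k_b Burst rate constant, 1/h; strictly positive.
#' @param t Time(s), hours; nonnegative. Vectorised.
#' @return Fraction(s) released by the burst mechanism, in `[0, 1)`.
#' @examples
#' burst_fraction(2.5, c(0, 0.5, 1, 5))
#' @export
burst_fraction <- function(k_b, t) {
  if (!is.finite(k_b) || k_b <= 0) stop("`k_b` must be > 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  1 - exp(-k_b * t)
}

#' Fickian plane-sheet diffusion fraction (exact series)
#'
#' Cumulative fraction released by diffusion from a plane sheet of thickness
#' `h` under perfect sink conditions and initially uniform loading:
#' \deqn{F_2(t) = 1 - \frac{8}{\pi^2} \sum_{n=0}^{\infty}
#'   \frac{1}{(2n+1)^2} \exp\!\left(-\frac{(2n+1)^2 \pi^2 D_e t}{h^2}\right)}
#' The series runs over odd indices `2n+1`, which makes `F2(0) = 0` exactly
#' (the odd reciprocal squares sum to `pi^2/8`). It is truncated as soon as
#' the next term's magnitude falls below `tol`, with a hard cap of 10,000
#' terms.
#'
#' @param D_e Effective diffusion coefficient, m^2/h; strictly positive.
#' @param thickness Sheet thickness `h`, m; strictly positive.
#' @param t Time(s), hours; nonnegative. Vectorised.
#' @param tol Series truncation tolerance (default `1e-12`).
#' @return Fraction(s) released by diffusion, in `[0, 1)`.
#' @examples
#' diffusion_fraction(1.62e-8, 0.002, c(0, 1, 10, 100))
#' @export
diffusion_fraction <- function(D_e, thickness, t, tol = 1e-12) {
  if (!is.finite(D_e) || D_e <= 0) stop("`D_e` must be > 0", call. = FALSE)
  if (!is.finite(thickness) || thickness <= 0) {
    stop("`thickness` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (!is.finite(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  rate <- pi^2 * D_e / thickness^2    # 1/h, decay rate of the leading mode
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    s <- numeric(length(tp))
    active <- rep(TRUE, length(tp))
    for (n in 0:9999) {
      m <- 2 * n + 1
      term <- exp(-m^2 * rate * tp[active]) / m^2
      s[active] <- s[active] + term
      still <- term >= tol
      if (!any(still)) break
      if (n == 9999L) break
      # keep iterating only where the last term was still above tol
      active[active] <- still
      if (!any(active)) break
    }
    out[pos] <- 1 - (8 / pi^2) * s
  }
  # t == 0 entries are exactly 0 by construction of the odd-index series
  pmax(out, 0)
}

#' Early-time diffusion approximation
#'
#' Square-root-of-time law for the initial stage of plane-sheet diffusion:
#' `Mt/Minf = 4 * sqrt(D_e * t / (pi * h^2))`. The approximation is accurate
#' up to roughly 60% cumulative release; a warning is issued when the
#' returned value exceeds 0.6.
#'
#' @inheritParams diffusion_fraction
#' @return Approximate fraction(s) released; can exceed 1 at late times
#'   (outside the law's validity range).
#' @examples
#' diffusion_early_approx(1.62e-8, 0.002, c(0, 1, 4))
#' @export
diffusion_early_approx <- function(D_e, thickness, t) {
  if (!is.finite(D_e) || D_e <= 0) stop("`D_e` must be > 0", call. = FALSE)
  if (!is.finite(thickness) || thickness <= 0) {
    stop("`thickness` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  val <- 4 * sqrt(D_e * t / (pi * thickness^2))
  if (any(val > 0.6)) {
    warning("early-time approximation used beyond 60% release; ",
            "values above 0.6 are unreliable", call. = FALSE)
  }
  val
}

#' Osmotic pumping fraction
#'
#' Zero-order release driven by the osmotic pressure gradient across the
#' film: `F3(t) = k_os * t`, with the lumped slope
#' `k_os = gamma * delta_pi` (fraction/h). Unbounded in `t`; within the
#' composite model the osmosis weight keeps the contribution physical over
#' the fitted window.
#'
#' @param k_os Zero-order slope, fraction/h; nonnegative.
#' @param t Time(s), hours; nonnegative. Vectorised.
#' @return Fraction(s) released by osmotic pumping.
#' @examples
#' osmotic_fraction(0.01, c(0, 10, 50))
#' @export
osmotic_fraction <- function(k_os, t) {
  if (!is.finite(k_os) || k_os < 0) stop("`k_os` must be >= 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  k_os * t
}

#' Convert an osmotic pressure gradient to the zero-order slope
#'
#' `k_os = gamma * delta_pi` with `gamma = A * h * Kp * S / M_inf` taken from
#' `geometry`, or the documented default `gamma = 1.111` 1/(h*atm) when
#' `geometry` is `NULL`.
#'
#' @param geometry A [geometry_constants()] object or `NULL`.
#' @param delta_pi Osmotic pressure gradient, atm; nonnegative.
#' @param gamma Conversion factor override; defaults to
#'   `osmotic_gamma(geometry)`.
#' @return Zero-order slope `k_os`, fraction/h.
#' @examples
#' osmotic_slope(NULL, 0.009)                 # default gamma
#' delta_pi_from_slope(NULL, 0.009 * 1.111)   # inverse
#' @export
osmotic_slope <- function(geometry = NULL, delta_pi,
                          gamma = osmotic_gamma(geometry)) {
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (any(!is.finite(delta_pi)) || any(delta_pi < 0)) {
    stop("`delta_pi` must be >= 0", call. = FALSE)
  }
  gamma * delta_pi
}

#' @rdname osmotic_slope
#' @param k_os Zero-order slope, fraction/h; nonnegative.
#' @return `delta_pi_from_slope`: osmotic pressure gradient, atm.
#' @export
delta_pi_from_slope <- function(geometry = NULL, k_os,
                                gamma = osmotic_gamma(geometry)) {
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (any(!is.finite(k_os)) || any(k_os < 0)) {
    stop("`k_os` must be >= 0", call. = FALSE)
  }
  k_os / gamma
}

#' Composite three-mechanism release curve
#'
#' Evaluates the weighted composite model
#' `Mt/Minf(t) = mu1*F1(t) + mu2*F2(t) + mu3*F3(t)`
#' on a time grid, with `F1` the burst term, `F2` the plane-sheet diffusion
#' series and `F3` the osmotic zero-order term. The composite is 0 at
#' `t = 0` and monotone nondecreasing. By default it is not clamped at 1:
#' the osmotic term grows without bound, and clamping is only meaningful
#' when simulating far beyond the fitted window (`clamp = TRUE`).
#'
#' @param params A [composite_params()] object.
#' @param times Time grid, hours; strictly increasing, first >= 0.
#' @param thickness Film thickness for the diffusion term, m
#'   (default 0.002 m, a 2 mm film).
#' @param series_tol Truncation tolerance for the diffusion series.
#' @param clamp If `TRUE`, cap the composite at 1.
#' @param label Label for the returned profile.
#' @return A [release_profile()] on `times`.
#' @examples
#' p <- composite_params(c(0.313, 0.559, 0.128), 2.5, 1.62e-8, 0.01)
#' composite_release(p, seq(0, 100, by = 10))
#' @export
composite_release <- function(params, times, thickness = 0.002,
                              series_tol = 1e-12, clamp = FALSE,
                              label = NULL) {
  stopifnot(inherits(params, "composite_params"))
  if (abs(sum(params$mu) - 1) > 1e-9) {
    stop("mechanism weights must sum to 1", call. = FALSE)
  }
  f <- composite_fractions(params, times, thickness, series_tol)
  if (clamp) f <- pmin(f, 1)
  release_profile(times, f, label = label)
}

# Bare-vector composite evaluation (no profile wrapper); used by the fitter.
composite_fractions <- function(params, times, thickness = 0.002,
                                series_tol = 1e-12) {
  mu <- params$mu
  f <- mu[[1L]] * burst_fraction(params$k_b, times) +
    mu[[2L]] * diffusion_fraction(params$D_e, thickness, times, series_tol) +
    mu[[3L]] * osmotic_fraction(params$k_os, times)
  unname(f)
}
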