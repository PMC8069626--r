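#' Construct a release profile
#'
#' A release profile is a cumulative-release curve: a strictly increasing time
#' grid (hours) paired with the fraction of the loaded drug released at each
#' time, `Mt/Minf`. Fractions are dimensionless and normally lie in `[0, 1]`;
#' values slightly above 1 are tolerated because experimental cumulative data
#' can overshoot through weighing noise.
#'
#' @param times Numeric vector of sampling times in hours; strictly
#'   increasing, first value >= 0.
#' @param fractions Numeric vector of cumulative fractions released
#'   (`Mt/Minf`), same length as `times`; all values finite.
#' @param label Optional free-text condition identifier (e.g.
#'   `"PU-20DE-Q7.5"`).
#' @return An object of class `release_profile`: a list with elements
#'   `times`, `fractions` and `label`.
#' @examples
#' p <- release_profile(0:5, c(0, 0.30, 0.45, 0.55, 0.62, 0.68), "example")
#' p
#' @export
release_profile <- function(times, fractions, label = NULL) {
  times <- as.numeric(times)
  fractions <- as.numeric(fractions)
  if (length(times) != length(fractions)) {
    stop("`times` and `fractions` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) {
    stop("a release profile needs at least one point", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("`times` must be finite", call. = FALSE)
  }
  if (anyNA(fractions) || any(!is.finite(fractions))) {
    stop("`fractions` must be finite", call. = FALSE)
  }
  if (times[1L] < 0) {
    stop("first time point must be >= 0", call. = FALSE)
  }
  bad <- which(diff(times) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("`times` must be strictly increasing (violated at row %d)",
                 bad[1L] + 1L), call. = FALSE)
  }
  structure(list(times = times, fractions = fractions,
                 label = if (is.null(label)) NA_character_ else as.character(label)),
            class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  lab <- if (is.na(x$label)) "<unlabelled>" else x$label
  cat(sprintf("Release profile '%s': %d points, t = %g..%g h, fraction %.4g..%.4g\n",
              lab, length(x$times), min(x$times), max(x$times),
              min(x$fractions), max(x$fractions)))
  invisible(x)
}

#' @export
as.data.frame.release_profile <- function(x, ...) {
  data.frame(time_h = x$times, fraction_released = x$fractions)
}

#' @export
length.release_profile <- function(x) length(x$times)

#' Construct a composite-model parameter set
#'
#' Parameters of the three-mechanism composite release model: simplex
#' weights for the burst, diffusion and osmosis contributions plus the
#' kinetic constant of each mechanism.
#'
#' @param mu Numeric 3-vector of mechanism weights, ordered
#'   (burst, diffusion, osmosis). Each weight must lie in `[0, 1]` and the
#'   weights must sum to 1 (within `1e-9`).
#' @param k_b Burst first-order rate constant, 1/h; strictly positive.
#' @param D_e Effective diffusion coefficient in the polymer, m^2/h;
#'   strictly positive.
#' @param k_os Osmotic zero-order slope, fraction/h; nonnegative. Related to
#'   the osmotic pressure gradient by `k_os = gamma * delta_pi` (see
#'   [osmotic_slope()]).
#' @return An object of class `composite_params`.
#' @examples
#' composite_params(c(0.313, 0.559, 0.128), k_b = 2.5, D_e = 1.62e-8,
#'                  k_os = 0.009 * 1.111)
#' @export
composite_params <- function(mu, k_b, D_e, k_os) {
  mu <- as.numeric(mu)
  if (length(mu) != 3L || anyNA(mu)) {
    stop("`mu` must be a numeric 3-vector (burst, diffusion, osmosis)",
         call. = FALSE)
  }
  if (any(mu < -1e-12) || any(mu > 1 + 1e-12)) {
    stop("each mechanism weight must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(mu) - 1) > 1e-9) {
    stop(sprintf("mechanism weights must sum to 1 (got %.12g)", sum(mu)),
         call. = FALSE)
  }
  if (!is.finite(k_b) || k_b <= 0) stop("`k_b` must be > 0", call. = FALSE)
  if (!is.finite(D_e) || D_e <= 0) stop("`D_e` must be > 0", call. = FALSE)
  if (!is.finite(k_os) || k_os < 0) stop("`k_os` must be >= 0", call. = FALSE)
  mu <- pmin(pmax(mu, 0), 1)
  structure(list(mu = c(burst = mu[1L], diffusion = mu[2L], osmosis = mu[3L]),
                 k_b = k_b, D_e = D_e, k_os = k_os),
            class = "composite_params")
}

#' @export
print.composite_params <- function(x, ...) {
  cat("Composite release parameters\n")
  cat(sprintf("  weights: burst %.4f, diffusion %.4f, osmosis %.4f\n",
              x$mu[["burst"]], x$mu[["diffusion"]], x$mu[["osmosis"]]))
  cat(sprintf("  k_b  = %.6g 1/h\n", x$k_b))
  cat(sprintf("  D_e  = %.6g m^2/h\n", x$D_e))
  cat(sprintf("  k_os = %.6g 1/h\n", x$k_os))
  invisible(x)
}

#' Construct film geometry and osmotic permeability constants
#'
#' Physical constants of the drug-loaded film used to convert the lumped
#' osmotic slope `k_os` (fraction/h) into an osmotic pressure gradient
#' (atm) and back. The conversion factor is
#' `gamma = A * h * Kp * S / M_inf`, with units 1/(h*atm).
#'
#' @param area Film surface area `A`, m^2.
#' @param thickness Film thickness `h`, m.
#' @param solubility Drug saturation solubility `S` in the release medium,
#'   kg/m^3.
#' @param loaded_mass Drug mass loaded `M_inf`, kg.
#' @param permeability Lumped membrane permeability `Kp` (the product of
#'   hydraulic permeability and reflection coefficient), in units such that
#'   `gamma` comes out in 1/(h*atm).
#' @return An object of class `geometry_constants`.
#' @seealso [osmotic_gamma()], [osmotic_slope()]
#' @export
geometry_constants <- function(area, thickness, solubility, loaded_mass,
                               permeability) {
  vals <- c(area = area, thickness = thickness, solubility = solubility,
            loaded_mass = loaded_mass, permeability = permeability)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry constants must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "geometry_constants")
}

#' @export
print.geometry_constants <- function(x, ...) {
  cat("Film geometry constants\n")
  cat(sprintf("  area        = %g m^2\n", x$area))
  cat(sprintf("  thickness   = %g m\n", x$thickness))
  cat(sprintf("  solubility  = %g kg/m^3\n", x$solubility))
  cat(sprintf("  loaded mass = %g kg\n", x$loaded_mass))
  cat(sprintf("  permeability= %g\n", x$permeability))
  cat(sprintf("  gamma       = %g 1/(h*atm)\n", osmotic_gamma(x)))
  invisible(x)
}

# Default osmotic conversion factor, 1/(h*atm). Chosen so that a gradient of
# 0.009 atm maps to a zero-order slope completing release in about 100 h.
.default_gamma <- 1.111

#' Osmotic slope/pressure conversion factor
#'
#' Returns `gamma = A * h * Kp * S / M_inf`, the factor converting an osmotic
#' pressure gradient (atm) into the zero-order release slope `k_os`
#' (fraction/h). When no geometry is supplied, the package default
#' `gamma = 1.111` 1/(h*atm) is returned.
#'
#' @param geometry A [geometry_constants()] object, or `NULL` for the
#'   documented default.
#' @return Conversion factor in 1/(h*atm).
#' @export
osmotic_gamma <- function(geometry = NULL) {
  if (is.null(geometry)) return(.default_gamma)
  stopifnot(inherits(geometry, "geometry_constants"))
  geometry$area * geometry$thickness * geometry$permeability *
    geometry$solubility / geometry$loaded_mass
}
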