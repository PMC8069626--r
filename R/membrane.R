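#' Porous-membrane specification
#'
#' Geometry and fluid constants of the porous film treated as a bundle of
#' cylindrical pores in laminar, incompressible flow.
#'
#' @param pore_radius Pore radius `a`, m.
#' @param pore_density Number of pores in the membrane `n` (dimensionless
#'   count).
#' @param thickness Membrane thickness `delta`, m.
#' @param viscosity Fluid dynamic viscosity `eta`, Pa*s.
#' @param solute_pore_ratio Ratio of solute particle radius to pore radius,
#'   dimensionless in `[0, 1]`; typically measured from SEM images.
#' @return An object of class `membrane_spec`.
#' @export
membrane_spec <- function(pore_radius, pore_density, thickness, viscosity,
                          solute_pore_ratio = NA_real_) {
  vals <- c(pore_radius, pore_density, thickness, viscosity)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("pore radius, pore density, thickness and viscosity must all be > 0",
         call. = FALSE)
  }
  if (!is.na(solute_pore_ratio) &&
      (solute_pore_ratio < 0 || solute_pore_ratio > 1)) {
    stop("`solute_pore_ratio` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(pore_radius = pore_radius, pore_density = pore_density,
                 thickness = thickness, viscosity = viscosity,
                 solute_pore_ratio = solute_pore_ratio),
            class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("Porous membrane\n")
  cat(sprintf("  pore radius  = %g m\n", x$pore_radius))
  cat(sprintf("  pore count   = %g\n", x$pore_density))
  cat(sprintf("  thickness    = %g m\n", x$thickness))
  cat(sprintf("  viscosity    = %g Pa*s\n", x$viscosity))
  if (!is.na(x$solute_pore_ratio)) {
    cat(sprintf("  solute/pore radius ratio = %g\n", x$solute_pore_ratio))
  }
  invisible(x)
}

#' Poiseuille pressure drop across a porous membrane
#'
#' `dP = 8 * eta * delta * Jv / (n * pi * a^4)` for laminar incompressible
#' flow through `n` cylindrical pores of radius `a`.
#'
#' @param spec A [membrane_spec()].
#' @param Jv Volumetric flux, m^3/(m^2*s); nonnegative. Vectorised.
#' @return Pressure drop in Pa, linear in `Jv`.
#' @export
pressure_drop <- function(spec, Jv) {
  stopifnot(inherits(spec, "membrane_spec"))
  if (any(!is.finite(Jv)) || any(Jv < 0)) stop("`Jv` must be >= 0", call. = FALSE)
  8 * spec$viscosity * spec$thickness * Jv /
    (spec$pore_density * pi * spec$pore_radius^4)
}

#' Hydraulic permeability of a porous membrane
#'
#' `Lp = n * pi * a^4 / (8 * eta * delta)`, the proportionality constant in
#' `Jv = dP * Lp`. By construction `pressure_drop(spec, Jv) * Lp == Jv`.
#'
#' @param spec A [membrane_spec()].
#' @return Hydraulic permeability `Lp`.
#' @export
hydraulic_permeability <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  spec$pore_density * pi * spec$pore_radius^4 /
    (8 * spec$viscosity * spec$thickness)
}

#' Reflection coefficient from the solute/pore radius ratio
#'
#' `sigma = (1 - (1 - phi)^2)^2`, the fraction of the theoretical osmotic
#' pressure a pore of finite size actually transmits. `sigma = 0` for a
#' freely permeable pore (`phi = 0`) and `sigma = 1` for a perfectly
#' semipermeable membrane (`phi = 1`); monotone increasing in between.
#'
#' @param phi Solute-to-pore radius ratio, dimensionless in `[0, 1]`.
#'   Vectorised.
#' @return Reflection coefficient(s) in `[0, 1]`.
#' @examples
#' reflection_coefficient(c(0, 0.5, 1))
#' @export
reflection_coefficient <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1)) {
    stop("`phi` must lie in [0, 1]", call. = FALSE)
  }
  (1 - (1 - phi)^2)^2
}

#' Free-volume fraction coefficient
#'
#' WLF-type estimate of the polymer free-volume fraction,
#' `f_g = B * delta_alpha * A / 2.303`.
#'
#' @param B Proportionality constant, dimensionless; > 0.
#' @param delta_alpha Thermal expansion coefficient increment at the glass
#'   transition, 1/K; > 0.
#' @param A_wlf WLF coefficient, K; > 0.
#' @return Free-volume fraction `f_g` (dimensionless).
#' @export
free_volume_fraction <- function(B, delta_alpha, A_wlf) {
  vals <- c(B, delta_alpha, A_wlf)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("`B`, `delta_alpha` and `A_wlf` must all be > 0", call. = FALSE)
  }
  B * delta_alpha * A_wlf / 2.303
}

# Pa per standard atmosphere.
.pa_per_atm <- 101325

#' Check osmotic dominance over hydrostatic pressure
#'
#' The osmotic zero-order model assumes the osmotic gradient dwarfs the
#' hydrostatic pressure drop (`delta_pi >> dP`). This converts both to Pa
#' and reports whether `delta_pi` exceeds `dP` by at least `factor`.
#'
#' @param delta_pi Osmotic pressure gradient, atm; nonnegative.
#' @param delta_P Hydrostatic pressure drop, Pa; nonnegative.
#' @param factor Dominance factor required (default 10).
#' @return A list with `dominant` (logical) and `ratio`
#'   (`delta_pi` in Pa divided by `delta_P`; `Inf` when `delta_P = 0` and
#'   `delta_pi > 0`, `NaN` when both are 0).
#' @export
osmosis_dominance_check <- function(delta_pi, delta_P, factor = 10) {
  if (!is.finite(delta_pi) || delta_pi < 0) {
    stop("`delta_pi` must be >= 0", call. = FALSE)
  }
  if (!is.finite(delta_P) || delta_P < 0) {
    stop("`delta_P` must be >= 0", call. = FALSE)
  }
  pi_pa <- delta_pi * .pa_per_atm
  ratio <- if (delta_P == 0) {
    if (pi_pa > 0) Inf else NaN
  } else {
    pi_pa / delta_P
  }
  list(dominant = isTRUE(ratio >= factor), ratio = ratio)
}
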