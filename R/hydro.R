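#' Cylinder geometry of a surface-anchored molecule
#'
#' @param a Cylinder radius in nm.
#' @param h_c Cylinder height in nm.
#' @return An object of class `molecule_geometry`.
#' @export
molecule_geometry <- function(a, h_c) {
  .check_num(a, "a", min = 0, strict = TRUE)
  .check_num(h_c, "h_c", min = 0)
  structure(list(a = a, h_c = h_c), class = "molecule_geometry")
}

#' Hydrodynamic area at zero coverage
#'
#' Empirical expression for the effective hydrodynamic area of an isolated
#' surface-anchored cylinder in shear flow,
#' \deqn{A_{hydro}(0) = \left(0.65 (h_c/a)^2 + 5.0\,(h_c/a) + 1\right)\pi a^2,}
#' which converts the wall shear stress to the drag force on one molecule.
#' A flat disk (`h_c = 0`) reduces to its geometric footprint.
#'
#' @param geom A [molecule_geometry()], or a radius in nm if `h_c` is given.
#' @param h_c Height in nm (when `geom` is a bare radius).
#' @return Area in nm^2.
#' @examples
#' a_hydro_zero(molecule_geometry(2.8, 5)) # ~296 nm^2, a streptavidin-like disk
#' @export
a_hydro_zero <- function(geom, h_c = NULL) {
  if (!inherits(geom, "molecule_geometry")) geom <- molecule_geometry(geom, h_c)
  x <- geom$h_c / geom$a
  (0.65 * x^2 + 5.0 * x + 1) * pi * geom$a^2
}

#' Effective height from a measured zero-coverage hydrodynamic area
#'
#' Inverts the empirical hydrodynamic-area expression for the height: with
#' \eqn{x = h_c/a}, solves \eqn{0.65 x^2 + 5 x + 1 = A/(\pi a^2)} for its
#' unique non-negative root. Round-trips with [a_hydro_zero()] exactly.
#'
#' @param a_hydro0 Measured zero-coverage hydrodynamic area in nm^2.
#' @param a Assumed molecular radius in nm.
#' @return Effective height in nm.
#' @examples
#' effective_height(300, 2.8) # ~5.1 nm
#' @export
effective_height <- function(a_hydro0, a) {
  .check_num(a, "a", min = 0, strict = TRUE)
  .check_num(a_hydro0, "a_hydro0")
  disk <- pi * a^2
  if (a_hydro0 < disk * (1 - 1e-12))
    .stopf("a_hydro0 = %.4g nm^2 is below the bare disk area pi*a^2 = %.4g nm^2; no non-negative height exists",
           a_hydro0, disk)
  q <- max(a_hydro0 / disk, 1)
  x <- (-5 + sqrt(25 - 4 * 0.65 * (1 - q))) / (2 * 0.65)
  a * x
}

#' Hydrodynamic force on a single molecule
#'
#' Linear drag law: force = effective hydrodynamic area times wall shear
#' stress.
#'
#' @param a_hydro Hydrodynamic area in nm^2.
#' @param sigma Shear stress in J/m^3 * m = N/m^2 (Pa).
#' @return Force in newton.
#' @export
force_from_shear <- function(a_hydro, sigma) {
  if (any(a_hydro < 0)) .stopf("'a_hydro' must be >= 0")
  a_hydro * 1e-18 * sigma
}

#' Radial shear-stress profile
#'
#' Magnitude of the inward-directed wall shear stress on a strictly
#' increasing radial grid. The sign convention stores magnitudes, so the
#' derived trap-energy profile is non-negative.
#'
#' @param r Radial grid in um, strictly increasing.
#' @param sigma Shear stress magnitude at each radius, in Pa.
#' @return An object of class `shear_profile` (a data frame).
#' @export
shear_profile <- function(r, sigma) {
  if (length(r) < 2L || any(diff(r) <= 0))
    .stopf("'r' must be a strictly increasing grid of length >= 2")
  if (length(sigma) != length(r)) .stopf("'sigma' and 'r' lengths differ")
  if (any(!is.finite(sigma))) .stopf("'sigma' must be finite")
  structure(data.frame(r = r, sigma = sigma),
            class = c("shear_profile", "data.frame"))
}

#' Trap-energy profile from a shear-stress profile
#'
#' The trap-energy density is the outward radial integral of the shear
#' stress, \eqn{\epsilon_{hydro}(r) = \int_r^{\infty} \sigma\, dr'},
#' evaluated by the trapezoid rule on the supplied grid from the outer edge
#' inward (so \eqn{\epsilon(r_{max}) = 0}). A warning is issued when the
#' profile has not decayed at the outer edge (|sigma| there above
#' `decay_tol` times its peak), since the integral is then truncated.
#'
#' @param profile A [shear_profile()].
#' @param decay_tol Outer-decay precondition, relative to the peak.
#' @return An object of class `trap_energy_profile` (a data frame with
#'   columns `r` in um and `epsilon` in J/m^2).
#' @export
epsilon_from_shear <- function(profile, decay_tol = 1e-3) {
  stopifnot(inherits(profile, "shear_profile"))
  r <- profile$r; s <- profile$sigma
  peak <- max(abs(s))
  if (peak > 0 && abs(s[length(s)]) > decay_tol * peak)
    .warnf("shear profile has not decayed at the outer edge (|sigma| = %.3g of peak); trap energy is truncated",
           abs(s[length(s)]) / peak)
  n <- length(r)
  # cumulative trapezoid from the outside in; r in um -> 1e-6 m
  seg <- diff(r) * 1e-6 * (s[-1] + s[-n]) / 2
  eps <- rev(c(0, cumsum(rev(seg))))
  trap_energy_profile(r, eps)
}

#' Construct a trap-energy profile
#'
#' @param r Radial grid in um, strictly increasing.
#' @param epsilon Trap-energy density in J/m^2, non-negative and
#'   non-increasing in r.
#' @return An object of class `trap_energy_profile`.
#' @export
trap_energy_profile <- function(r, epsilon) {
  if (length(r) < 2L || any(diff(r) <= 0))
    .stopf("'r' must be a strictly increasing grid of length >= 2")
  if (length(epsilon) != length(r)) .stopf("'epsilon' and 'r' lengths differ")
  if (any(epsilon < -1e-15)) .stopf("'epsilon' must be >= 0 (stored as magnitude)")
  if (any(diff(epsilon) > 1e-12 * max(epsilon, 1e-300)))
    .warnf("trap-energy profile is not monotone non-increasing in r")
  structure(data.frame(r = r, epsilon = pmax(epsilon, 0)),
            class = c("trap_energy_profile", "data.frame"))
}

#' Parametric micropipette flow model
#'
#' A documented stand-in for finite-element simulations of the flow under a
#' micropipette: a monotone-decaying radial shear-stress kernel
#' \deqn{\sigma(r) = S\,(r/r_0)\, e^{-r/r_0}, \qquad
#'   r_0 = \mathrm{tip} + \mathrm{gap},}
#' whose amplitude is linear in the applied pressure. The closed-form trap
#' energy is \eqn{\epsilon(r) = S r_0 (1 + r/r_0) e^{-r/r_0}} (in SI units),
#' so \eqn{\epsilon(0) = S r_0}. The dimensionless shape coefficient is
#' chosen so that the default geometry at the intermediate study pressure
#' (-9.7 kPa) yields a peak trap energy of order 1e-4 J/m^2. Users with real
#' finite-element output should supply a tabulated [shear_profile()] instead.
#'
#' @param tip_radius Pipette inner tip radius in um.
#' @param gap Pipette-to-surface distance in um.
#' @param delta_p Applied pressure in kPa (sign ignored; magnitude drives the
#'   trap).
#' @param shape Dimensionless amplitude coefficient:
#'   `epsilon(0) = shape * |delta_p[Pa]| * r0[m]`.
#' @return An object of class `parametric_flow_model`.
#' @export
parametric_flow_model <- function(tip_radius = 1.5, gap = 1.5, delta_p = -9.7,
                                  shape = 3.44e-3) {
  .check_num(tip_radius, "tip_radius", min = 0, strict = TRUE)
  .check_num(gap, "gap", min = 0, strict = TRUE)
  .check_num(delta_p, "delta_p")
  .check_num(shape, "shape", min = 0, strict = TRUE)
  structure(list(tip_radius = tip_radius, gap = gap, delta_p = delta_p,
                 shape = shape, r0 = tip_radius + gap),
            class = "parametric_flow_model")
}

#' Shear stress of the parametric flow model on a radial grid
#'
#' @param model A [parametric_flow_model()].
#' @param r Radial grid in um.
#' @return A [shear_profile()].
#' @export
flow_model_shear <- function(model, r) {
  stopifnot(inherits(model, "parametric_flow_model"))
  r0 <- model$r0
  S <- model$shape * abs(model$delta_p) * 1e3 # Pa; epsilon(0) = S * r0[m]
  shear_profile(r, S * (r / r0) * exp(-r / r0))
}

#' Trap energy of the parametric flow model (closed form)
#'
#' @param model A [parametric_flow_model()].
#' @param r Radial grid in um.
#' @return A [trap_energy_profile()].
#' @export
flow_model_epsilon <- function(model, r) {
  stopifnot(inherits(model, "parametric_flow_model"))
  r0 <- model$r0
  eps0 <- model$shape * abs(model$delta_p) * 1e3 * r0 * 1e-6
  trap_energy_profile(r, eps0 * (1 + r / r0) * exp(-r / r0))
}

#' Coverage-dependent flow shielding
#'
#' Molecules shield each other from the flow as the surface gets crowded, so
#' the effective hydrodynamic area decreases with coverage. The default
#' attenuation family is \eqn{g(\Phi) = (1-\Phi)^{\nu}} with `nu = 1`;
#' `nu = 0` disables shielding. Any `g` must satisfy g(0) = 1, be monotone
#' non-increasing, and stay in (0, 1].
#'
#' @param nu Exponent of the default power family, `>= 0`.
#' @param g Optional custom attenuation function of coverage.
#' @return An object of class `shielding_model`.
#' @export
shielding_model <- function(nu = 1, g = NULL) {
  if (is.null(g)) {
    .check_num(nu, "nu", min = 0)
    g <- function(phi) (1 - pmin(phi, 0.999))^nu
  } else {
    if (abs(g(0) - 1) > 1e-9) .stopf("shielding function must satisfy g(0) = 1")
  }
  structure(list(nu = nu, g = g), class = "shielding_model")
}

#' Hydrodynamic area at finite coverage
#'
#' @param a_hydro0 Zero-coverage hydrodynamic area in nm^2.
#' @param phi Coverage fraction(s), `0 <= phi < 1`.
#' @param shielding A [shielding_model()].
#' @return Attenuated hydrodynamic area(s) in nm^2.
#' @export
a_hydro_of_coverage <- function(a_hydro0, phi, shielding = shielding_model()) {
  if (any(phi < 0) || any(phi >= 1)) .stopf("coverage must satisfy 0 <= phi < 1")
  stopifnot(inherits(shielding, "shielding_model"))
  a_hydro0 * shielding$g(phi)
}
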