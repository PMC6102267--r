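#' Steady-state trap profiles for two co-trapped species
#'
#' Forward model for trapping two differently sized molecules at once. At
#' each trap energy the coupled force balances
#' \deqn{d\mu_i = A_i(c_1, c_2)\, d\epsilon, \qquad
#'   \mu_i = \ln(c_i/c_{0,i}) + \mu_i^{ex}(c_1, c_2)}
#' are integrated from the common baseline. The excess term combines each
#' species' own hard-disk virial series with a second-virial cross term
#' from the mutual exclusion area,
#' \eqn{\mu_i^{ex} = \mu^{ex}_{HD}(\Phi_i) + \pi (a_i + a_j)^2 c_j}, so the
#' model reduces exactly to the single-species solution when the other
#' baseline is zero. Optionally the smaller species is shielded from the
#' flow by the larger one (its hydrodynamic area attenuated by the larger
#' species' local coverage), the mechanism behind the ring-shaped
#' distribution of the smaller species around the trap centre. The mixture
#' treatment is second-virial only and intended for qualitative orderings.
#'
#' @param models List of two [hard_disk_model()] objects.
#' @param a_hydro0 Numeric vector: zero-coverage hydrodynamic areas in nm^2.
#' @param eps A [trap_energy_profile()] (or [parametric_flow_model()]).
#' @param c0 Numeric vector: baseline densities in molecules/um^2.
#' @param shield_small Shield the species with the smaller hydrodynamic
#'   area by the other species' coverage.
#' @param shielding A [shielding_model()] used for that attenuation.
#' @param r Radial grid in um (default: the trap-energy grid).
#' @return A data frame of class `two_species_profiles`: `r`, `eps`,
#'   `conc1`, `conc2`, `phi1`, `phi2`.
#' @export
two_species_steady_state <- function(models, a_hydro0, eps, c0,
                                     shield_small = TRUE,
                                     shielding = shielding_model(nu = 2),
                                     r = NULL) {
  stopifnot(length(models) == 2L, inherits(models[[1]], "hard_disk_model"),
            inherits(models[[2]], "hard_disk_model"),
            length(a_hydro0) == 2L, length(c0) == 2L)
  if (any(c0 < 0)) .stopf("baseline densities must be >= 0")
  if (inherits(eps, "parametric_flow_model")) {
    if (is.null(r)) r <- seq(0.05, 12 * eps$r0, length.out = 200)
    eps <- flow_model_epsilon(eps, r)
  }
  stopifnot(inherits(eps, "trap_energy_profile"))
  if (is.null(r)) r <- eps$r
  a1 <- models[[1]]$a_hd; a2 <- models[[2]]$a_hd
  A2_1 <- pi * a1^2 * 1e-6; A2_2 <- pi * a2^2 * 1e-6 # nm^2 -> um^2 footprint
  Xc <- pi * (a1 + a2)^2 * 1e-6 # cross exclusion per concentration
  phi_tot0 <- c0[1] * A2_1 + c0[2] * A2_2
  if (phi_tot0 >= 1) .stopf("total far-field coverage %.2f >= 1", phi_tot0)
  small <- which.min(a_hydro0)
  g <- shielding$g
  active <- c0 > 0 # an absent species stays absent
  rhs <- function(e, y, parms) {
    c1 <- max(y[1], 0); c2 <- max(y[2], 0)
    phi1 <- min(c1 * A2_1, 0.999); phi2 <- min(c2 * A2_2, 0.999)
    A <- a_hydro0
    if (shield_small) {
      phi_other <- if (small == 1L) phi2 else phi1
      A[small] <- A[small] * g(phi_other)
    }
    # Jacobian of (mu1, mu2) wrt (c1, c2)
    J11 <- 1 / max(c1, 1e-9) + mu_excess_hard_disk_deriv(phi1, models[[1]]) * A2_1
    J22 <- 1 / max(c2, 1e-9) + mu_excess_hard_disk_deriv(phi2, models[[2]]) * A2_2
    J12 <- Xc; J21 <- Xc
    det <- J11 * J22 - J12 * J21
    if (!is.finite(det) || abs(det) < 1e-300)
      .stopf("two-species solve is singular at epsilon = %.3g", e)
    Ak <- A * NM2_EPS_TO_KBT
    dc <- c((J22 * Ak[1] - J12 * Ak[2]) / det,
            (J11 * Ak[2] - J21 * Ak[1]) / det)
    list(ifelse(active, dc, 0))
  }
  eps_max <- max(eps$epsilon)
  e_grid <- seq(0, eps_max, length.out = 400)
  sol <- tryCatch(
    deSolve::lsoda(y = c(c1 = c0[1], c2 = c0[2]), times = e_grid, func = rhs,
                   parms = NULL, rtol = 1e-8, atol = 1e-8),
    error = function(e) .stopf("two-species steady-state solve failed: %s",
                               conditionMessage(e)))
  if (nrow(sol) < length(e_grid))
    .stopf("two-species solve did not converge beyond epsilon = %.3g J/m^2",
           sol[nrow(sol), 1])
  e_of_r <- approx(eps$r, eps$epsilon, xout = r, rule = 2)$y
  c1r <- approx(sol[, 1], sol[, 2], xout = e_of_r, rule = 2)$y
  c2r <- approx(sol[, 1], sol[, 3], xout = e_of_r, rule = 2)$y
  out <- data.frame(r = r, eps = e_of_r, conc1 = c1r, conc2 = c2r,
                    phi1 = c1r * A2_1, phi2 = c2r * A2_2)
  class(out) <- c("two_species_profiles", "data.frame")
  out
}
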