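#' Ground truth for a synthetic trapping experiment
#'
#' Everything needed to generate a steady-state trap dataset with known
#' answers: the chemical-potential model of the molecule, its zero-coverage
#' hydrodynamic area and shielding, the baseline density, the trap-energy
#' source, the camera model, and the seed. Regeneration from the same
#' object and seed is bit-identical.
#'
#' @param mu_model A [hard_disk_model()], or a list
#'   `list(type = "linear", slope = s)` giving `mu_ex = s * conc` (kBT per
#'   molecules/um^2), or `list(type = "curve", conc, mu_ex)` for an
#'   interpolated table (e.g. from an MC sweep).
#' @param a_hydro0 Zero-coverage hydrodynamic area in nm^2.
#' @param c0 Baseline density in molecules/um^2.
#' @param eps Trap-energy source: a [trap_energy_profile()] or a
#'   [parametric_flow_model()].
#' @param shielding A [shielding_model()] (shielding disabled by default:
#'   the low-coverage analysis regime).
#' @param noise Camera model: list with `counts_per_molecule` (photon
#'   counts contributed per molecule per pixel), `background` (counts),
#'   `read_sd` (Gaussian read noise, counts), and optionally `shot = FALSE`
#'   to disable Poisson counting noise (a noiseless render for
#'   consistency checks).
#' @param image_size Image side in pixels.
#' @param pixel_size Pixel size in um/px.
#' @param seed Integer seed recorded with the truth.
#' @param phi_cap Physicality cap on generated coverage.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(mu_model, a_hydro0, c0, eps,
                         shielding = shielding_model(nu = 0),
                         noise = list(counts_per_molecule = 80,
                                      background = 400, read_sd = 3),
                         image_size = 512L, pixel_size = 0.22, seed = 1L,
                         phi_cap = 0.5) {
  .check_num(a_hydro0, "a_hydro0", min = 0, strict = TRUE)
  .check_num(c0, "c0", min = 0, strict = TRUE)
  stopifnot(inherits(eps, "trap_energy_profile") ||
              inherits(eps, "parametric_flow_model"))
  structure(list(mu_model = mu_model, a_hydro0 = a_hydro0, c0 = c0,
                 eps = eps, shielding = shielding, noise = noise,
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size, seed = as.integer(seed),
                 phi_cap = phi_cap),
            class = "ground_truth")
}

# mu_ex and its concentration derivative for the supported mu-model forms.
.mu_model_funs <- function(mu_model) {
  if (inherits(mu_model, "hard_disk_model")) {
    a2 <- pi * mu_model$a_hd^2 * 1e-6
    list(mu_ex = function(c) mu_excess_hard_disk(pmin(c * a2, 0.999), mu_model),
         dmu_ex = function(c) mu_excess_hard_disk_deriv(pmin(c * a2, 0.999), mu_model) * a2,
         phi = function(c) c * a2)
  } else if (identical(mu_model$type, "linear")) {
    s <- mu_model$slope
    list(mu_ex = function(c) s * c, dmu_ex = function(c) rep(s, length(c)),
         phi = function(c) rep(0, length(c)))
  } else if (identical(mu_model$type, "curve")) {
    o <- order(mu_model$conc)
    cc <- mu_model$conc[o]; mm <- mu_model$mu_ex[o]
    list(mu_ex = function(c) approx(cc, mm, xout = c, rule = 2)$y,
         dmu_ex = function(c) {
           h <- diff(range(cc)) * 1e-6
           (approx(cc, mm, xout = c + h, rule = 2)$y -
              approx(cc, mm, xout = c - h, rule = 2)$y) / (2 * h)
         },
         phi = function(c) rep(0, length(c)))
  } else .stopf("unsupported mu model")
}

.eps_on_grid <- function(eps, r) {
  if (inherits(eps, "parametric_flow_model")) flow_model_epsilon(eps, r)
  else trap_energy_profile(r, approx(eps$r, eps$epsilon, xout = r, rule = 2)$y)
}

#' Steady-state radial concentration profile from ground truth
#'
#' Solves the steady-state force balance: the chemical potential gradient
#' balances the hydrodynamic force, so along the trap
#' \eqn{d\mu = A_{hydro}(c)\, d\epsilon} with
#' \eqn{\mu = \ln(c/c_0) + \mu^{ex}(c)} (kBT units). The concentration as a
#' function of trap energy is obtained by integrating
#' \eqn{dc/d\epsilon = A_{hydro}(c) / \mu'(c)} from the baseline
#' (`deSolve::lsoda`), then evaluated at the trap energy of each radius.
#' With constant hydrodynamic area this coincides with per-radius root
#' finding on \eqn{\mu(c) = A\,\epsilon}; with shielding the integral form
#' is the definition. Coverages crossing the physicality cap are reported
#' with the saturating radius.
#'
#' @param truth A [ground_truth()].
#' @param r Radial grid in um (default: pixel-resolution grid across the
#'   image half-diagonal).
#' @return A [radial_profile()] of concentration (molecules/um^2), with
#'   attribute `c0`.
#' @export
forward_steady_state <- function(truth, r = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(r)) {
    r_max <- truth$image_size * truth$pixel_size * 0.75
    r <- seq(truth$pixel_size / 2, r_max, by = truth$pixel_size)
  }
  epsp <- .eps_on_grid(truth$eps, r)
  funs <- .mu_model_funs(truth$mu_model)
  g <- truth$shielding$g
  amodel <- if (inherits(truth$mu_model, "hard_disk_model"))
    function(c) truth$a_hydro0 * g(pmin(funs$phi(c), 0.999))
  else function(c) rep(truth$a_hydro0, length(c)) * g(pmin(funs$phi(c), 0.999))
  eps_max <- max(epsp$epsilon)
  if (eps_max <= 0) {
    out <- radial_profile(r, rep(truth$c0, length(r)))
    attr(out, "c0") <- truth$c0
    return(out)
  }
  dcde <- function(e, y, parms) {
    c <- max(y[1], 1e-12)
    list(amodel(c) * NM2_EPS_TO_KBT / (1 / c + funs$dmu_ex(c)))
  }
  e_grid <- seq(0, eps_max, length.out = 400)
  sol <- deSolve::lsoda(y = c(conc = truth$c0), times = e_grid, func = dcde,
                        parms = NULL, rtol = 1e-9, atol = 1e-9)
  c_of_e <- approx(sol[, 1], sol[, 2], xout = epsp$epsilon, rule = 2)$y
  phi <- funs$phi(c_of_e)
  if (inherits(truth$mu_model, "hard_disk_model") && any(phi > truth$phi_cap)) {
    r_sat <- max(r[phi > truth$phi_cap])
    .warnf("coverage exceeds the cap %.2g inside r = %.3g um", truth$phi_cap, r_sat)
  }
  out <- radial_profile(r, c_of_e)
  attr(out, "c0") <- truth$c0
  out
}

#' Render a noisy trap image from a radial concentration profile
#'
#' Pixel intensity (in camera counts) is background plus
#' `counts_per_molecule` times the number of molecules per pixel, with
#' Poisson counting noise on the signal and Gaussian read noise on top.
#' Seeded and reproducible.
#'
#' @param profile A [radial_profile()] of concentration covering the image
#'   radial extent.
#' @param truth A [ground_truth()] supplying geometry and camera model (or
#'   a compatible list).
#' @param centre Trap centre in um; defaults to the image centre.
#' @param seed Overrides `truth$seed`.
#' @return A [trap_image()] in camera counts.
#' @export
render_image <- function(profile, truth, centre = NULL, seed = truth$seed) {
  stopifnot(inherits(profile, "radial_profile"))
  n <- truth$image_size; px <- truth$pixel_size
  if (is.null(centre)) centre <- c(n, n) * px / 2
  xs <- (seq_len(n) - 0.5) * px
  r_pix <- sqrt(outer((xs - centre[1])^2, (xs - centre[2])^2, `+`))
  if (max(r_pix) > max(profile$r) * 1.5)
    .stopf("profile (r <= %.3g um) does not cover the image extent (%.3g um)",
           max(profile$r), max(r_pix))
  conc <- approx(profile$r, profile$value, xout = pmin(r_pix, max(profile$r)),
                 rule = 2)$y
  nz <- truth$noise
  mol_per_px <- conc * px^2
  signal_mean <- matrix(nz$counts_per_molecule * mol_per_px, n, n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  signal <- if (isTRUE(nz$shot %||% TRUE))
    matrix(rpois(n * n, lambda = signal_mean), n, n)
  else signal_mean
  I <- nz$background + signal +
    if (nz$read_sd > 0) matrix(rnorm(n * n, sd = nz$read_sd), n, n) else 0
  trap_image(pmax(I, 0), px)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Built-in synthetic trapping scenarios
#'
#' Presets reproducing the geometry of the four study molecules: globular
#' streptavidin ("SA") and the rod-like immune-cell proteins "CD2", "CD4"
#' and "CD45". Each returns a fully populated [ground_truth()] whose
#' hydrodynamic area comes from the cylinder model of the molecule's
#' structural dimensions and whose trap energy comes from the parametric
#' flow model scaled so the peak trap energy is about 1e-4 J/m^2 at the
#' default intermediate pressure. The experimental fit values (effective
#' hard-disk radii) are carried as metadata only: they derive from
#' unreleased experimental curves and are not recomputed here.
#'
#' CD45 is modelled as a freely rotating rod; its preset uses a linear
#' excess chemical potential (the near-linear coverage dependence of a
#' rotating rod) matched to its low-coverage effective area, or accepts a
#' simulated curve via `mu_model`.
#'
#' @param name One of `"SA"`, `"CD2"`, `"CD4"`, `"CD45"` (alias
#'   `"CD45-rotating-rod"`).
#' @param delta_p Applied pressure in kPa.
#' @param seed Seed stored in the truth.
#' @param mu_model Optional override of the preset chemical-potential model.
#' @return A [ground_truth()] with attribute `scenario` (geometry and
#'   reference values).
#' @export
make_scenario <- function(name, delta_p = -9.7, seed = 1L, mu_model = NULL) {
  presets <- list(
    SA = list(a = 2.8, h_c = 5, a_hd = 3.2, c0 = 300),
    CD2 = list(a = 1.5, h_c = 7.5, a_hd = 5.3, c0 = 300),
    CD4 = list(a = 1.5, h_c = 11, a_hd = 3.7, c0 = 300),
    CD45 = list(a = 1.5, h_c = 15, a_hd = 8.0, c0 = 150, rotating = TRUE)
  )
  key <- if (identical(name, "CD45-rotating-rod")) "CD45" else name
  if (!key %in% names(presets))
    .stopf("unknown scenario '%s'; available: %s, CD45-rotating-rod",
           name, paste(names(presets), collapse = ", "))
  p <- presets[[key]]
  flow <- parametric_flow_model(delta_p = delta_p)
  a0 <- a_hydro_zero(molecule_geometry(p$a, p$h_c))
  if (is.null(mu_model)) {
    mu_model <- if (isTRUE(p$rotating))
      list(type = "linear", slope = 2 * 2 * pi * p$a_hd^2 * 1e-6)
    else hard_disk_model(p$a_hd)
  }
  truth <- ground_truth(mu_model = mu_model, a_hydro0 = a0, c0 = p$c0,
                        eps = flow, seed = seed)
  attr(truth, "scenario") <- c(list(name = key), p, list(a_hydro0_theory = a0))
  truth
}
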