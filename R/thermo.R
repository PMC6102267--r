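#' Two-dimensional hard-disk model
#'
#' A hard disk of radius `a_hd` with the virial coefficients of the 2D
#' hard-disk equation of state. The excess chemical potential of a fluid of
#' such disks at surface coverage \eqn{\Phi = c \pi a^2} is the truncated
#' virial series
#' \deqn{\mu^{ex}(\Phi) = k_BT\,(2B_2\Phi + \tfrac{3}{2}B_3\Phi^2 +
#'   \tfrac{4}{3}B_4\Phi^3).}
#' The defaults are the literature values for hard disks in two dimensions.
#'
#' @param a_hd Disk radius in nm.
#' @param B2,B3,B4 Dimensionless virial coefficients.
#' @param mu0 Standard-state offset in kBT. Only differences in chemical
#'   potential are ever used, so this defaults to 0.
#' @return An object of class `hard_disk_model`.
#' @examples
#' m <- hard_disk_model(3.2)
#' mu_excess_hard_disk(0.1, m)
#' @export
hard_disk_model <- function(a_hd, B2 = 2, B3 = 3.128, B4 = 4.258, mu0 = 0) {
  .check_num(a_hd, "a_hd", min = 0, strict = TRUE)
  .check_num(B2, "B2"); .check_num(B3, "B3"); .check_num(B4, "B4")
  structure(list(a_hd = a_hd, B2 = B2, B3 = B3, B4 = B4, mu0 = mu0),
            class = "hard_disk_model")
}

#' @export
print.hard_disk_model <- function(x, ...) {
  cat(sprintf("Hard-disk model: a_hd = %.3g nm (B2 = %g, B3 = %g, B4 = %g)\n",
              x$a_hd, x$B2, x$B3, x$B4))
  invisible(x)
}

#' Excess chemical potential of a 2D hard-disk fluid
#'
#' Evaluates the truncated virial series for the excess chemical potential at
#' surface coverage `phi`. Strictly increasing in coverage for positive
#' coefficients and exactly zero at zero coverage.
#'
#' @param phi Surface coverage fraction(s), `0 <= phi < 1`.
#' @param model A [hard_disk_model()]. Only the virial coefficients are used.
#' @return Excess chemical potential in kBT, same length as `phi`.
#' @export
mu_excess_hard_disk <- function(phi, model = hard_disk_model(1)) {
  if (!is.numeric(phi) || any(!is.finite(phi)))
    .stopf("'phi' must be finite numeric")
  if (any(phi < 0) || any(phi >= 1))
    .stopf("coverage must satisfy 0 <= phi < 1 (got %g)", phi[phi < 0 | phi >= 1][1])
  2 * model$B2 * phi + 1.5 * model$B3 * phi^2 + (4 / 3) * model$B4 * phi^3
}

# derivative d mu_ex / d phi, used by the steady-state solvers
mu_excess_hard_disk_deriv <- function(phi, model) {
  2 * model$B2 + 3 * model$B3 * phi + 4 * model$B4 * phi^2
}

#' Surface coverage from molecular concentration
#'
#' \eqn{\Phi = c \cdot \pi a^2} with `c` in molecules/um^2 and `a` in nm.
#'
#' @param conc Surface concentration(s) in molecules/um^2.
#' @param a_hd Disk radius in nm.
#' @return Dimensionless coverage fraction(s).
#' @export
coverage_fraction <- function(conc, a_hd) {
  if (any(conc < 0)) .stopf("concentrations must be >= 0")
  conc * pi * a_hd^2 * 1e-6
}

#' Fit a hard-disk radius to a measured excess chemical potential curve
#'
#' Least-squares fit of the virial excess chemical potential to measured
#' `(concentration, mu_excess)` pairs, with the disk radius as the only free
#' parameter. Residuals are relative by default (each residual divided by
#' `pmax(abs(mu), weight_floor)`), since the measured curve spans an order of
#' magnitude in kBT; absolute residuals are available via `relative = FALSE`.
#'
#' @param conc Concentrations in molecules/um^2.
#' @param mu_ex Measured excess chemical potentials in kBT.
#' @param model Template [hard_disk_model()] supplying virial coefficients.
#' @param radius_bounds Search interval for the radius in nm.
#' @param relative Use relative residuals (default) or absolute.
#' @param weight_floor Floor on the relative-residual denominator in kBT.
#' @param weights Optional per-point weights (multiplied into the residuals).
#' @param conc0 Baseline concentration (molecules/um^2) if the measured
#'   curve is referenced to a trap baseline: measured excess chemical
#'   potentials inferred from trapping are zero at `c0` by construction, so
#'   the model is evaluated as `mu_ex(phi) - mu_ex(phi0)`. `NULL` (default)
#'   fits the absolute virial curve.
#' @return A list of class `hd_fit` with elements `a_hd` (nm), `se` (nm),
#'   `status` (`"ok"`, `"boundary"` or `"failed"`), `fitted`, `residuals`.
#' @export
fit_hard_disk_radius <- function(conc, mu_ex, model = hard_disk_model(1),
                                 radius_bounds = c(0.1, 50), relative = TRUE,
                                 weight_floor = 0.05, weights = NULL,
                                 conc0 = NULL) {
  keep <- is.finite(conc) & is.finite(mu_ex) & conc > 0
  conc <- conc[keep]; mu_ex <- mu_ex[keep]
  if (length(conc) < 4L)
    .stopf("need at least 4 finite curve points, got %d", length(conc))
  if (diff(range(conc)) <= 0) .stopf("degenerate concentration range")
  if (all(abs(mu_ex) < 1e-12)) {
    return(structure(list(a_hd = NA_real_, se = NA_real_, status = "failed",
                          message = "all-zero excess chemical potential",
                          fitted = rep(0, length(conc)), residuals = mu_ex),
                     class = "hd_fit"))
  }
  w <- if (is.null(weights)) rep(1, length(conc)) else weights[keep]
  denom <- if (relative) pmax(abs(mu_ex), weight_floor) else rep(1, length(mu_ex))
  resid_fun <- function(a) {
    phi <- pmin(coverage_fraction(conc, a), 0.999)
    base <- if (is.null(conc0)) 0
    else mu_excess_hard_disk(min(coverage_fraction(conc0, a), 0.999), model)
    w * (mu_excess_hard_disk(phi, model) - base - mu_ex) / denom
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = list(a = sqrt(mean(radius_bounds))),
                       lower = radius_bounds[1], upper = radius_bounds[2],
                       fn = function(par) resid_fun(par$a),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(structure(list(a_hd = NA_real_, se = NA_real_, status = "failed",
                          message = "non-convergent fit"), class = "hd_fit"))
  }
  a_hat <- fit$par$a
  status <- "ok"
  tol_b <- 1e-6 * diff(radius_bounds)
  if (a_hat <= radius_bounds[1] + tol_b || a_hat >= radius_bounds[2] - tol_b)
    status <- "boundary"
  dof <- length(conc) - 1L
  se <- tryCatch({
    s2 <- sum(fit$fvec^2) / max(dof, 1L)
    sqrt(s2 * solve(fit$hessian)[1, 1]) * sqrt(2) # hessian = 2 J'J for nls.lm
  }, error = function(e) NA_real_)
  phi_hat <- coverage_fraction(conc, a_hat)
  base_hat <- if (is.null(conc0)) 0
  else mu_excess_hard_disk(min(coverage_fraction(conc0, a_hat), 0.999), model)
  structure(list(a_hd = a_hat, se = se, status = status,
                 fitted = mu_excess_hard_disk(pmin(phi_hat, 0.999), model) - base_hat,
                 residuals = fit$fvec), class = "hd_fit")
}

#' @export
print.hd_fit <- function(x, ...) {
  if (identical(x$status, "ok") || identical(x$status, "boundary"))
    cat(sprintf("Hard-disk fit: a_hd = %.3g +/- %.2g nm [%s]\n",
                x$a_hd, x$se, x$status))
  else cat(sprintf("Hard-disk fit failed: %s\n", x$message))
  invisible(x)
}

#' Glycan area-mapping model
#'
#' Empirical map from the normalized projected area of a glycosylated
#' molecule (protein + sugars, normalized to the sugar-free protein) to its
#' normalized effective hard-disk area,
#' \deqn{A_{hd} = \frac{p_1 (A_p-1)^2 + p_2 (A_p-1) + 1}
#'   {p_1 (A_p-1)^2 / q + 1},}
#' which is approximately linear near \eqn{A_p = 1} and saturates at the
#' plateau \eqn{q}: the normalized projected area of a disk whose radius is
#' the protein radius plus the sugar length. On the physical domain
#' \eqn{1 \le A_p \le q} the map is monotone and bounded by the plateau
#' (outside it, where the projected area would exceed the full
#' protein+sugar disk, the rational form overshoots before levelling off).
#'
#' @param p1,p2 Dimensionless coefficients.
#' @param plateau Dimensionless saturation value.
#' @return An object of class `glyco_area_model`.
#' @export
glyco_area_model <- function(p1 = 0.66, p2 = 0.95, plateau = 9.82) {
  .check_num(p1, "p1"); .check_num(p2, "p2")
  .check_num(plateau, "plateau", min = 1, strict = TRUE)
  structure(list(p1 = p1, p2 = p2, plateau = plateau),
            class = "glyco_area_model")
}

#' Normalized hard-disk area of a glycosylated molecule
#'
#' @param a_projected Normalized projected area(s), `>= 1`.
#' @param model A [glyco_area_model()].
#' @return Normalized hard-disk area(s).
#' @export
glyco_hard_disk_area <- function(a_projected, model = glyco_area_model()) {
  if (any(!is.finite(a_projected)) || any(a_projected < 1))
    .stopf("'a_projected' must be >= 1 (normalized to the sugar-free protein)")
  x <- a_projected - 1
  (model$p1 * x^2 + model$p2 * x + 1) / (model$p1 * x^2 / model$plateau + 1)
}

#' Fit the glycan area-mapping coefficients
#'
#' Least-squares fit of `p1` and `p2` with the plateau held fixed (the
#' plateau is a geometric quantity, the normalized projected area of the
#' protein-radius + sugar-length disk, not a free parameter).
#'
#' @param a_projected Normalized projected areas (`>= 1`).
#' @param a_hard_disk Normalized hard-disk areas.
#' @param plateau Fixed plateau value.
#' @param start Starting values for `p1`, `p2`.
#' @return A [glyco_area_model()] with attributes `se` (standard errors) and
#'   `status`.
#' @export
fit_glyco_coefficients <- function(a_projected, a_hard_disk, plateau = 9.82,
                                   start = c(p1 = 0.5, p2 = 1)) {
  if (length(a_projected) < 3L || length(a_hard_disk) != length(a_projected))
    .stopf("need >= 3 paired (projected, hard-disk) area points")
  if (diff(range(a_projected)) < 1e-9)
    .stopf("degenerate input: all projected areas identical")
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = as.list(start),
      fn = function(par) {
        m <- glyco_area_model(par$p1, par$p2, plateau)
        glyco_hard_disk_area(a_projected, m) - a_hard_disk
      },
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  bad <- is.null(fit) || !fit$info %in% 1:4
  cov_ok <- !bad && tryCatch({
    h <- solve(fit$hessian); all(diag(h) > 0)
  }, error = function(e) FALSE)
  if (bad || !cov_ok) {
    out <- structure(list(p1 = if (bad) NA_real_ else fit$par$p1,
                          p2 = if (bad) NA_real_ else fit$par$p2,
                          plateau = plateau), class = "glyco_area_model")
    attr(out, "status") <- "ill-conditioned"
    attr(out, "se") <- c(p1 = NA_real_, p2 = NA_real_)
    return(out)
  }
  s2 <- sum(fit$fvec^2) / max(length(a_projected) - 2L, 1L)
  se <- sqrt(2 * s2 * diag(solve(fit$hessian)))
  out <- glyco_area_model(fit$par$p1, fit$par$p2, plateau)
  attr(out, "status") <- "ok"
  attr(out, "se") <- setNames(se, c("p1", "p2"))
  out
}
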