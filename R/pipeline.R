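#' Trap image
#'
#' A 2D fluorescence intensity grid with its pixel size. Row/column indices
#' map to physical coordinates through the pixel size (pixel centres at
#' `(i - 0.5) * pixel_size`).
#'
#' @param intensity Numeric matrix of non-negative intensities.
#' @param pixel_size Pixel size in um/px.
#' @return An object of class `trap_image`.
#' @export
trap_image <- function(intensity, pixel_size = 0.22) {
  intensity <- as.matrix(intensity)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    .stopf("intensities must be finite and non-negative")
  .check_num(pixel_size, "pixel_size", min = 0, strict = TRUE)
  structure(list(intensity = intensity, pixel_size = pixel_size),
            class = "trap_image")
}

#' @export
print.trap_image <- function(x, ...) {
  cat(sprintf("Trap image: %d x %d px, %.3g um/px\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size))
  invisible(x)
}

#' Locate the trap centre in an image
#'
#' Intensity-weighted centroid of the brightest pixels (top `quantile_top`
#' fraction), giving a sub-pixel estimate. An image without a clear peak
#' above background (peak below `min_contrast` robust deviations above the
#' median) yields an error status instead of a coordinate.
#'
#' @param image A [trap_image()].
#' @param quantile_top Quantile defining the bright-pixel set.
#' @param min_contrast Required peak height in units of the robust scale
#'   (median absolute deviation) above the median.
#' @return A list with `x`, `y` (um), and `status` (`"ok"` or `"no-peak"`).
#' @export
find_trap_centre <- function(image, quantile_top = 0.995, min_contrast = 8) {
  stopifnot(inherits(image, "trap_image"))
  I <- image$intensity
  med <- median(I)
  scale <- max(stats::mad(I), 1e-12)
  if ((max(I) - med) / scale < min_contrast)
    return(list(x = NA_real_, y = NA_real_, status = "no-peak"))
  thr <- quantile(I, quantile_top)
  idx <- which(I >= thr, arr.ind = TRUE)
  wts <- I[idx] - med
  wts <- pmax(wts, 0)
  px <- image$pixel_size
  list(x = sum((idx[, 1] - 0.5) * wts) / sum(wts) * px,
       y = sum((idx[, 2] - 0.5) * wts) / sum(wts) * px,
       status = "ok")
}

#' Radially averaged profile around a centre
#'
#' Mean intensity per annulus of width `bin_width` around `centre`,
#' reported out to the largest radius whose annulus lies fully inside the
#' image. Bins are averages over the pixels whose centres fall in the
#' annulus (no area weighting beyond pixel counting); empty bins are
#' dropped, not interpolated.
#'
#' @param image A [trap_image()].
#' @param centre List or vector with `x`, `y` in um (e.g. from
#'   [find_trap_centre()]).
#' @param bin_width Radial bin width in um.
#' @return An object of class `radial_profile` (data frame with `r` bin
#'   centres in um, `value`, `n` pixel counts).
#' @export
radial_average <- function(image, centre, bin_width = 0.22) {
  stopifnot(inherits(image, "trap_image"))
  cx <- centre$x %||% centre[[1]]
  cy <- centre$y %||% centre[[2]]
  px <- image$pixel_size
  nr <- nrow(image$intensity); nc <- ncol(image$intensity)
  if (cx < 0 || cy < 0 || cx > nr * px || cy > nc * px)
    .stopf("centre (%.3g, %.3g) um lies outside the image", cx, cy)
  xs <- ((seq_len(nr)) - 0.5) * px
  ys <- ((seq_len(nc)) - 0.5) * px
  r <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`))
  r_max <- min(cx, cy, nr * px - cx, nc * px - cy)
  bins <- floor(r / bin_width)
  keep <- r < r_max
  agg_n <- tabulate(bins[keep] + 1L)
  agg_s <- vapply(seq_along(agg_n), function(b)
    sum(image$intensity[keep & bins == b - 1L]), numeric(1))
  nonzero <- agg_n > 0
  radial_profile(r = (which(nonzero) - 0.5) * bin_width,
                 value = agg_s[nonzero] / agg_n[nonzero],
                 n = agg_n[nonzero])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a radial profile
#'
#' @param r Bin centres in um, strictly increasing.
#' @param value Mean intensity or concentration per bin.
#' @param n Pixel/observation counts per bin.
#' @return An object of class `radial_profile`.
#' @export
radial_profile <- function(r, value, n = rep(1L, length(r))) {
  if (any(diff(r) <= 0)) .stopf("'r' must be strictly increasing")
  if (length(value) != length(r)) .stopf("'value' and 'r' lengths differ")
  structure(data.frame(r = r, value = value, n = n),
            class = c("radial_profile", "data.frame"))
}

#' Intensity calibration
#'
#' Converts background-subtracted fluorescence intensity to molecular
#' density, either through an explicit conversion factor (intensity per
#' molecule per pixel area, from single-molecule imaging) or by anchoring
#' the far-field intensity to a known baseline density `c0`.
#'
#' @param factor Molecules per um^2 per intensity unit (exclusive with
#'   `c0`).
#' @param c0 Baseline density in molecules/um^2 for far-field anchoring.
#' @param background Additive background intensity offset.
#' @return An object of class `intensity_calibration`.
#' @export
intensity_calibration <- function(factor = NULL, c0 = NULL, background = 0) {
  if (is.null(factor) && is.null(c0))
    .stopf("provide either a conversion 'factor' or a baseline 'c0'")
  if (!is.null(factor)) .check_num(factor, "factor", min = 0, strict = TRUE)
  if (!is.null(c0)) .check_num(c0, "c0", min = 0, strict = TRUE)
  structure(list(factor = factor, c0 = c0, background = background),
            class = "intensity_calibration")
}

#' Convert a radial intensity profile to molecular concentration
#'
#' Linear map `(I - background) * factor`. With `c0` anchoring, the factor
#' is set so the far-field value (mean over the outer `far_frac` of the
#' radial range) equals `c0`. Negative background-subtracted intensities
#' are clipped to zero and counted in the `clipped` attribute.
#'
#' @param profile A [radial_profile()] of intensities.
#' @param cal An [intensity_calibration()].
#' @param far_frac Fraction of the outer radial range used as far field.
#' @return A [radial_profile()] in molecules/um^2, with attributes
#'   `factor`, `c0` and `clipped`.
#' @export
intensity_to_concentration <- function(profile, cal, far_frac = 0.1) {
  stopifnot(inherits(profile, "radial_profile"),
            inherits(cal, "intensity_calibration"))
  net <- profile$value - cal$background
  clipped <- sum(net < 0)
  if (clipped > 0)
    .warnf("%d background-subtracted intensities were negative and clipped to 0", clipped)
  net <- pmax(net, 0)
  if (!is.null(cal$factor)) {
    factor <- cal$factor
    c0 <- cal$c0
  } else {
    far <- profile$r >= max(profile$r) - far_frac * diff(range(profile$r))
    far_mean <- sum(net[far] * profile$n[far]) / sum(profile$n[far])
    if (far_mean <= 0) .stopf("far-field intensity is zero; cannot anchor to c0")
    factor <- cal$c0 / far_mean
    c0 <- cal$c0
  }
  out <- radial_profile(profile$r, net * factor, profile$n)
  attr(out, "factor") <- factor
  attr(out, "c0") <- c0
  attr(out, "clipped") <- clipped
  out
}

#' Build an interaction curve
#'
#' Pairs the measured concentration at each radius with the trap energy at
#' the same radius (the trap-energy profile is interpolated onto the
#' concentration bins, which carry the noise statistics), and sorts by trap
#' energy. The result, ln(c) versus epsilon, is the molecule's interaction
#' curve; its low-coverage slope is A_hydro(0)/kBT.
#'
#' @param conc A [radial_profile()] in molecules/um^2.
#' @param eps A [trap_energy_profile()].
#' @param c0 Baseline concentration; defaults to the calibration anchor or
#'   the outermost value.
#' @return An object of class `interaction_curve` (data frame with
#'   `epsilon` in J/m^2, `conc`, `r`, `n`), with attribute `c0`.
#' @export
build_interaction_curve <- function(conc, eps, c0 = NULL) {
  stopifnot(inherits(conc, "radial_profile"),
            inherits(eps, "trap_energy_profile"))
  if (min(conc$r) > max(eps$r) || max(conc$r) < min(eps$r))
    .stopf("concentration and trap-energy profiles have disjoint radial supports")
  inside <- conc$r >= min(eps$r) & conc$r <= max(eps$r)
  if (!any(inside)) .stopf("no concentration bins inside the trap-energy support")
  e <- approx(eps$r, eps$epsilon, xout = conc$r[inside])$y
  if (is.null(c0)) c0 <- attr(conc, "c0") %||% conc$value[which.max(conc$r)]
  o <- order(e)
  out <- data.frame(epsilon = e[o], conc = conc$value[inside][o],
                    r = conc$r[inside][o], n = conc$n[inside][o])
  attr(out, "c0") <- c0
  class(out) <- c("interaction_curve", "data.frame")
  out
}

#' Zero-coverage hydrodynamic area from the interaction-curve slope
#'
#' The low-coverage slope of ln(c) versus trap energy is
#' `A_hydro(0)/kBT`. Two refinements make the estimator accurate on real
#' curves: (i) the default `"quadratic"` method fits
#' `ln c ~ epsilon + epsilon^2` on the low-coverage window and reports the
#' linear term — the initial slope at zero trap energy — which removes the
#' first-order curvature bias of a straight-line fit through an already
#' bending window; (ii) even at zero trap energy the slope is depressed by
#' the factor `1 + phi0 * dmu_ex/dphi(phi0)` when the baseline itself is
#' interacting, so the estimate is multiplied back by that factor computed
#' at the provisional radius (`baseline_correction`, on by default).
#'
#' @param curve An [build_interaction_curve()] result.
#' @param a_provisional Provisional radius in nm used to define the
#'   low-coverage cutoff and the baseline correction.
#' @param phi_max Low-coverage cutoff (coverage fraction).
#' @param weighted Weight points by their pixel counts.
#' @param method `"quadratic"` (initial slope, default) or `"linear"`.
#' @param baseline_correction Correct for baseline-coverage interactions.
#' @return A list of class `slope_fit`: `a_hydro0` (nm^2), `se` (nm^2),
#'   `n_points`, `phi_max`, `method`, `baseline_factor`, `status`.
#' @export
slope_a_hydro0 <- function(curve, a_provisional, phi_max = 0.05,
                           weighted = TRUE,
                           method = c("quadratic", "linear"),
                           baseline_correction = TRUE) {
  stopifnot(inherits(curve, "interaction_curve"))
  method <- match.arg(method)
  phi <- coverage_fraction(curve$conc, a_provisional)
  keep <- phi <= phi_max & curve$conc > 0
  if (sum(keep) < 4L)
    .stopf("only %d points below the coverage cutoff phi <= %g; need >= 4",
           sum(keep), phi_max)
  d <- curve[keep, , drop = FALSE]
  w <- if (weighted) d$n else rep(1, nrow(d))
  fit <- if (method == "quadratic" && nrow(d) >= 6L)
    lm(log(conc) ~ epsilon + I(epsilon^2), data = d, weights = w)
  else lm(log(conc) ~ epsilon, data = d, weights = w)
  slope <- coef(fit)[["epsilon"]] # 1/(J/m^2)
  se_slope <- sqrt(vcov(fit)["epsilon", "epsilon"])
  bf <- 1
  if (baseline_correction) {
    c0 <- attr(curve, "c0") %||% d$conc[which.min(d$epsilon)]
    phi0 <- min(coverage_fraction(c0, a_provisional), 0.5)
    bf <- 1 + phi0 * mu_excess_hard_disk_deriv(phi0, hard_disk_model(a_provisional))
  }
  status <- if (abs(slope) <= 2 * se_slope) "flat" else "ok"
  structure(list(a_hydro0 = slope * bf * KBT_J * 1e18,
                 se = se_slope * bf * KBT_J * 1e18,
                 n_points = nrow(d), phi_max = phi_max, method = method,
                 baseline_factor = bf, status = status),
            class = "slope_fit")
}

#' Chemical potential from an interaction curve
#'
#' Integrates the force balance along the curve: at steady state
#' \eqn{\mu(c) = \mu(c_0) + \int_0^{\epsilon} A_{hydro}(c)\, d\epsilon'},
#' evaluated as a cumulative trapezoid over the curve (with the point
#' `(epsilon = 0, c = c0)` prepended). The excess part subtracts the ideal
#' term, \eqn{\mu^{ex} = \mu - k_BT \ln(c/c_0)}, and is zero at `c0` by
#' construction. A non-monotone concentration-versus-energy relation beyond
#' `noise_tol` triggers isotonic pre-smoothing (with a warning); the raw
#' concentrations are retained in the output.
#'
#' @param curve An [build_interaction_curve()] result.
#' @param a_hydro_fun Function mapping concentration (molecules/um^2) to
#'   hydrodynamic area (nm^2); e.g. built from [a_hydro_of_coverage()].
#'   A constant area may be given as a single number.
#' @param noise_tol Allowed relative non-monotonicity before smoothing.
#' @return A data frame of class `mu_curve`: `conc`, `epsilon`, `mu`
#'   (kBT, relative to `c0`), `mu_ex` (kBT), `conc_raw`.
#' @export
mu_from_curve <- function(curve, a_hydro_fun, noise_tol = 0.02) {
  stopifnot(inherits(curve, "interaction_curve"))
  if (nrow(curve) < 2L) .stopf("interaction curve has fewer than 2 points")
  if (is.numeric(a_hydro_fun)) {
    a_const <- a_hydro_fun
    a_hydro_fun <- function(c) rep(a_const, length(c))
  }
  c0 <- attr(curve, "c0")
  eps <- c(0, curve$epsilon)
  conc_raw <- c(c0, curve$conc)
  conc <- conc_raw
  drops <- diff(conc) < 0
  if (any(drops)) {
    rel <- abs(pmin(diff(conc), 0)) / pmax(conc[-length(conc)], 1e-12)
    if (max(rel) > noise_tol)
      .warnf("concentration is non-monotone in trap energy (max drop %.1f%%); applying isotonic smoothing",
             100 * max(rel))
    conc <- isoreg(eps, conc)$yf
  }
  A <- a_hydro_fun(conc) # nm^2
  integrand <- A * NM2_EPS_TO_KBT # kBT per (J/m^2)
  n <- length(eps)
  mu <- c(0, cumsum(diff(eps) * (integrand[-1] + integrand[-n]) / 2))
  mu_ex <- mu - log(pmax(conc, 1e-300) / c0)
  out <- data.frame(conc = conc[-1], epsilon = eps[-1], mu = mu[-1],
                    mu_ex = mu_ex[-1], conc_raw = conc_raw[-1])
  attr(out, "c0") <- c0
  class(out) <- c("mu_curve", "data.frame")
  out
}

#' Fit candidate interaction models to an excess chemical potential curve
#'
#' Least-squares fits of each candidate model to the measured
#' `(concentration, mu_ex)` data, ranked by residual sum of squares. Two
#' candidate types are supported: `"hard_disk"` (free disk radius, the
#' virial equation of state) and `"mc_curve"` (a simulated reference curve
#' of `mu_ex` versus coverage, e.g. a rotating rod, scaled by a free
#' footprint radius).
#'
#' @param mu_curve A [mu_from_curve()] result or data frame with `conc` and
#'   `mu_ex`.
#' @param candidates Named list of candidates; each is a list with `type`
#'   (`"hard_disk"` or `"mc_curve"`) and, for `"mc_curve"`, elements `phi`
#'   and `mu_ex` giving the reference curve.
#' @param radius_bounds Search bounds for the scale radius in nm.
#' @param conc0 Baseline concentration; trap-inferred excess chemical
#'   potentials are zero at the baseline, so candidate model curves are
#'   referenced to it. Defaults to the curve's `c0` attribute, if any.
#' @return A list of class `model_ranking`: per-candidate fits (with `rss`,
#'   `a` and `status`) ordered best first, and `best`, the winning name.
#' @export
fit_interaction_models <- function(mu_curve,
                                   candidates = list(hard_disk = list(type = "hard_disk")),
                                   radius_bounds = c(0.1, 50),
                                   conc0 = attr(mu_curve, "c0")) {
  d <- mu_curve[is.finite(mu_curve$conc) & is.finite(mu_curve$mu_ex) &
                  mu_curve$conc > 0, , drop = FALSE]
  if (nrow(d) < 2L) .stopf("need at least 2 finite (conc, mu_ex) points")
  fits <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    if (identical(cand$type, "hard_disk")) {
      f <- fit_hard_disk_radius(d$conc, d$mu_ex, radius_bounds = radius_bounds,
                                relative = FALSE, conc0 = conc0)
      if (!f$status %in% c("ok", "boundary"))
        return(list(name = nm, status = "failed", rss = Inf, a = NA_real_))
      rss <- sum((f$fitted - d$mu_ex)^2)
      list(name = nm, status = f$status, rss = rss, a = f$a_hd, se = f$se,
           type = "hard_disk")
    } else if (identical(cand$type, "mc_curve")) {
      ref <- cand[c("phi", "mu_ex")]
      if (max(d$mu_ex) > max(ref$mu_ex) * 1.05)
        return(list(name = nm, status = "skipped: reference curve range insufficient",
                    rss = Inf, a = NA_real_))
      pred <- function(a) {
        phi <- coverage_fraction(d$conc, a)
        base <- if (is.null(conc0)) 0
        else approx(ref$phi, ref$mu_ex, xout = coverage_fraction(conc0, a),
                    rule = 2)$y
        approx(ref$phi, ref$mu_ex, xout = phi, rule = 2)$y - base
      }
      obj <- function(a) sum((pred(a) - d$mu_ex)^2)
      opt <- optimize(obj, radius_bounds)
      status <- if (opt$minimum <= radius_bounds[1] * 1.001 ||
                    opt$minimum >= radius_bounds[2] * 0.999) "boundary" else "ok"
      list(name = nm, status = status, rss = opt$objective, a = opt$minimum,
           type = "mc_curve")
    } else .stopf("unknown candidate type '%s'", cand$type)
  })
  names(fits) <- names(candidates)
  ord <- order(vapply(fits, function(f) f$rss, numeric(1)))
  structure(list(fits = fits[ord], best = names(fits)[ord][1]),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Model ranking (best first):\n")
  for (f in x$fits)
    cat(sprintf("  %-14s rss = %.4g  a = %.3g nm  [%s]\n",
                f$name, f$rss, f$a, f$status))
  invisible(x)
}
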