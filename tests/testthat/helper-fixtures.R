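# Shared fixtures: small synthetic datasets built in code at test time.

# Quick MC sweep with reduced sampling for unit tests (not used by the
# acceptance checks, which run at the default production length).
quick_sweep <- function(topology, phi_grid, restraint = restraint_spec(),
                        n_steps = 4e4, seed = 1) {
  sweep_coverage(topology, phi_grid, restraint = restraint,
                 config = mc_config(n_steps = n_steps, n_samples = 300,
                                    n_insert = 40, seed = seed))
}

# Radially symmetric Gaussian blob image with a flat background, in counts.
blob_image <- function(n = 128, px = 0.22, centre = c(n, n) * px / 2,
                       amp = 2000, sd_um = 2, background = 300,
                       noise_sd = 0, seed = 1) {
  xs <- (seq_len(n) - 0.5) * px
  r2 <- outer((xs - centre[1])^2, (xs - centre[2])^2, `+`)
  I <- background + amp * exp(-r2 / (2 * sd_um^2))
  if (noise_sd > 0) {
    set.seed(seed)
    I <- I + matrix(rnorm(n * n, sd = noise_sd), n, n)
  }
  trap_image(pmax(I, 0), px)
}

# A small hard-disk ground truth with a gentle trap, cheap to solve.
hd_truth <- function(a_hd = 3.2, a_hydro0 = 296, c0 = 300, delta_p = -9.7,
                     seed = 1, image_size = 256L,
                     noise = list(counts_per_molecule = 80, background = 400,
                                  read_sd = 3)) {
  ground_truth(mu_model = hard_disk_model(a_hd), a_hydro0 = a_hydro0,
               c0 = c0, eps = parametric_flow_model(delta_p = delta_p),
               noise = noise, image_size = image_size, seed = seed)
}

# Analyze a rendered image back to (A_hydro(0), a_hd) with the true trap
# energy profile, mirroring the experimental inference chain.
analyze_synthetic <- function(img, truth, a_provisional = 3, phi_max = 0.05) {
  ctr <- find_trap_centre(img)
  prof <- radial_average(img, ctr)
  conc <- intensity_to_concentration(
    prof, intensity_calibration(c0 = truth$c0,
                                background = truth$noise$background))
  eps <- flow_model_epsilon(truth$eps, conc$r)
  curve <- build_interaction_curve(conc, eps)
  slope <- slope_a_hydro0(curve, a_provisional, phi_max = phi_max)
  mu <- mu_from_curve(curve, slope$a_hydro0)
  fit <- fit_hard_disk_radius(mu$conc, mu$mu_ex, conc0 = attr(mu, "c0"))
  list(curve = curve, slope = slope, mu = mu, fit = fit)
}
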