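test_that("WCA pair potential has the cut-and-shifted repulsive form", {
  sig <- 0.1
  expect_equal(wca_pair_energy(2^(1 / 6) * sig, sig), 0)
  expect_equal(wca_pair_energy(1, sig), 0) # zero beyond the cutoff, exactly
  expect_equal(wca_pair_energy(sig, sig, eps_lj = 1), 1) # 1 LJ unit at sigma
  rs <- seq(0.4, 1.12, by = 0.02) * sig
  us <- wca_pair_energy(rs, sig)
  expect_true(all(diff(us) < 0)) # strictly decreasing below the minimum
  expect_true(is.finite(wca_pair_energy(0, sig))) # capped, not infinite
  expect_gt(wca_pair_energy(0, sig), 1e6)
})

test_that("the soft-disk coverage correction multiplies by 1.075 squared", {
  expect_equal(corrected_coverage(0), 0)
  expect_equal(corrected_coverage(0.1), 0.1155625)
  expect_equal(corrected_coverage(1), 1.155625)
})

test_that("incremental energy bookkeeping does not drift", {
  run <- run_mc(bead_rod(3, 0.1), 40, sim_box(2, 2, 2), restraint_spec(0),
                mc_config(n_steps = 3e4, seed = 5))
  expect_equal(run$energy_running, run$energy_recomputed,
               tolerance = 1e-8)
})

test_that("seeded runs are bit-reproducible", {
  r1 <- run_mc(bead_rod(3, 0.1), 20, sim_box(2, 2, 2), restraint_spec(0),
               mc_config(n_steps = 1e4, seed = 7))
  r2 <- run_mc(bead_rod(3, 0.1), 20, sim_box(2, 2, 2), restraint_spec(0),
               mc_config(n_steps = 1e4, seed = 7))
  expect_identical(r1$states_xy, r2$states_xy)
  expect_identical(r1$states_q, r2$states_q)
  w1 <- widom_mu_excess(r1)
  w2 <- widom_mu_excess(r2)
  expect_identical(w1$mu_ex, w2$mu_ex)
})

test_that("move amplitudes auto-tune into a healthy acceptance window", {
  run <- run_mc(bead_rod(3, 0.1), 60, sim_box(2, 2, 2), restraint_spec(0),
                mc_config(n_steps = 5e4, seed = 3))
  expect_gt(run$acc_trans, 0.2); expect_lt(run$acc_trans, 0.8)
  expect_gt(run$acc_rot, 0.2); expect_lt(run$acc_rot, 0.8)
})

test_that("the tilt restraint narrows the tilt distribution monotonically", {
  q95 <- sapply(c(1, 5, 50), function(kf) {
    run <- run_mc(bead_rod(3, 0.1), 1, sim_box(2, 2, 2), restraint_spec(kf),
                  mc_config(n_steps = 4e4, n_samples = 2000, seed = 11))
    quantile(run$tilt, 0.95) * 180 / pi
  })
  expect_true(all(diff(q95) < 0))
  # sampled quantiles agree with the analytic single-molecule distribution
  expect_equal(unname(q95[2]), tilt_quantile(5, bead_rod(3, 0.1)$L_max),
               tolerance = 0.08)
})

test_that("a stiff spring pins the rod upright", {
  rod <- bead_rod(3, 0.1)
  kf <- kf_for_tilt(2, rod$L_max) # 95% within 2 degrees
  run <- run_mc(rod, 1, sim_box(2, 2, 2), restraint_spec(kf),
                mc_config(n_steps = 2e4, n_samples = 500, seed = 2))
  expect_lt(quantile(run$tilt, 0.95) * 180 / pi, 4)
})

test_that("tilt calibration and its quantile are mutual inverses", {
  for (ang in c(5, 10, 30)) {
    kf <- kf_for_tilt(ang, 0.25)
    expect_equal(tilt_quantile(kf, 0.25), ang, tolerance = 1e-5)
  }
})

test_that("Widom insertion respects its exact limits", {
  # empty box: mu_ex = 0 +/- 0
  run0 <- run_mc(bead_rod(1, 0.1), 0, sim_box(2, 2, 2), restraint_spec(rigid = TRUE),
                 mc_config(n_steps = 100, seed = 1))
  w0 <- widom_mu_excess(run0)
  expect_identical(c(w0$mu_ex, w0$se), c(0, 0))
  # two seeds agree within 3 combined standard errors
  est <- lapply(c(13, 17), function(s) {
    run <- run_mc(bead_rod(1, 0.1), 50, sim_box(2, 2, 2),
                  restraint_spec(rigid = TRUE), mc_config(n_steps = 5e4, seed = s))
    widom_mu_excess(run)
  })
  dmu <- abs(est[[1]]$mu_ex - est[[2]]$mu_ex)
  expect_lt(dmu, 3 * sqrt(est[[1]]$se^2 + est[[2]]$se^2))
})

test_that("squat grafted spheres reproduce the hard-disk virial curve", {
  # spec example at phi = 0.05: within 5% of the virial oracle
  cur <- quick_sweep(bead_rod(1, 0.1), 0.05 / 1.075^2, n_steps = 6e4, seed = 19)
  expect_equal(cur$mu_ex, mu_excess_hard_disk(cur$phi), tolerance = 0.05)
})

test_that("coverage sweeps produce monotone curves with exact zero point", {
  cur0 <- sweep_coverage(bead_rod(1, 0.1), 0)
  expect_identical(c(cur0$phi, cur0$mu_ex, cur0$se), c(0, 0, 0))
  cur <- quick_sweep(bead_rod(1, 0.1), c(0.04, 0.1, 0.16), seed = 23)
  expect_true(all(diff(cur$mu_ex) > -2 * sqrt(cur$se[-1]^2 + cur$se[-3]^2)))
  expect_true(all(cur$ok))
})

test_that("the 1 kBT coverage interpolator matches a root-finding oracle", {
  # oracle: uniroot on the virial series, 4p + 4.692p^2 + 5.6773p^3 = 1
  phi_star <- 0.1949213
  phis <- seq(0.01, 0.4, by = 0.01)
  curve <- data.frame(phi = phis, mu_ex = mu_excess_hard_disk(phis))
  expect_equal(coverage_at_1kT(curve), phi_star, tolerance = 1e-3)
  # exact crossing point is returned as-is
  exact <- data.frame(phi = c(0.1, 0.25, 0.4), mu_ex = c(0.3, 1, 2.2))
  expect_identical(coverage_at_1kT(exact), 0.25)
  expect_error(coverage_at_1kT(data.frame(phi = 1:3 / 10, mu_ex = c(1.2, 1.5, 2))),
               "bracket")
  expect_error(coverage_at_1kT(data.frame(phi = 1:3 / 10, mu_ex = c(0.1, 0.2, 0.3))),
               "bracket")
})

test_that("identical curves give unit width and area amplification", {
  phis <- seq(0.05, 0.4, by = 0.05)
  cur <- data.frame(phi = phis, mu_ex = mu_excess_hard_disk(phis))
  expect_equal(effective_width_ratio(cur, cur), 1)
  expect_equal(hard_disk_area_ratio(cur, cur), 1)
})

test_that("projected areas are unions of circular projections", {
  # single sphere
  one <- bead_rod(1, 0.3)
  expect_equal(projected_area(one), pi * 0.15^2, tolerance = 1e-4)
  # collinear stack projects to a single circle (union, not sum)
  stack <- bead_rod(3, 0.3)
  expect_equal(projected_area(stack), pi * 0.15^2, tolerance = 1e-4)
  # four tangent sugar chains at distinct azimuths: areas add exactly
  glyco <- glyco_bead_chain(4)
  pa <- projected_area(glyco, normalize = TRUE)
  expect_equal(pa$normalized, 1 + 4 * 2 * 0.08^2 / 0.15^2, tolerance = 1e-3)
  # excluding sugars recovers the protein footprint
  expect_equal(projected_area(glyco, include_sugars = FALSE), pi * 0.15^2,
               tolerance = 1e-4)
})

test_that("infeasible coverages fail with the achievable maximum reported", {
  expect_error(run_mc(bead_rod(1, 0.1), 500, sim_box(1, 1, 1),
                      restraint_spec(rigid = TRUE), mc_config(n_steps = 100)),
               "achievable maximum")
})

test_that("glycosylation increases repulsion between the bounds of the area map", {
  # scaled-down glycosylation probe: 2 sugars on the middle protein sphere
  ref <- quick_sweep(glyco_bead_chain(0), c(0.08, 0.14, 0.2, 0.26, 0.32),
                     restraint = restraint_spec(5), n_steps = 5e4, seed = 31)
  gly <- quick_sweep(glyco_bead_chain(2), c(0.04, 0.08, 0.12, 0.16, 0.2, 0.26),
                     restraint = restraint_spec(5), n_steps = 5e4, seed = 37)
  ratio <- hard_disk_area_ratio(gly, ref)
  a_proj <- projected_area(glyco_bead_chain(2), normalize = TRUE)$normalized
  plateau <- (0.47 / 0.15)^2
  expect_gt(ratio, 1)        # sugars always add repulsion
  expect_lt(ratio, plateau)  # bounded by the full protein+sugar disk
  # near-upright molecules: hard-disk area at least the projected area scale
  expect_gt(ratio, 0.8 * a_proj)
})
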