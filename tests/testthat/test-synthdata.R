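test_that("steady-state solver honours its limits", {
  # zero trap energy: the profile stays at the baseline
  r <- seq(0.5, 20, by = 0.5)
  truth0 <- ground_truth(hard_disk_model(3.2), 296, 300,
                         trap_energy_profile(r, rep(0, length(r))))
  prof0 <- forward_steady_state(truth0, r)
  expect_true(all(prof0$value == 300))
  # ideal molecules with constant area: exact exponential accumulation
  truth_id <- ground_truth(list(type = "linear", slope = 0), 250, 40,
                           parametric_flow_model(delta_p = -4))
  prof_id <- forward_steady_state(truth_id, r)
  eps <- flow_model_epsilon(truth_id$eps, r)$epsilon
  expect_equal(prof_id$value, 40 * exp(250 * 1e-18 / 4.11e-21 * eps),
               tolerance = 1e-5, ignore_attr = TRUE)
  # interacting molecules accumulate less than ideal ones
  truth_hd <- hd_truth(a_hd = 3.2, a_hydro0 = 250, c0 = 40, delta_p = -4)
  prof_hd <- forward_steady_state(truth_hd, r)
  expect_true(all(prof_hd$value <= prof_id$value + 1e-9))
  expect_true(all(diff(prof_hd$value) <= 1e-9)) # monotone out of the trap
})

test_that("coverage physicality cap is reported with a radius", {
  truth <- hd_truth(a_hd = 6, a_hydro0 = 1500, c0 = 800, delta_p = -19.4)
  expect_warning(forward_steady_state(truth), "exceeds the cap")
})

test_that("rendered images are reproducible and unbiased", {
  truth <- hd_truth(seed = 9, image_size = 128L)
  prof <- forward_steady_state(truth)
  i1 <- render_image(prof, truth)
  i2 <- render_image(prof, truth)
  expect_identical(i1$intensity, i2$intensity) # bit-identical at fixed seed
  i3 <- render_image(prof, truth, seed = 10)
  expect_false(identical(i1$intensity, i3$intensity))
  # noiseless render followed by radial averaging returns the input profile
  truth0 <- hd_truth(image_size = 128L,
                     noise = list(counts_per_molecule = 80, background = 0,
                                  read_sd = 0, shot = FALSE))
  p0 <- forward_steady_state(truth0)
  img0 <- render_image(p0, truth0)
  got <- radial_average(img0, list(x = 128 * 0.22 / 2, y = 128 * 0.22 / 2))
  want <- 80 * 0.22^2 * approx(p0$r, p0$value, xout = got$r)$y
  expect_lt(max(abs(got$value / want - 1)), 0.03)
  # with noise on, the seed-averaged profile is unbiased
  dev <- sapply(1:8, function(s) {
    img <- render_image(prof, truth, seed = s)
    g <- radial_average(img, list(x = 128 * 0.22 / 2, y = 128 * 0.22 / 2))
    w <- truth$noise$background + truth$noise$counts_per_molecule *
      approx(prof$r, prof$value, xout = g$r)$y * truth$pixel_size^2
    mean(g$value / w - 1)
  })
  expect_lt(abs(mean(dev)), 0.01)
})

test_that("generation and inference are mutually consistent at zero noise", {
  truth <- hd_truth(a_hd = 3.2, a_hydro0 = 296)
  r <- seq(0.25, 30, by = 0.25)
  prof <- forward_steady_state(truth, r)
  curve <- build_interaction_curve(radial_profile(prof$r, prof$value),
                                   flow_model_epsilon(truth$eps, r),
                                   c0 = truth$c0)
  mu <- mu_from_curve(curve, truth$a_hydro0)
  ref <- mu_excess_hard_disk(coverage_fraction(mu$conc, 3.2), hard_disk_model(3.2)) -
    mu_excess_hard_disk(coverage_fraction(truth$c0, 3.2), hard_disk_model(3.2))
  expect_lt(max(abs(mu$mu_ex - ref)), 0.02) # quadrature error only
})

test_that("scenario presets carry the study geometries", {
  sa <- make_scenario("SA")
  expect_equal(round(sa$a_hydro0), 296)
  cd4 <- make_scenario("CD4")
  expect_equal(round(cd4$a_hydro0), 513)
  cd45 <- make_scenario("CD45-rotating-rod")
  expect_equal(attr(cd45, "scenario")$name, "CD45")
  # the trap-energy peak is of order 1e-4 J/m^2 at the default pressure
  eps <- flow_model_epsilon(sa$eps, seq(0.01, 40, by = 0.05))
  expect_equal(max(eps$epsilon), 1e-4, tolerance = 0.05)
  expect_error(make_scenario("CD99"), "available")
})
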