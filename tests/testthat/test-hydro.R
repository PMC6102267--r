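test_that("hydrodynamic area model reproduces the cylinder limits", {
  # flat disk: bare footprint
  expect_equal(a_hydro_zero(molecule_geometry(2, 0)), pi * 4)
  # strictly increasing in height at fixed radius
  hs <- seq(0, 40, by = 1)
  As <- vapply(hs, function(h) a_hydro_zero(molecule_geometry(1.5, h)), numeric(1))
  expect_true(all(diff(As) > 0))
})

test_that("height inversion round-trips the area model", {
  grid <- expand.grid(a = c(0.8, 1.5, 2.8, 5), h = c(0, 0.5, 5, 11, 22, 40))
  for (i in seq_len(nrow(grid))) {
    A <- a_hydro_zero(molecule_geometry(grid$a[i], grid$h[i]))
    expect_equal(effective_height(A, grid$a[i]), grid$h[i], tolerance = 1e-10)
  }
  expect_equal(effective_height(pi * 2.8^2, 2.8), 0)
  expect_error(effective_height(10, 2.8), "below the bare disk")
})

test_that("drag force is the linear area-stress product", {
  expect_equal(force_from_shear(300, 0), 0)
  # 300 nm^2 at 1 mPa: 3e-19 N
  expect_equal(force_from_shear(300, 1e-3), 3e-19)
  expect_equal(force_from_shear(300, 2e-3), 2 * force_from_shear(300, 1e-3))
})

test_that("trap energy is the outward integral of shear stress", {
  # constant stress on a finite support: epsilon(0) = S * R
  r <- seq(0, 5, by = 0.01)
  S <- 2e-5 # Pa
  expect_warning(ep <- epsilon_from_shear(shear_profile(r, rep(S, length(r)))),
                 "not decayed")
  expect_equal(ep$epsilon[1], S * 5e-6, tolerance = 1e-12)
  expect_equal(ep$epsilon[length(r)], 0)
  # zero stress: zero energy
  ep0 <- epsilon_from_shear(shear_profile(r, rep(0, length(r))))
  expect_true(all(ep0$epsilon == 0))
  # monotone non-increasing for one-signed stress
  fm <- parametric_flow_model()
  eps <- epsilon_from_shear(flow_model_shear(fm, seq(0.01, 40, by = 0.02)))
  expect_true(all(diff(eps$epsilon) <= 1e-15))
})

test_that("trap energy scales linearly with applied pressure", {
  r <- seq(0.01, 40, by = 0.05)
  eref <- flow_model_epsilon(parametric_flow_model(delta_p = -3.0), r)$epsilon
  for (p in c(-9.7, -19.4)) {
    e <- flow_model_epsilon(parametric_flow_model(delta_p = p), r)$epsilon
    expect_equal(e, eref * abs(p) / 3.0, tolerance = 1e-12)
  }
  # numerically integrated stress agrees with the closed form
  eq <- epsilon_from_shear(flow_model_shear(parametric_flow_model(), r))
  ec <- flow_model_epsilon(parametric_flow_model(), r)
  expect_equal(eq$epsilon[1], ec$epsilon[1], tolerance = 2e-3)
})

test_that("quadrature converges under grid refinement", {
  fm <- parametric_flow_model()
  e1 <- epsilon_from_shear(flow_model_shear(fm, seq(0.01, 40, by = 0.04)))$epsilon[1]
  e2 <- epsilon_from_shear(flow_model_shear(fm, seq(0.01, 40, by = 0.02)))$epsilon[1]
  expect_lt(abs(e2 / e1 - 1), 0.005)
})

test_that("flow shielding attenuates the hydrodynamic area physically", {
  sh <- shielding_model(nu = 1)
  expect_equal(a_hydro_of_coverage(300, 0, sh), 300)
  a <- a_hydro_of_coverage(300, 0.3, sh)
  expect_gt(a, 0); expect_lt(a, 300)
  # identity configuration: shielding disabled
  expect_equal(a_hydro_of_coverage(300, 0.3, shielding_model(nu = 0)), 300)
  phis <- seq(0, 0.9, by = 0.05)
  g <- shielding_model(nu = 2)$g(phis)
  expect_true(all(diff(g) <= 0) && all(g > 0) && g[1] == 1)
})
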