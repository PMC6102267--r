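test_that("virial excess chemical potential matches the truncated series", {
  expect_identical(mu_excess_hard_disk(0), 0)
  # direct evaluation of 4*phi + 4.692*phi^2 + 5.6773*phi^3 at phi = 0.1
  expect_equal(mu_excess_hard_disk(0.1), 0.4525973, tolerance = 1e-6)
  # strictly increasing on (0, 0.5]
  phis <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(mu_excess_hard_disk(phis)) > 0))
  # B2-only truncation at low coverage: exact relative deviation is
  # 1.173*phi + 1.419*phi^2, i.e. 6.22% at the phi = 0.05 boundary
  lo <- seq(0.005, 0.05, by = 0.005)
  dev <- abs(mu_excess_hard_disk(lo) / (4 * lo) - 1)
  expect_true(all(dev < 0.063))
  expect_equal(dev, (1.5 * 3.128 / 4) * lo + ((4 / 3) * 4.258 / 4) * lo^2,
               tolerance = 1e-9)
  expect_error(mu_excess_hard_disk(-0.01), "coverage")
  expect_error(mu_excess_hard_disk(1), "coverage")
})

test_that("hard-disk radius fit recovers generating radii", {
  conc <- seq(200, 8000, length.out = 12)
  # noise-free self-consistency at 3.2 nm: machine-level recovery
  mu <- mu_excess_hard_disk(coverage_fraction(conc, 3.2), hard_disk_model(3.2))
  fit <- fit_hard_disk_radius(conc, mu)
  expect_equal(fit$status, "ok")
  expect_equal(fit$a_hd, 3.2, tolerance = 1e-7)
  # parameter recovery under 2% multiplicative noise, 50 replicates
  set.seed(42)
  conc5 <- seq(100, 4000, length.out = 10)
  mu5 <- mu_excess_hard_disk(coverage_fraction(conc5, 5.3), hard_disk_model(5.3))
  a_hat <- replicate(50, {
    fit_hard_disk_radius(conc5, mu5 * (1 + rnorm(10, sd = 0.02)))$a_hd
  })
  expect_true(all(abs(a_hat / 5.3 - 1) < 0.1))
  expect_equal(mean(a_hat), 5.3, tolerance = 0.02)
})

test_that("degenerate radius-fit inputs are flagged, not silently returned", {
  conc <- seq(200, 2000, length.out = 6)
  fit0 <- fit_hard_disk_radius(conc, rep(0, 6))
  expect_equal(fit0$status, "failed")
  expect_true(is.na(fit0$a_hd))
  expect_error(fit_hard_disk_radius(conc[1:3], rep(1, 3)), "at least 4")
})

test_that("glycan area map is anchored, bounded and monotone", {
  expect_equal(glyco_hard_disk_area(1), 1)
  expect_equal(glyco_hard_disk_area(1e6), 9.82, tolerance = 1e-3)
  y33 <- glyco_hard_disk_area(3.3)
  expect_gt(y33, 3.3)
  expect_lt(y33, 9.82)
  # monotone and plateau-bounded on the physical domain: a normalized
  # projected area cannot exceed the protein+sugar disk, a_projected <= 9.82
  xs <- seq(1, 9.82, by = 0.02)
  ys <- glyco_hard_disk_area(xs)
  expect_true(all(diff(ys) >= -1e-12))
  expect_true(all(ys <= 9.82 + 1e-9))
  expect_error(glyco_hard_disk_area(0.9), ">= 1")
})

test_that("glycan coefficients are recovered with the plateau held fixed", {
  xs <- c(1.2, 1.8, 2.6, 3.5, 5, 7)
  ys <- glyco_hard_disk_area(xs) # defaults p1 = 0.66, p2 = 0.95
  fit <- fit_glyco_coefficients(xs, ys)
  expect_equal(attr(fit, "status"), "ok")
  expect_equal(fit$p1, 0.66, tolerance = 1e-5)
  expect_equal(fit$p2, 0.95, tolerance = 1e-5)
  # collinear points pinned at the plateau: ill-conditioned, flagged
  flat <- fit_glyco_coefficients(c(100, 200, 300), rep(9.82, 3))
  expect_equal(attr(flat, "status"), "ill-conditioned")
  expect_error(fit_glyco_coefficients(c(1, 2), c(1, 2)), ">= 3")
})
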