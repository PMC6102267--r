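test_that("two-species model reduces to one species when the other is absent", {
  eps <- flow_model_epsilon(parametric_flow_model(delta_p = -6), seq(0.1, 30, by = 0.2))
  m <- hard_disk_model(3.2)
  two <- two_species_steady_state(list(m, hard_disk_model(8)),
                                  a_hydro0 = c(296, 1536), eps = eps,
                                  c0 = c(300, 0), shield_small = FALSE)
  single <- forward_steady_state(
    ground_truth(m, 296, 300, eps), r = eps$r)
  expect_equal(two$conc1, single$value, tolerance = 1e-4, ignore_attr = TRUE)
  expect_true(all(two$conc2 < 1e-6))
})

test_that("identical species give identical symmetric profiles", {
  eps <- flow_model_epsilon(parametric_flow_model(delta_p = -6), seq(0.1, 30, by = 0.2))
  m <- hard_disk_model(4)
  two <- two_species_steady_state(list(m, m), a_hydro0 = c(400, 400),
                                  eps = eps, c0 = c(200, 200),
                                  shield_small = FALSE)
  expect_equal(two$conc1, two$conc2, tolerance = 1e-8)
})

test_that("profiles relax to baselines where the trap vanishes", {
  eps <- flow_model_epsilon(parametric_flow_model(delta_p = -9.7), seq(0.1, 60, by = 0.2))
  two <- two_species_steady_state(list(hard_disk_model(5.3), hard_disk_model(8)),
                                  a_hydro0 = c(324, 1536), eps = eps,
                                  c0 = c(300, 150))
  n <- nrow(two)
  expect_equal(two$conc1[n], 300, tolerance = 0.02)
  expect_equal(two$conc2[n], 150, tolerance = 0.02)
})

test_that("the smaller species is displaced into a ring around the centre", {
  eps <- flow_model_epsilon(parametric_flow_model(delta_p = -19.4),
                            seq(0.05, 40, by = 0.1))
  two <- two_species_steady_state(list(hard_disk_model(5.3), hard_disk_model(8)),
                                  a_hydro0 = c(324, 1536), eps = eps,
                                  c0 = c(300, 150), shield_small = TRUE)
  i1 <- which.max(two$conc1) # small species: off-centre maximum (ring)
  i2 <- which.max(two$conc2) # large species: peak at the centre
  expect_gt(two$r[i1], two$r[1])
  expect_equal(i2, 1L)
  expect_gt(two$conc1[i1], two$conc1[1])
})
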