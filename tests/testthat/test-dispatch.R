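test_that("config validation rejects unknown fields before any computation", {
  d <- withr::local_tempdir()
  expect_error(read_run_config(list(seed = 1, bogus_field = 2)), "bogus_field")
  expect_error(dispatch("synth", list(seed = 1, out_dir = d, bogus_field = 2)),
               "bogus_field")
  expect_length(list.files(d), 0) # no partial outputs
})

test_that("synth followed by analyze-trap recovers the generating radius", {
  d <- withr::local_tempdir()
  dispatch("synth", list(seed = 4, out_dir = d, scenario = "SA"))
  expect_true(file.exists(file.path(d, "trap-image.tif")))
  expect_true(file.exists(file.path(d, "ground-truth.json")))
  expect_true(file.exists(file.path(d, "resolved-config.json")))
  d2 <- withr::local_tempdir()
  dispatch("analyze-trap",
           list(seed = 4, out_dir = d2,
                image = file.path(d, "trap-image.tif"),
                eps_csv = file.path(d, "trap-energy.csv"),
                calibration = list(c0 = 300, background = 400)))
  rep <- jsonlite::read_json(file.path(d2, "fit-report.json"))
  expect_equal(rep$a_hydro0_nm2, 296, tolerance = 0.08)
  expect_equal(rep$a_hd_nm, 3.2, tolerance = 0.15)
  expect_equal(rep$fit_status, "ok")
})

test_that("mc-sweep runs are seed-consistent within stochastic error", {
  ds <- replicate(2, withr::local_tempdir(.local_envir = parent.frame()))
  curves <- lapply(1:2, function(i)
    read_curve_csv(dispatch("mc-sweep",
      list(seed = i * 41, out_dir = ds[i],
           mc = list(n_spheres = 1, diameter = 0.1, rigid = TRUE,
                     n_steps = 3e4, phi_grid = c(0.06, 0.12))))$curve))
  dmu <- abs(curves[[1]]$mu_ex - curves[[2]]$mu_ex)
  se <- sqrt(curves[[1]]$se^2 + curves[[2]]$se^2)
  expect_true(all(dmu < 4 * se))
})

test_that("two-species command writes both radial profiles", {
  d <- withr::local_tempdir()
  out <- dispatch("two-species", list(seed = 1, out_dir = d))
  prof <- read.csv(out$profiles)
  expect_true(all(c("r", "conc1", "conc2") %in% names(prof)))
  expect_true(all(is.finite(prof$conc1)))
})
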