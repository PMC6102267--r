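#' Read a run configuration
#'
#' Configurations are single YAML (or JSON) documents with per-command
#' parameter blocks, a global seed, and an output directory. Unknown fields
#' are rejected up front with their paths, before any computation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a list.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  known <- c("seed", "out_dir", "verbose", "scenario", "delta_p", "noise",
             "calibration", "eps_csv", "flow_model", "image", "profile_csv",
             "pixel_size", "mc", "fit", "two_species")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    .stopf("unknown config field(s): %s", paste(extra, collapse = ", "))
  structure(cfg, class = c("run_config", "list"))
}

.resolved_config_path <- function(cfg, out_dir, command) {
  resolved <- unclass(cfg)
  resolved$command <- command
  resolved$package_version <- as.character(utils::packageVersion("hydrotrap"))
  resolved$config_hash <- digest_bits(resolved)
  path <- file.path(out_dir, "resolved-config.json")
  jsonlite::write_json(resolved, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  path
}

# cheap stable hash of a config (FNV-1a style rolling hash over the
# serialized bytes); identifies runs without a cryptographic dependency
digest_bits <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a named analysis command from a configuration
#'
#' The reproducible entry point binding the modules together. Supported
#' commands:
#' \describe{
#'   \item{`synth`}{Generate a synthetic trapping dataset from a scenario
#'     preset: TIFF image, ground-truth JSON, profile CSVs.}
#'   \item{`analyze-trap`}{Image (TIFF) or profile CSV to interaction
#'     curve, excess chemical potential and model fits.}
#'   \item{`mc-sweep`}{Coverage sweep of a bead-chain system; writes the
#'     curve CSV, an XYZ snapshot and a run log.}
#'   \item{`fit-models`}{Fit candidate models to a mu_ex curve CSV.}
#'   \item{`two-species`}{Two-species forward model; writes both radial
#'     profiles.}
#' }
#' Every run writes its resolved configuration (with seed, package version
#' and config hash) next to its outputs.
#'
#' @param command Command name.
#' @param config A [read_run_config()] result, config file path, or list.
#' @return Invisibly, a named list of artifact paths.
#' @export
dispatch <- function(command = c("synth", "analyze-trap", "mc-sweep",
                                 "fit-models", "two-species"),
                     config) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list(config = .resolved_config_path(cfg, out_dir, command))
  seed <- as.integer(cfg$seed)

  if (command == "synth") {
    truth <- make_scenario(cfg$scenario %||% "SA",
                           delta_p = cfg$delta_p %||% -9.7, seed = seed)
    if (!is.null(cfg$noise)) truth$noise <- modifyList(truth$noise, cfg$noise)
    prof <- forward_steady_state(truth)
    img <- render_image(prof, truth)
    artifacts$image <- file.path(out_dir, "trap-image.tif")
    write_trap_tiff(img, artifacts$image)
    artifacts$profile <- file.path(out_dir, "concentration-profile.csv")
    write_profile_csv(prof, artifacts$profile)
    artifacts$epsilon <- file.path(out_dir, "trap-energy.csv")
    write_profile_csv(.eps_on_grid(truth$eps, prof$r), artifacts$epsilon)
    artifacts$truth <- file.path(out_dir, "ground-truth.json")
    meta <- attr(truth, "scenario")
    jsonlite::write_json(
      list(scenario = meta, c0 = truth$c0, a_hydro0 = truth$a_hydro0,
           seed = truth$seed, noise = truth$noise,
           pixel_size = truth$pixel_size, image_size = truth$image_size),
      artifacts$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "analyze-trap") {
    eps <- if (!is.null(cfg$eps_csv)) read_profile_csv(cfg$eps_csv, "epsilon")
    else do.call(parametric_flow_model, cfg$flow_model %||% list())
    cal <- do.call(intensity_calibration, cfg$calibration %||% list(c0 = 300))
    if (!is.null(cfg$image)) {
      img <- read_trap_tiff(cfg$image, cfg$pixel_size %||% 0.22)
      ctr <- find_trap_centre(img)
      if (!identical(ctr$status, "ok")) .stopf("no trap found in image")
      prof <- radial_average(img, ctr)
      conc <- intensity_to_concentration(prof, cal)
    } else if (!is.null(cfg$profile_csv)) {
      prof <- read_profile_csv(cfg$profile_csv, "radial")
      conc <- intensity_to_concentration(prof, cal)
    } else .stopf("analyze-trap needs 'image' or 'profile_csv'")
    if (inherits(eps, "parametric_flow_model") || is.null(eps))
      eps <- flow_model_epsilon(if (is.null(eps)) parametric_flow_model() else eps,
                                conc$r)
    curve <- build_interaction_curve(conc, eps)
    fit_cfg <- cfg$fit %||% list()
    a_prov <- fit_cfg$a_provisional %||% 3
    slope <- slope_a_hydro0(curve, a_prov, phi_max = fit_cfg$phi_max %||% 0.05)
    mu <- mu_from_curve(curve, function(c)
      a_hydro_of_coverage(slope$a_hydro0, pmin(coverage_fraction(c, a_prov), 0.999),
                          shielding_model(nu = fit_cfg$shielding_nu %||% 0)))
    hd <- fit_hard_disk_radius(mu$conc, mu$mu_ex, conc0 = attr(curve, "c0"))
    artifacts$curve <- file.path(out_dir, "interaction-curve.csv")
    write_curve_csv(curve, artifacts$curve)
    artifacts$mu <- file.path(out_dir, "mu-ex-curve.csv")
    write_curve_csv(mu, artifacts$mu)
    artifacts$report <- file.path(out_dir, "fit-report.json")
    jsonlite::write_json(
      list(a_hydro0_nm2 = slope$a_hydro0, a_hydro0_se = slope$se,
           slope_status = slope$status, a_hd_nm = hd$a_hd, a_hd_se = hd$se,
           fit_status = hd$status, c0 = attr(curve, "c0"), seed = seed),
      artifacts$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "mc-sweep") {
    mc <- cfg$mc %||% list()
    topo <- if (!is.null(mc$n_sugars))
      do.call(glyco_bead_chain, mc[intersect(names(mc),
        c("n_sugars", "n_protein", "protein_d", "sugar_d", "sugar_spheres"))])
    else bead_rod(mc$n_spheres %||% 3, mc$diameter %||% 0.1)
    restr <- if (isTRUE(mc$rigid)) restraint_spec(rigid = TRUE)
    else restraint_spec(k_f = mc$k_f %||% 0)
    box <- sim_box(mc$box %||% 2, mc$box %||% 2, mc$box_z %||% (mc$box %||% 2))
    cfg_mc <- mc_config(n_steps = mc$n_steps %||% 1e5, seed = seed)
    grid <- mc$phi_grid %||% seq(0.02, 0.3, by = 0.04)
    curve <- sweep_coverage(topo, grid, box, restr, cfg_mc, seed = seed)
    artifacts$curve <- file.path(out_dir, "mc-curve.csv")
    write_curve_csv(curve, artifacts$curve)
    run1 <- run_mc(topo, max(curve$n_mol), box, restr,
                   mc_config(n_steps = 2e4, seed = seed))
    artifacts$snapshot <- file.path(out_dir, "final-state.xyz")
    write_xyz_snapshot(run1, artifacts$snapshot)
    artifacts$log <- file.path(out_dir, "mc-log.json")
    jsonlite::write_json(
      list(seed = seed, acc_trans = run1$acc_trans, acc_rot = run1$acc_rot,
           amp_trans = run1$amp_trans, amp_rot = run1$amp_rot,
           n_points = nrow(curve)),
      artifacts$log, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "fit-models") {
    d <- read_curve_csv(cfg$fit$mu_csv)
    ranking <- fit_interaction_models(d)
    artifacts$report <- file.path(out_dir, "model-ranking.json")
    jsonlite::write_json(
      list(best = ranking$best,
           fits = lapply(ranking$fits, function(f)
             f[c("name", "status", "rss", "a")])),
      artifacts$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "two-species") {
    ts <- cfg$two_species %||% list()
    prof <- two_species_steady_state(
      models = list(hard_disk_model(ts$a1 %||% 5.3), hard_disk_model(ts$a2 %||% 8.0)),
      a_hydro0 = c(ts$A1 %||% 324, ts$A2 %||% 1536),
      eps = parametric_flow_model(delta_p = ts$delta_p %||% -9.7),
      c0 = c(ts$c01 %||% 300, ts$c02 %||% 150))
    artifacts$profiles <- file.path(out_dir, "two-species-profiles.csv")
    write.csv(as.data.frame(prof), artifacts$profiles, row.names = FALSE,
              quote = FALSE)
  }
  invisible(artifacts)
}
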