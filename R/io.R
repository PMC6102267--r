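#' Read and write two-column profile CSVs
#'
#' Profiles (radial intensity/concentration, shear stress, trap energy) are
#' exchanged as comma-separated tables with a header naming the units.
#'
#' @param path File path.
#' @param type One of `"radial"`, `"shear"`, `"epsilon"`: controls the
#'   class and expected columns.
#' @return The corresponding profile object.
#' @export
read_profile_csv <- function(path, type = c("radial", "shear", "epsilon")) {
  type <- match.arg(type)
  d <- read.csv(path, check.names = FALSE)
  if (ncol(d) < 2L) .stopf("profile CSV must have at least two columns")
  switch(type,
         radial = radial_profile(d[[1]], d[[2]],
                                 n = if (ncol(d) >= 3) d[[3]] else rep(1L, nrow(d))),
         shear = shear_profile(d[[1]], d[[2]]),
         epsilon = trap_energy_profile(d[[1]], d[[2]]))
}

#' @rdname read_profile_csv
#' @param profile Profile object to write.
#' @export
write_profile_csv <- function(profile, path) {
  headers <- list(
    radial_profile = c("r_um", "value", "n_pixels"),
    shear_profile = c("r_um", "sigma_Pa"),
    trap_energy_profile = c("r_um", "epsilon_J_per_m2"))
  cls <- intersect(class(profile), names(headers))[1]
  if (is.na(cls)) .stopf("unsupported profile class")
  d <- as.data.frame(profile)
  names(d)[seq_along(headers[[cls]])] <- headers[[cls]][seq_len(ncol(d))]
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a coverage / chemical-potential curve as CSV
#'
#' @param curve An `mc_curve`, `interaction_curve` or `mu_curve` data frame.
#' @param path File path.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) read.csv(path)

#' Serialize a fitted model to JSON
#'
#' Writes coefficients together with their provenance (class, package
#' version, date) so fitted models are self-describing.
#'
#' @param model A `hard_disk_model`, `glyco_area_model`, `hd_fit` or plain
#'   list.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  payload <- list(class = class(model)[1], coefficients = unclass(model),
                  provenance = list(
                    package = "hydrotrap",
                    version = as.character(utils::packageVersion("hydrotrap")),
                    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read and write 16-bit grayscale trap TIFFs
#'
#' Intensities are stored as 16-bit counts (0..65535); values outside that
#' range are clamped on write.
#'
#' @param image A [trap_image()].
#' @param path File path.
#' @param pixel_size Pixel size in um/px to attach on read.
#' @export
write_trap_tiff <- function(image, path) {
  stopifnot(inherits(image, "trap_image"))
  x <- pmin(pmax(image$intensity, 0), 65535) / 65535
  tiff::writeTIFF(x, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_trap_tiff
#' @export
read_trap_tiff <- function(path, pixel_size = 0.22) {
  x <- tiff::readTIFF(path)
  if (is.list(x)) x <- x[[1]]
  if (length(dim(x)) == 3L) x <- x[, , 1]
  trap_image(x * 65535, pixel_size)
}

#' Write an MC snapshot in a plain-text XYZ-like dialect
#'
#' One block: an atom count line, a comment line with the seed and box,
#' then one `label x y z` line per sphere (coordinates in nm; labels are
#' `P` for protein spheres and `S` for sugars).
#'
#' @param run An `mc_run` object (the final configuration is written).
#' @param path File path.
#' @export
write_xyz_snapshot <- function(run, path) {
  stopifnot(inherits(run, "mc_run"))
  topo <- run$topology
  m <- nrow(topo$positions)
  labels <- ifelse(topo$sugar, "S", "P")
  lines <- character(0)
  n_total <- run$n_mol * m
  lines <- c(lines, as.character(n_total),
             sprintf("hydrotrap snapshot seed=%d box=%g,%g,%g nm",
                     run$config$seed, run$box$Lx, run$box$Ly, run$box$Lz))
  if (run$n_mol > 0 && run$n_samples > 0) {
    last <- (run$n_samples - 1L) * run$n_mol + seq_len(run$n_mol)
    for (i in seq_len(run$n_mol)) {
      row <- last[i]
      q <- run$states_q[row, ]
      for (k in seq_len(m)) {
        p <- .quat_rotate(q, topo$positions[k, ])
        lines <- c(lines, sprintf("%s %.6f %.6f %.6f", labels[k],
                                  p[1] + run$states_xy[row, 1],
                                  p[2] + run$states_xy[row, 2], p[3]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.quat_rotate <- function(q, p) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  t <- 2 * c(y * p[3] - z * p[2], z * p[1] - x * p[3], x * p[2] - y * p[1])
  p + w * t + c(y * t[3] - z * t[2], z * t[1] - x * t[3], x * t[2] - y * t[1])
}
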