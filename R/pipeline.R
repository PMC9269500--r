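# End-to-end studies: the three-way range comparison (CSDA vs MC-projected vs
# image-measured) and the tomography round trip (frames -> sinogram -> FBP),
# with seeded reproducibility and a JSON manifest of every run.

.derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)

.write_manifest <- function(out_dir, config, files) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("scintdose")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = config,
    checksums = as.list(tools::md5sum(files))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Three-way electron-range study (CSDA vs MC vs image pipeline)
#'
#' For each beam energy: computes the CSDA range (specific and linear),
#' simulates the electron beam and extracts the practical range from the MC
#' depth-dose curve, renders a synthetic fluorescence photograph of the dose
#' grid, and re-extracts the practical range through the image pipeline
#' (V-cut segmentation, pixel calibration, tangent/background intersection).
#'
#' @param config List with elements `material` ([material]), `energies` (MeV),
#'   `n_histories`, `seed`, `cell_size` (cm), `camera` ([camera_model] or
#'   NULL for the electron-image default), `v_cut`, `tangent_window`,
#'   `out_dir` (NULL = no artifacts written). Missing elements take the
#'   defaults documented here.
#' @return A data frame (class `range_study`) with one row per energy:
#'   `energy_MeV`, `csda_gcm2`, `csda_cm`, `rp_mc_cm`, `rp_image_cm`,
#'   `rp_image_unc_cm`, `zmax_mc_cm`. When `out_dir` is given, all
#'   intermediate artifacts and `manifest.json` are written there (attribute
#'   `manifest`).
#' @export
run_range_study <- function(config = list()) {
  cfg <- utils::modifyList(list(
    material = abls_material(), energies = c(6, 9, 12), n_histories = 1e5,
    seed = 1L, cell_size = 0.05, camera = NULL, v_cut = 0.3,
    tangent_window = NULL, out_dir = NULL), config)
  stopifnot(inherits(cfg$material, "material"), length(cfg$energies) >= 1)
  geom <- geometry_spec(cell_size = cfg$cell_size, material = cfg$material)
  cam <- if (is.null(cfg$camera)) {
    nz <- as.integer(round(geom$depth / cfg$cell_size))
    nb <- max(2L, round(0.02 * nz))
    camera_model(reflection_bands = list(list(rows = c(1L, nb), v = 0.25),
                                         list(rows = c(nz - nb + 1L, nz), v = 0.25)))
  } else cfg$camera
  rows <- list()
  files <- character(0)
  if (!is.null(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE,
                                        showWarnings = FALSE)
  for (k in seq_along(cfg$energies)) {
    en <- cfg$energies[k]
    csda <- csda_range(en, cfg$material)
    csda_cm <- specific_to_linear_range(csda, cfg$material$density)
    beam <- beam_spec("electron", energy = en, n_histories = cfg$n_histories,
                      seed = .derive_seed(cfg$seed, k))
    grid <- simulate_electron_beam(beam, geom)
    pdd_mc <- pdd_from_dose_grid(grid)
    rr_mc <- practical_range(pdd_mc, tangent_window = cfg$tangent_window)
    cam$seed <- .derive_seed(cfg$seed, 100 + k)
    img <- render_fluorescence_image(grid, cam)
    dm <- dose_map_from_image(img, v_cut = cfg$v_cut,
                              calibration = cfg$cell_size)
    rr_im <- practical_range(pdd_from_dose_grid(dm),
                             tangent_window = cfg$tangent_window)
    rows[[k]] <- data.frame(energy_MeV = en, csda_gcm2 = csda,
                            csda_cm = csda_cm, rp_mc_cm = rr_mc$r_p,
                            rp_image_cm = rr_im$r_p,
                            rp_image_unc_cm = rr_im$uncertainty,
                            zmax_mc_cm = rr_mc$z_max)
    if (!is.null(cfg$out_dir)) {
      f1 <- file.path(cfg$out_dir, sprintf("pdd_mc_%gMeV.csv", en))
      f2 <- file.path(cfg$out_dir, sprintf("pdd_image_%gMeV.csv", en))
      f3 <- file.path(cfg$out_dir, sprintf("dose_grid_%gMeV.csv", en))
      write_depth_dose(pdd_mc, f1)
      write_depth_dose(pdd_from_dose_grid(dm), f2)
      write_dose_grid(grid, f3)
      files <- c(files, f1, f2, f3, paste0(f3, ".json"))
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("range_study", "data.frame")
  if (!is.null(cfg$out_dir)) {
    f <- file.path(cfg$out_dir, "range_report.csv")
    utils::write.csv(report, f, row.names = FALSE)
    files <- c(files, f)
    cfg_plain <- cfg
    cfg_plain$material <- cfg$material$name
    cfg_plain$camera <- NULL
    cfg_plain$out_dir <- NULL
    attr(report, "manifest") <- .write_manifest(cfg$out_dir, cfg_plain, files)
  }
  report
}

# normalized RMSE of a reconstruction against the phantom truth, inside the
# inscribed circle, after least-squares amplitude matching
.recon_residual <- function(recon, truth) {
  N <- nrow(truth)
  ctr <- (N + 1) / 2
  xs <- seq_len(N) - ctr
  mask <- outer(xs, xs, function(a, b) a^2 + b^2) <= (0.95 * N / 2)^2
  a <- recon[mask]; b <- truth[mask]
  sqrt(mean((a - b)^2)) / (max(b) - min(b))
}

#' Tomography study: frames to sinogram to reconstruction, 180 vs 360 degrees
#'
#' Renders the rotating T-bar frame stack, assembles the optical-density
#' sinogram, reconstructs with filtered back-projection from the full
#' 360-degree data and from the first half (180 degrees), and reports the
#' normalized RMSE of each against the rasterized phantom truth.
#'
#' @param config List with elements `spec` ([rot_phantom_spec]), `filter`,
#'   `out_dir` (NULL = no artifacts).
#' @return List of class `tomo_study`: `sinogram`, `recon_360`, `recon_180`,
#'   `truth`, `residual_360`, `residual_180`; artifacts and manifest written
#'   when `out_dir` is given.
#' @export
run_tomo_study <- function(config = list()) {
  cfg <- utils::modifyList(list(spec = rot_phantom_spec(), filter = "ramp",
                                out_dir = NULL), config)
  stopifnot(inherits(cfg$spec, "rot_phantom_spec"))
  stack <- render_rotation_frames(cfg$spec)
  sino <- sinogram_from_frames(stack, as_optical_density = TRUE, i0 = 1)
  truth <- phantom_slice_truth(cfg$spec$phantom, size = cfg$spec$width)
  rec360 <- inverse_radon_fbp(sino, filter = cfg$filter)
  half <- sino$angles < 180
  sino180 <- sinogram(sino$intensities[half, , drop = FALSE],
                      sino$angles[half], sino$detector_spacing)
  rec180 <- inverse_radon_fbp(sino180, filter = cfg$filter)
  out <- list(sinogram = sino, recon_360 = rec360, recon_180 = rec180,
              truth = truth,
              residual_360 = .recon_residual(rec360$image, truth),
              residual_180 = .recon_residual(rec180$image, truth))
  class(out) <- "tomo_study"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(cfg$out_dir, "sinogram.csv")
    f2 <- file.path(cfg$out_dir, "recon_360.csv")
    f3 <- file.path(cfg$out_dir, "recon_180.csv")
    utils::write.table(sino$intensities, f1, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(rec360$image, f2, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(rec180$image, f3, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    cfg_plain <- list(filter = cfg$filter,
                      seed = cfg$spec$seed,
                      frames = cfg$spec$n_frames,
                      frames_per_rev = cfg$spec$frames_per_rev,
                      residual_360 = out$residual_360,
                      residual_180 = out$residual_180)
    .write_manifest(cfg$out_dir, cfg_plain, c(f1, f2, f3))
  }
  out
}

#' @export
print.tomo_study <- function(x, ...) {
  cat("<tomo_study> residual (NRMSE vs truth): 360deg",
      signif(x$residual_360, 4), "| 180deg", signif(x$residual_180, 4), "\n")
  invisible(x)
}
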