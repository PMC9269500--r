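# Synthetic-data generators: everything the real experiment would supply.
# A camera model turns a dose grid into a fluorescence photograph (blue
# emission, PSF blur, container-reflection bands, sensor noise, sRGB encoding,
# 8-bit quantization); a rotation-rig model produces frame stacks of the
# T-bar-in-vial phantom with known rotation period; analytic toy depth-dose
# curves provide fixtures with known practical range.

#' Camera model for fluorescence rendering
#'
#' @param emission_color Linear-RGB direction of the scintillation emission
#'   (blue-dominant by default; normalized internally to max 1).
#' @param gain Linear gain applied to the normalized dose (> 0). The brightest
#'   pixel maps to linear value `gain` (clipped at 1).
#' @param psf_sigma Gaussian point-spread sigma in pixels (>= 0).
#' @param noise_sd Gaussian sensor noise sigma on linear values.
#' @param poisson_scale Photon-shot-noise scale (0 = off); linear values are
#'   replaced by `rpois(v * scale) / scale`.
#' @param reflection_bands List of `list(rows = c(from, to), v = level)`;
#'   each band is container glare rendered at encoded V = `level`.
#' @param depth_scale Apparent-depth compression factor emulating refraction
#'   at the container wall (1 = none).
#' @param seed RNG seed used by the render (NULL = leave RNG state alone).
#' @return A `camera_model` object.
#' @export
camera_model <- function(emission_color = c(0.06, 0.18, 1.0), gain = 1,
                         psf_sigma = 1.5, noise_sd = 0.01, poisson_scale = 0,
                         reflection_bands = list(), depth_scale = 1,
                         seed = NULL) {
  stopifnot(gain > 0, psf_sigma >= 0, noise_sd >= 0, poisson_scale >= 0,
            depth_scale > 0, length(emission_color) == 3,
            all(emission_color >= 0), max(emission_color) > 0)
  for (b in reflection_bands)
    stopifnot(length(b$rows) == 2, b$v >= 0, b$v <= 1)
  structure(list(emission_color = emission_color / max(emission_color),
                 gain = gain, psf_sigma = psf_sigma, noise_sd = noise_sd,
                 poisson_scale = poisson_scale,
                 reflection_bands = reflection_bands,
                 depth_scale = depth_scale, seed = seed),
            class = "camera_model")
}

# separable Gaussian blur with edge clamping
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(mm) {           # along rows (dimension 1)
    out <- matrix(0, nrow(mm), ncol(mm))
    n <- nrow(mm)
    for (j in seq_along(k)) {
      off <- j - r - 1
      src <- pmin(pmax(seq_len(n) + off, 1), n)
      out <- out + k[j] * mm[src, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Render a fluorescence photograph from a dose grid
#'
#' Pipeline: normalize dose, apply gain and the apparent-depth compression,
#' map to linear RGB along the emission color, blur with the PSF, add
#' container-reflection bands, add noise, sRGB-encode, quantize to 8 bits.
#'
#' @param dose A `dose_grid` (rows = depth) or a plain nonnegative matrix.
#' @param cam A [camera_model].
#' @return An sRGB-encoded `rgb_image`; rows are depths, columns lateral
#'   position. Attribute `cm_per_px` carries the grid calibration when the
#'   input was a `dose_grid`.
#' @export
render_fluorescence_image <- function(dose, cam = camera_model()) {
  stopifnot(inherits(cam, "camera_model"))
  calib <- NULL
  if (inherits(dose, "dose_grid")) {
    calib <- dose$cell_size
    dose <- dose$deposited
  }
  stopifnot(is.matrix(dose), all(dose >= 0))
  if (!is.null(cam$seed)) set.seed(cam$seed)
  b <- if (max(dose) > 0) dose / max(dose) * cam$gain else dose
  b <- pmin(b, 1)
  if (cam$depth_scale != 1) {
    # apparent row r displays the true depth r / depth_scale
    n <- nrow(b)
    src <- seq_len(n) / cam$depth_scale
    b <- apply(b, 2, function(col)
      stats::approx(seq_len(n), col, xout = src, rule = 1, yleft = 0,
                    yright = 0, ties = "ordered")$y)
    b[is.na(b)] <- 0
  }
  b <- .gauss_blur(b, cam$psf_sigma)
  px <- array(0, c(dim(b), 3))
  for (ch in 1:3) px[, , ch] <- b * cam$emission_color[ch]
  for (band in cam$reflection_bands) {
    rows <- seq(max(1, band$rows[1]), min(nrow(b), band$rows[2]))
    lin <- srgb_decode(band$v)
    for (ch in 1:3)
      px[rows, , ch] <- pmax(px[rows, , ch], lin * cam$emission_color[ch])
  }
  if (cam$poisson_scale > 0)
    px[] <- stats::rpois(length(px), pmin(px, 1) * cam$poisson_scale) /
      cam$poisson_scale
  if (cam$noise_sd > 0)
    px[] <- px + stats::rnorm(length(px), sd = cam$noise_sd)
  px <- pmin(pmax(px, 0), 1)
  px <- srgb_encode(px)
  px <- round(px * 255) / 255
  out <- rgb_image(px, "sRGB")
  if (!is.null(calib)) attr(out, "cm_per_px") <- calib
  out
}

#' Render a photon-style ("gamma") fluorescence image
#'
#' Emulates the photograph of the gamma irradiation: a nearly uniform,
#' exponentially attenuated glow filling the container (encoded V near
#' 0.6-0.7) plus container-reflection bands at V = 0.3 at the top and bottom —
#' the configuration that produces the double-peaked V histogram.
#'
#' @param nz,nx Image size (depth rows x lateral columns).
#' @param mu Effective exponential attenuation along depth, 1/row-units scaled
#'   so the full depth attenuates by `exp(-mu * nz * cell)`.
#' @param cell Physical row size in cm.
#' @param gain Camera gain (default puts the direct emission at V 0.64-0.70).
#' @param band_v Encoded V level of the reflection bands.
#' @param band_frac Fraction of rows covered by each band.
#' @param noise_sd,seed Noise level and RNG seed.
#' @return An sRGB `rgb_image` with attribute `signal_rows` (rows of direct
#'   emission) and `band_rows` (rows of the reflection bands).
#' @export
render_gamma_style_image <- function(nz = 200, nx = 200, mu = 0.02, cell = 0.05,
                                     gain = 0.448, band_v = 0.3,
                                     band_frac = 0.04, margin_frac = 0.08,
                                     noise_sd = 0.005, seed = 7L) {
  # the photograph shows dark margins above/below the container; the glare
  # bands sit in those margins, the direct emission fills the container rows
  nm <- max(2L, round(margin_frac * nz))
  z <- (seq_len(nz - 2L * nm) - 0.5) * cell
  dose <- matrix(0, nz, nx)
  dose[(nm + 1L):(nz - nm), ] <- matrix(rep(exp(-mu * z), nx), ncol = nx)
  nb <- max(1L, round(band_frac * nz))
  b1 <- c(nm - nb + 1L, nm)                 # just above the container
  b2 <- c(nz - nm + 1L, nz - nm + nb)       # just below it
  cam <- camera_model(gain = gain, psf_sigma = 1, noise_sd = noise_sd,
                      reflection_bands = list(
                        list(rows = b1, v = band_v),
                        list(rows = b2, v = band_v)),
                      seed = seed)
  img <- render_fluorescence_image(dose, cam)
  attr(img, "cm_per_px") <- cell
  attr(img, "band_rows") <- c(seq(b1[1], b1[2]), seq(b2[1], b2[2]))
  attr(img, "signal_rows") <- seq(nm + 3L, nz - nm - 2L)
  img
}

# ---- rotation rig -----------------------------------------------------------

#' Rotating-phantom specification
#'
#' @param phantom A [t_bar_phantom].
#' @param frames_per_rev Frames per revolution (the experiment: 50 s at 30 fps
#'   = 1500; desk-scale defaults are smaller).
#' @param n_frames Total frames (>= frames_per_rev; multiple revolutions are
#'   averaged).
#' @param width Frame width in pixels (detector axis).
#' @param height Frame height in pixels.
#' @param baseline_row Row of the hole-centre slice.
#' @param hole_z_radius Vertical half-extent (rows) of the cylindrical holes.
#' @param refraction_strength Even detector-coordinate perturbation (pixels at
#'   the frame edge) emulating refraction through the vial; 0 = ideal.
#' @param noise_sd Gaussian intensity noise on the frames.
#' @param seed RNG seed.
#' @return A `rot_phantom_spec` object.
#' @export
rot_phantom_spec <- function(phantom = t_bar_phantom(), frames_per_rev = 180,
                             n_frames = 360, width = 160, height = 48,
                             baseline_row = 24, hole_z_radius = 5,
                             refraction_strength = 0, noise_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(phantom, "tbar_phantom"), n_frames >= frames_per_rev,
            baseline_row >= 1, baseline_row <= height)
  structure(list(phantom = phantom, frames_per_rev = frames_per_rev,
                 n_frames = n_frames, width = width, height = height,
                 baseline_row = baseline_row, hole_z_radius = hole_z_radius,
                 refraction_strength = refraction_strength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "rot_phantom_spec")
}

# interval [t1, t2] where a*t + b in [-c, c]; returns 2-column matrix
.lin_interval <- function(a, b, c) {
  lo <- ifelse(abs(a) < 1e-12, ifelse(abs(b) <= c, -Inf, Inf), (-c - b) / a)
  hi <- ifelse(abs(a) < 1e-12, ifelse(abs(b) <= c, Inf, -Inf), (c - b) / a)
  cbind(pmin(lo, hi), pmax(lo, hi))
}

# analytic optical-density projection of the rotated phantom at scanner angle
# theta (degrees): line integrals of mu along rays x = s (normalized units).
.phantom_projection <- function(spec, theta, s) {
  ph <- spec
  th <- -theta * pi / 180                   # object counter-rotates vs scanner
  rot <- function(p) c(cos(th) * p[1] - sin(th) * p[2],
                       sin(th) * p[1] + cos(th) * p[2])
  od <- numeric(length(s))
  chord <- function(cx, r) {
    d2 <- r^2 - (s - cx)^2
    2 * sqrt(pmax(d2, 0))
  }
  # vial glass annulus + interior liquid (centred on the rotation axis)
  od <- od + ph$mu$glass * (chord(0, ph$vial_radius) -
                              chord(0, ph$vial_radius - ph$vial_wall))
  inner <- chord(0, ph$vial_radius - ph$vial_wall)
  bc <- rot(ph$bar_center)
  bar <- chord(bc[1], ph$bar_radius)
  od <- od + ph$mu$liquid * pmax(inner - bar, 0) + ph$mu$bar * bar
  # holes: rectangles across the bar; intersect each ray interval with the bar
  bar_half <- sqrt(pmax(ph$bar_radius^2 - (s - bc[1])^2, 0))
  t_bar <- cbind(bc[2] - bar_half, bc[2] + bar_half)
  for (h in spec$holes_active) {
    phih <- (h$angle) * pi / 180 + th
    ca <- cos(phih); sa <- sin(phih)
    # u along the hole, v across; ray points are (s, t)
    bu <- (s - bc[1]) * ca - bc[2] * sa
    au <- sa
    bv <- -(s - bc[1]) * sa - bc[2] * ca
    av <- ca
    iu <- .lin_interval(rep(au, length(s)), bu, ph$bar_radius)
    iv <- .lin_interval(rep(av, length(s)), bv, h$half_width_now)
    t1 <- pmax(iu[, 1], iv[, 1], t_bar[, 1])
    t2 <- pmin(iu[, 2], iv[, 2], t_bar[, 2])
    od <- od - (ph$mu$bar - ph$mu$hole) * pmax(t2 - t1, 0)
  }
  od
}

#' Render a rotating-phantom frame stack
#'
#' For each frame the phantom is rotated by the frame angle and parallel line
#' integrals of attenuation are computed analytically per image column; frame
#' intensity is the transmitted light `exp(-integral)`. Rows away from the
#' hole centre show the bar without (or with narrowed) holes, producing the
#' T-bar appearance. An optional even detector-coordinate perturbation
#' emulates refraction through the vial and is reduced by 360-degree sampling.
#'
#' @param spec A [rot_phantom_spec].
#' @return A [frame_stack]; field `od_scale` holds the normalized-to-pixel
#'   length factor (`width/2`) used when converting to optical density.
#' @export
render_rotation_frames <- function(spec) {
  stopifnot(inherits(spec, "rot_phantom_spec"))
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height; N <- spec$n_frames
  s <- (seq_len(W) - (W + 1) / 2) / (W / 2)    # normalized detector coords
  frames <- array(0, c(H, W, N))
  # vertical structure: which rows see the vial, and the hole half-width/row
  vial_rows <- seq_len(H)
  hz <- spec$hole_z_radius
  for (f in seq_len(N)) {
    theta <- ((f - 1L) %% spec$frames_per_rev) * 360 / spec$frames_per_rev
    sp <- spec$phantom
    for (r in vial_rows) {
      dz <- abs(r - spec$baseline_row)
      holes <- list()
      if (dz < hz) {
        shrink <- sqrt(1 - (dz / hz)^2)
        holes <- lapply(sp$holes, function(h)
          list(angle = h$angle, half_width_now = h$width / 2 * shrink))
      }
      spr <- sp
      spr$holes_active <- holes
      od <- .phantom_projection(spr, theta, s)
      frames[r, , f] <- exp(-od)
    }
    if (spec$refraction_strength != 0) {
      shift <- spec$refraction_strength * s^2          # even in s (pixels)
      xout <- seq_len(W) + shift
      for (r in vial_rows)
        frames[r, , f] <- stats::approx(seq_len(W), frames[r, , f],
                                        xout = xout, rule = 2,
                                        ties = "ordered")$y
    }
  }
  if (spec$noise_sd > 0)
    frames <- frames + array(stats::rnorm(length(frames), sd = spec$noise_sd),
                             dim(frames))
  frames <- pmin(pmax(frames, 0), 1.5)
  fs <- frame_stack(frames, spec$frames_per_rev, spec$baseline_row)
  fs$od_scale <- W / 2
  fs
}

# ---- toy curves -------------------------------------------------------------

#' Analytic toy depth-dose curves with known practical range
#'
#' `"trapezoid"`: 100% plateau to `plateau_end`, linear fall of `fall_slope`
#' %/cm down to the `background` level, then a flat tail; the true practical
#' range is `plateau_end + (100 - background)/fall_slope`.
#' `"gaussian_falloff"`: 100% plateau followed by a Gaussian distal edge.
#'
#' @param shape Curve family.
#' @param plateau_end Depth where the falloff starts, cm.
#' @param fall_slope Distal slope magnitude, %/cm (trapezoid).
#' @param background Flat tail level, % (trapezoid).
#' @param sigma Distal-edge sigma, cm (gaussian_falloff).
#' @param depth_max,cell Grid extent and spacing, cm.
#' @param noise_sd Gaussian noise added to the dose values, % points.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A [depth_dose_curve] with attribute `true_rp` (trapezoid only).
#' @export
make_toy_pdd <- function(shape = c("trapezoid", "gaussian_falloff"),
                         plateau_end = 3, fall_slope = 98, background = 2,
                         sigma = 0.4, depth_max = 6, cell = 0.02,
                         noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  z <- seq(cell / 2, depth_max, by = cell)
  dose <- switch(shape,
                 trapezoid = pmax(pmin(100, 100 - fall_slope * (z - plateau_end)),
                                  background),
                 gaussian_falloff = ifelse(z <= plateau_end, 100,
                                           100 * exp(-(z - plateau_end)^2 / (2 * sigma^2))))
  if (noise_sd > 0) {
    set.seed(seed)
    dose <- pmax(dose + stats::rnorm(length(dose), sd = noise_sd), 0)
  }
  out <- depth_dose_curve(z, dose, provenance = "synthetic")
  if (shape == "trapezoid")
    attr(out, "true_rp") <- plateau_end + (100 - background) / fall_slope
  out
}
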