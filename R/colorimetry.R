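# Colorimetric decomposition of fluorescence photographs: sRGB transfer
# functions, CIE XYZ / normalized xyz chromaticity, the hexcone HSV model,
# V histograms and V-cut segmentation, and the relative dose map extracted
# from an image.
#
# HSV is computed on gamma-encoded channel values by default, matching common
# image-processing practice (and the published V-cut levels); dose amplitude
# recovery linearizes first, because fluorescence intensity is proportional to
# dose in linear light, not in the camera's gamma-encoded values.

# sRGB <-> CIE XYZ (D65), IEC 61966-2-1
.RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                     0.2126729, 0.7151522, 0.0721750,
                     0.0193339, 0.1191920, 0.9503041),
                   nrow = 3, byrow = TRUE)

#' Construct an RGB image object
#'
#' @param pixels `H x W x 3` array with values in `[0, 1]`.
#' @param colorspace `"sRGB"` (gamma-encoded, as decoded from 8-bit camera
#'   files) or `"linear"`.
#' @return An `rgb_image` (the array with a `colorspace` attribute).
#' @export
rgb_image <- function(pixels, colorspace = c("sRGB", "linear")) {
  colorspace <- match.arg(colorspace)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  structure(pixels, colorspace = colorspace, class = "rgb_image")
}

.img_space <- function(img) attr(img, "colorspace")

#' sRGB electro-optical transfer (decode to linear light)
#'
#' @param img An `rgb_image` tagged `"sRGB"` (a bare numeric array/vector is
#'   decoded as-is).
#' @return Linear-light `rgb_image` (or numeric of the same shape).
#' @export
srgb_decode <- function(img) {
  is_img <- inherits(img, "rgb_image")
  if (is_img && .img_space(img) == "linear") {
    warning("image already linear; returning unchanged", call. = FALSE)
    return(img)
  }
  u <- unclass(img)
  v <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  attributes(v) <- attributes(u)
  if (is_img) rgb_image(v, "linear") else v
}

#' sRGB opto-electronic transfer (encode linear light)
#'
#' @param img Linear-light `rgb_image` or numeric values in `[0, 1]`.
#' @return Gamma-encoded `rgb_image` (or numeric).
#' @export
srgb_encode <- function(img) {
  is_img <- inherits(img, "rgb_image")
  if (is_img && .img_space(img) == "sRGB") {
    warning("image already sRGB-encoded; returning unchanged", call. = FALSE)
    return(img)
  }
  u <- unclass(img)
  v <- ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
  attributes(v) <- attributes(u)
  if (is_img) rgb_image(v, "sRGB") else v
}

#' CIE XYZ decomposition (with normalized xyz chromaticity)
#'
#' Per-pixel multiplication by the sRGB/D65 matrix. Chromaticity planes are
#' defined as 0 where X + Y + Z = 0.
#'
#' @param img A linear-light `rgb_image` (decode sRGB input first with
#'   [srgb_decode()]).
#' @return An `xyz_decomposition`: list of `H x W` planes `X, Y, Z, x, y, z`.
#' @export
rgb_to_xyz <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  if (.img_space(img) != "linear")
    stop("rgb_to_xyz expects linear RGB; apply srgb_decode() first", call. = FALSE)
  d <- dim(img)
  m <- matrix(unclass(img), ncol = 3)            # pixels x 3
  xyz <- m %*% t(.RGB2XYZ)
  s <- rowSums(xyz)
  chrom <- xyz / ifelse(s > 0, s, 1)
  chrom[s <= 0, ] <- 0
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(X = shape(xyz[, 1]), Y = shape(xyz[, 2]), Z = shape(xyz[, 3]),
                 x = shape(chrom[, 1]), y = shape(chrom[, 2]),
                 z = shape(chrom[, 3])),
            class = "xyz_decomposition")
}

#' Hexcone HSV decomposition
#'
#' `V = max(R,G,B)`, `S = (max - min)/max` (0 where max = 0), H by the sextant
#' rule in degrees `[0, 360)`; H is set to 0 where S = 0 by convention. By
#' default operates on the values as stored (gamma-encoded for camera input,
#' matching the published V-cut levels); set `linearize = TRUE` for
#' linear-light HSV.
#'
#' @param img An `rgb_image`.
#' @param linearize Decode sRGB to linear light first.
#' @return An `hsv_image`: list of `H x W` planes `H` (degrees), `S`, `V`.
#' @export
rgb_to_hsv_image <- function(img, linearize = FALSE) {
  stopifnot(inherits(img, "rgb_image"))
  if (linearize && .img_space(img) == "sRGB") img <- srgb_decode(img)
  d <- dim(img)
  r <- matrix(unclass(img)[, , 1], d[1], d[2])
  g <- matrix(unclass(img)[, , 2], d[1], d[2])
  b <- matrix(unclass(img)[, , 3], d[1], d[2])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  c_ <- mx - mn
  S <- ifelse(mx > 0, c_ / mx, 0)
  H <- matrix(0, d[1], d[2])
  nz <- c_ > 0
  hr <- nz & mx == r
  hg <- nz & mx == g & !hr
  hb <- nz & mx == b & !hr & !hg
  H[hr] <- 60 * (((g - b)[hr] / c_[hr]) %% 6)
  H[hg] <- 60 * ((b - r)[hg] / c_[hg] + 2)
  H[hb] <- 60 * ((r - g)[hb] / c_[hb] + 4)
  H <- H %% 360
  structure(list(H = H, S = S, V = mx), class = "hsv_image")
}

#' Invert an HSV decomposition back to RGB
#'
#' @param hsv An `hsv_image`.
#' @param colorspace Colorspace tag for the reconstructed image.
#' @return An `rgb_image`.
#' @export
hsv_to_rgb_image <- function(hsv, colorspace = "sRGB") {
  stopifnot(inherits(hsv, "hsv_image"))
  H <- hsv$H; S <- hsv$S; V <- hsv$V
  c_ <- V * S
  hp <- H / 60
  xcomp <- c_ * (1 - abs(hp %% 2 - 1))
  m <- V - c_
  r <- g <- b <- array(0, dim(as.matrix(H)))
  sext <- floor(hp) %% 6
  r <- ifelse(sext %in% c(0, 5), c_, ifelse(sext %in% c(1, 4), xcomp, 0))
  g <- ifelse(sext %in% c(1, 2), c_, ifelse(sext %in% c(0, 3), xcomp, 0))
  b <- ifelse(sext %in% c(3, 4), c_, ifelse(sext %in% c(2, 5), xcomp, 0))
  px <- array(0, c(dim(as.matrix(H)), 3))
  px[, , 1] <- r + m; px[, , 2] <- g + m; px[, , 3] <- b + m
  rgb_image(px, colorspace)
}

#' Histogram of the V (value) channel
#'
#' @param hsv An `hsv_image`.
#' @param n_bins Number of equal bins over `[0, 1]` (>= 2).
#' @return Data frame with `bin_mid`, `count`; counts sum to the pixel count.
#' @export
v_histogram <- function(hsv, n_bins = 100) {
  stopifnot(inherits(hsv, "hsv_image"), n_bins >= 2)
  br <- seq(0, 1, length.out = n_bins + 1)
  v <- pmin(pmax(as.numeric(hsv$V), 0), 1)
  idx <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), n_bins)
  data.frame(bin_mid = (br[-1] + br[-(n_bins + 1)]) / 2,
             count = tabulate(idx, n_bins))
}

#' V-threshold segmentation
#'
#' Keeps pixels with `V >= v_cut` (the published cuts are 0.3 for electron
#' images and 0.6 for photon images).
#'
#' @param hsv An `hsv_image`.
#' @param v_cut Threshold in `[0, 1]`.
#' @return A `v_mask`: list with `v_cut`, logical `mask`, and `masked_V`
#'   (V on kept pixels, 0 elsewhere).
#' @export
v_threshold <- function(hsv, v_cut) {
  stopifnot(inherits(hsv, "hsv_image"), v_cut >= 0, v_cut <= 1)
  mask <- hsv$V >= v_cut
  structure(list(v_cut = v_cut, mask = mask,
                 masked_V = ifelse(mask, hsv$V, 0)),
            class = "v_mask")
}

#' Relative 2D dose map from a fluorescence photograph
#'
#' Applies the V-cut on the (gamma-encoded) V channel to separate fluorescence
#' from reflections, then recovers the dose amplitude on the kept pixels —
#' in linear light by default (`linear_dose = TRUE`), since emission intensity
#' is proportional to dose before the camera's gamma encoding — and rescales
#' the maximum to 100%. Image rows are depths (beam entering at the top).
#'
#' @param img An `rgb_image` (sRGB-encoded camera output).
#' @param v_cut V threshold (default 0.3, the electron-image cut).
#' @param calibration Physical size of one pixel, cm/pixel (> 0).
#' @param linear_dose Recover amplitude in linear light (default) or use the
#'   encoded V directly.
#' @return A relative `dose_grid` (arbitrary units, max 100; no energy
#'   accounting).
#' @export
dose_map_from_image <- function(img, v_cut = 0.3, calibration, linear_dose = TRUE) {
  stopifnot(inherits(img, "rgb_image"), calibration > 0)
  hsv <- rgb_to_hsv_image(img)
  vm <- v_threshold(hsv, v_cut)
  if (!any(vm$mask)) stop("empty mask: no pixels at or above v_cut", call. = FALSE)
  amp <- if (linear_dose) {
    lin <- unclass(if (.img_space(img) == "sRGB") srgb_decode(img) else img)
    pmax(lin[, , 1], lin[, , 2], lin[, , 3])
  } else hsv$V
  dose <- ifelse(vm$mask, amp, 0)
  dose <- dose / max(dose) * 100
  structure(list(deposited = dose, cell_size = calibration, beam = NULL,
                 geometry = NULL, escaped_energy = NA_real_, relative = TRUE),
            class = "dose_grid")
}
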