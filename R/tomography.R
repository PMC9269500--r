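# Optical tomography of a rotating sample: sinogram assembly from frame
# stacks, the forward Radon transform, and filtered back-projection.
#
# Conventions: angle 0 at the first frame, counter-clockwise positive; the
# detector axis is the image column axis centred on the rotation axis.
# Projection at angle theta integrates the slice along rays
# (x, y) = (s cos(theta) - t sin(theta), s sin(theta) + t cos(theta)).

#' Construct a frame stack
#'
#' @param frames `H x W x N` numeric array of grayscale intensities, or a list
#'   of `H x W` matrices (RGB frames may be supplied as `H x W x 3` matrices in
#'   a list and are converted to luma).
#' @param rotation_period Frames per revolution.
#' @param baseline_row Pixel row used as the sinogram baseline.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, rotation_period, baseline_row) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("frames of mixed size", call. = FALSE)
    frames <- lapply(frames, function(f) {
      if (length(dim(f)) == 3)
        0.2126 * f[, , 1] + 0.7152 * f[, , 2] + 0.0722 * f[, , 3]
      else f
    })
    frames <- array(unlist(frames), c(dim(frames[[1]])[1:2], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (n < rotation_period) stop("need at least one full revolution of frames", call. = FALSE)
  if (baseline_row < 1 || baseline_row > dim(frames)[1])
    stop("baseline_row outside the image", call. = FALSE)
  structure(list(frames = frames, rotation_period = rotation_period,
                 baseline_row = as.integer(baseline_row)),
            class = "frame_stack")
}

#' Sinogram from a rotating-sample frame stack
#'
#' Extracts `baseline_row` from every frame; the frame angle is
#' `(i mod rotation_period) * 360 / rotation_period` and multiple revolutions
#' are averaged per angle. Optionally converts transmitted intensity to
#' optical density `-log(I / I0)` so that filtered back-projection
#' reconstructs attenuation.
#'
#' @param stack A [frame_stack].
#' @param as_optical_density Convert intensities to `-log(I/I0)`.
#' @param i0 Reference intensity for the conversion (default: the stack
#'   maximum).
#' @return A `sinogram`: `intensities` (n_angles x n_detector), `angles`
#'   (degrees, strictly increasing), `detector_spacing` (pixel units).
#' @export
sinogram_from_frames <- function(stack, as_optical_density = FALSE, i0 = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  P <- stack$rotation_period
  n <- dim(stack$frames)[3]
  rows <- t(stack$frames[stack$baseline_row, , ])   # frames x detector
  idx <- (seq_len(n) - 1L) %% P
  acc <- rowsum(rows, idx)
  cnt <- as.numeric(table(factor(idx, levels = sort(unique(idx)))))
  sino <- acc / cnt
  angles <- sort(unique(idx)) * 360 / P
  if (as_optical_density) {
    if (is.null(i0)) i0 <- max(stack$frames)
    sino <- -log(pmax(sino, 1e-12) / i0)
    # generated stacks carry the normalized-to-pixel length factor so the
    # optical-density sinogram is in pixel units, comparable to forward_radon
    if (!is.null(stack$od_scale)) sino <- sino * stack$od_scale
  }
  structure(list(intensities = sino, angles = angles, detector_spacing = 1),
            class = "sinogram")
}

#' Sinogram constructor (for synthetic or precomputed data)
#'
#' @param intensities n_angles x n_detector matrix of finite values.
#' @param angles Strictly increasing angles in degrees.
#' @param detector_spacing Detector bin size (pixel or cm).
#' @return A `sinogram` object.
#' @export
sinogram <- function(intensities, angles, detector_spacing = 1) {
  stopifnot(is.matrix(intensities), nrow(intensities) == length(angles),
            all(is.finite(intensities)), all(diff(angles) > 0))
  structure(list(intensities = intensities, angles = angles,
                 detector_spacing = detector_spacing), class = "sinogram")
}

# bilinear sample of image at continuous (row, col); zero outside
.bilinear <- function(img, rr, cc) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  val <- numeric(length(rr))
  get <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  val <- get(r0, c0) * (1 - fr) * (1 - fc) +
    get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc +
    get(r0 + 1, c0 + 1) * fr * fc
  val
}

#' Forward Radon transform (parallel beam)
#'
#' Line integrals over parallel rays per angle, with bilinear interpolation of
#' the image; the detector has one bin per image column, centred on the image
#' centre.
#'
#' @param image Square numeric matrix.
#' @param angles Projection angles in degrees.
#' @return A `sinogram` (detector spacing 1 pixel).
#' @export
forward_radon <- function(image, angles) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  N <- nrow(image)
  ctr <- (N + 1) / 2
  s <- seq_len(N) - ctr
  t <- seq_len(N) - ctr
  sg <- matrix(0, length(angles), N)
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    # x = s cos - t sin ; y = s sin + t cos  (x: columns, y: rows)
    ss <- rep(s, each = N); tt <- rep(t, times = N)
    cc <- ss * cos(th) - tt * sin(th) + ctr
    rr <- ss * sin(th) + tt * cos(th) + ctr
    v <- .bilinear(image, rr, cc)
    sg[a, ] <- colSums(matrix(v, N, N))
  }
  sinogram(sg, angles)
}

.fbp_filter <- function(nfft, name) {
  # frequency axis in cycles/sample for an even-length FFT
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) / nfft
  ramp <- abs(f)
  switch(name,
         ramp = ramp,
         "shepp-logan" = ramp * ifelse(f == 0, 1, sin(pi * f) / (pi * f)),
         hann = ramp * (0.5 + 0.5 * cos(2 * pi * f)),
         none = rep(1 / 2, nfft),   # plain back-projection (scaled)
         stop("unknown filter: ", name, call. = FALSE))
}

#' Filtered back-projection (inverse Radon transform)
#'
#' Frequency-domain filtering of each projection followed by back-projection
#' with linear interpolation. Requires angular coverage of at least 180
#' degrees; 360-degree sinograms are used directly (opposing views are
#' averaged by the back-projection sum). The reconstruction is masked to the
#' inscribed circle.
#'
#' @param sino A `sinogram`.
#' @param filter `"ramp"` (Ram-Lak, default), `"shepp-logan"`, `"hann"` or
#'   `"none"` (unfiltered back-projection).
#' @param output_size Side of the square reconstruction (default: detector
#'   length).
#' @return A `reconstructed_slice`: `image`, `pixel_size`, `filter_name`.
#' @export
inverse_radon_fbp <- function(sino, filter = c("ramp", "shepp-logan", "hann", "none"),
                              output_size = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  filter <- match.arg(filter)
  ang <- sino$angles
  if (length(ang) < 2) stop("need at least 2 angles", call. = FALSE)
  dth <- stats::median(diff(ang))
  span <- max(ang) - min(ang) + dth
  if (span < 180 - 1e-6)
    stop("insufficient angular coverage: span ", round(span, 2),
         " degrees < 180", call. = FALSE)
  P <- sino$intensities
  nd <- ncol(P)
  if (is.null(output_size)) output_size <- nd
  nfft <- 2^ceiling(log2(2 * nd))
  H <- .fbp_filter(nfft, filter)
  Ppad <- cbind(P, matrix(0, nrow(P), nfft - nd))
  Pf <- t(apply(Ppad, 1, function(row) Re(stats::fft(stats::fft(row) * H,
                                                     inverse = TRUE)) / nfft))
  Pf <- Pf[, seq_len(nd), drop = FALSE]

  N <- output_size
  ctr_out <- (N + 1) / 2
  ctr_det <- (nd + 1) / 2
  xs <- (seq_len(N) - ctr_out) * nd / N
  img <- matrix(0, N, N)
  X <- matrix(rep(xs, each = N), N, N)     # column offsets (x)
  Y <- matrix(rep(xs, times = N), N, N)    # row offsets (y)
  for (a in seq_along(ang)) {
    th <- ang[a] * pi / 180
    sdet <- X * cos(th) + Y * sin(th) + ctr_det
    i0 <- floor(sdet)
    fr <- sdet - i0
    ok0 <- i0 >= 1 & i0 <= nd
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= nd
    v <- matrix(0, N, N)
    row <- Pf[a, ]
    v[ok0] <- row[i0[ok0]] * (1 - fr[ok0])
    v[ok1] <- v[ok1] + row[i0[ok1] + 1] * fr[ok1]
    img <- img + v
  }
  # Delta-theta * sum approximates the 0..pi integral; full-circle data
  # double-covers it and the factor 2 cancels, so pi/n_angles in both cases.
  img <- img * pi / length(ang)
  mask <- (X^2 + Y^2) <= (nd / 2)^2
  img[!mask] <- 0
  structure(list(image = img, pixel_size = sino$detector_spacing * nd / N,
                 filter_name = filter), class = "reconstructed_slice")
}

# ---- phantom ----------------------------------------------------------------

#' T-bar phantom geometry
#'
#' A glass vial (annulus) filled with scintillator, containing a cylindrical
#' bar crossed by horizontal cylindrical holes — the slice through a hole
#' centre shows the bar disk with a low-attenuation rectangle across it.
#' Lengths are in units of the slice half-width (the rendered image maps
#' `[-1, 1]` across).
#'
#' @param vial_radius,vial_wall Outer radius and wall thickness of the vial.
#' @param bar_radius Radius of the bar cross-section.
#' @param bar_center `c(x, y)` centre of the bar.
#' @param holes List of hole specs, each `list(width=, angle=)`: a rectangle of
#'   the given width spanning the bar along direction `angle` (degrees).
#' @param mu Attenuation levels: `glass`, `liquid`, `bar`, `hole`.
#' @return A `tbar_phantom` specification object.
#' @export
t_bar_phantom <- function(vial_radius = 0.92, vial_wall = 0.06,
                          bar_radius = 0.42, bar_center = c(0.08, 0),
                          holes = list(list(width = 0.12, angle = 0)),
                          mu = list(glass = 0.8, liquid = 0.25, bar = 1.0,
                                    hole = 0.15)) {
  stopifnot(vial_radius > 0, bar_radius > 0, vial_wall >= 0)
  if (sqrt(sum(bar_center^2)) + bar_radius > vial_radius - vial_wall + 1e-9)
    stop("bar must lie inside the vial", call. = FALSE)
  for (h in holes)
    if (h$width > 2 * bar_radius) stop("hole wider than the bar", call. = FALSE)
  structure(list(vial_radius = vial_radius, vial_wall = vial_wall,
                 bar_radius = bar_radius, bar_center = bar_center,
                 holes = holes, mu = mu),
            class = "tbar_phantom")
}

#' Ground-truth attenuation image of a phantom slice
#'
#' Rasterizes the phantom on a square pixel grid (point-in-shape tests), for
#' quantitative comparison with reconstructions. `NULL` input gives a zero
#' image.
#'
#' @param spec A [t_bar_phantom] (or `NULL`).
#' @param size Image side in pixels.
#' @return `size x size` matrix of attenuation values.
#' @export
phantom_slice_truth <- function(spec, size = 160) {
  img <- matrix(0, size, size)
  if (is.null(spec)) return(img)
  stopifnot(inherits(spec, "tbar_phantom"))
  ctr <- (size + 1) / 2
  xs <- (seq_len(size) - ctr) / (size / 2)
  X <- matrix(rep(xs, each = size), size, size)   # x: columns
  Y <- matrix(rep(xs, times = size), size, size)  # y: rows
  r2 <- X^2 + Y^2
  img[r2 <= spec$vial_radius^2] <- spec$mu$glass
  inner <- r2 <= (spec$vial_radius - spec$vial_wall)^2
  img[inner] <- spec$mu$liquid
  bx <- X - spec$bar_center[1]; by <- Y - spec$bar_center[2]
  inbar <- bx^2 + by^2 <= spec$bar_radius^2
  img[inbar] <- spec$mu$bar
  for (h in spec$holes) {
    th <- h$angle * pi / 180
    u <- bx * cos(th) + by * sin(th)      # along the hole
    v <- -bx * sin(th) + by * cos(th)     # across the hole
    inhole <- inbar & abs(v) <= h$width / 2 & abs(u) <= spec$bar_radius
    img[inhole] <- max(spec$mu$hole, 0)   # negative shapes clip at 0
  }
  img
}
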