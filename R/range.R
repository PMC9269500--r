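# Depth-dose curves and practical-range extraction.
#
# The practical range Rp is the depth at which the tangent through the
# steepest point of the distal falloff meets the horizontal bremsstrahlung
# background — the standard clinical construction for electron-beam ranges.

#' Construct a depth-dose curve
#'
#' Dose is stored in relative percent with the maximum normalized to 100.
#'
#' @param depth Strictly increasing depth grid in cm.
#' @param dose Dose values (any nonnegative scale; normalized to max = 100).
#' @param provenance `"mc"`, `"image"` or `"synthetic"`.
#' @return A data frame of class `depth_dose` with columns `depth`, `dose`.
#' @export
depth_dose_curve <- function(depth, dose, provenance = c("synthetic", "mc", "image")) {
  provenance <- match.arg(provenance)
  stopifnot(length(depth) == length(dose), length(depth) >= 3)
  if (any(diff(depth) <= 0)) stop("depth grid must be strictly increasing", call. = FALSE)
  if (max(dose) <= 0) stop("curve has no dose", call. = FALSE)
  out <- data.frame(depth = depth, dose = dose / max(dose) * 100)
  attr(out, "provenance") <- provenance
  class(out) <- c("depth_dose", "data.frame")
  out
}

.moving_average3 <- function(v) {
  sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}

.rp_once <- function(depth, dose, sm, imax, ist, window, background) {
  # index-based window: robust to float ties and exactly equivariant under
  # uniform depth rescaling
  half <- max(1L, round(window / 2 / stats::median(diff(depth))))
  sel <- max(imax, ist - half):min(length(depth), ist + half)
  if (length(sel) < 2) sel <- max(ist - 1, 1):min(ist + 1, length(depth))
  fit <- stats::lm.fit(cbind(1, depth[sel]), dose[sel])
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] >= 0)
    return(list(rp = NA_real_, slope = NA_real_))
  list(rp = unname((background - b[1]) / b[2]), slope = unname(b[2]))
}

#' Practical range, R50 and depth of maximum from a depth-dose curve
#'
#' Finds the steepest-descent point of the distal falloff on a lightly
#' smoothed curve (moving average, window 3 cells), fits a tangent line to the
#' unsmoothed data over `tangent_window` centred there, fits a constant
#' background over the distal `tail_window`, and intersects the two.
#'
#' @param curve A [depth_dose_curve].
#' @param tangent_window Width (cm) of the tangent fit window; default 20% of
#'   the falloff extent (measured from the 80% to the 20% distal crossings).
#' @param tail_window Length (cm) of the distal tail over which the background
#'   is averaged; default 10% of the grid.
#' @return A `range_result` list: `r_p`, `r_50`, `z_max` (cm), `tangent`
#'   (slope %/cm and anchor), `background` (%), `uncertainty` (cm; half-range
#'   of the Rp shift when the tangent window is varied +/-50%).
#' @export
practical_range <- function(curve, tangent_window = NULL, tail_window = NULL) {
  stopifnot(inherits(curve, "depth_dose"))
  depth <- curve$depth; dose <- curve$dose
  n <- length(depth)
  sm <- .moving_average3(dose)
  imax <- which.max(sm)
  post <- seq_len(n) > imax
  if (!any(post & sm < max(sm) * 0.5))
    stop("no finite range: curve lacks a distal falloff within the grid", call. = FALSE)

  # background over the distal tail
  if (is.null(tail_window)) tail_window <- 0.1 * (depth[n] - depth[1])
  tail_sel <- depth >= depth[n] - tail_window
  if (sum(tail_sel) < 1) tail_sel[n] <- TRUE
  background <- mean(dose[tail_sel])

  # steepest descent on the smoothed distal edge (ignore the sub-2% tail)
  iend <- which(post & sm < max(2, background))[1]
  if (is.na(iend)) iend <- n
  dd <- c(diff(sm) / diff(depth), 0)
  dd[seq_len(imax)] <- 0
  if (iend < n) dd[seq(iend, n)] <- 0
  # ties (flat linear falloffs): take the middle of the tied edge; the
  # tolerance is relative so grid-rescaling float jitter cannot split ties
  cand <- which(dd <= min(dd) + abs(min(dd)) * 1e-6 + 1e-12)
  ist <- cand[ceiling(length(cand) / 2)]
  if (dd[ist] >= 0)
    stop("no finite range: no decreasing distal edge found", call. = FALSE)

  # falloff extent from the 80% -> 20% crossings (span scaled to 100% -> 0%)
  i80 <- which(post & sm < 80)[1]
  i20 <- which(post & sm < 20)[1]
  ext <- if (!is.na(i80) && !is.na(i20) && i20 > i80)
    (depth[i20] - depth[i80]) / 0.6 else 4 * mean(diff(depth))
  if (is.null(tangent_window)) tangent_window <- 0.2 * ext

  main <- .rp_once(depth, dose, sm, imax, ist, tangent_window, background)
  r_p <- main$rp
  if (is.na(r_p)) stop("tangent fit failed on the distal edge", call. = FALSE)
  alt <- c(.rp_once(depth, dose, sm, imax, ist, 0.5 * tangent_window, background)$rp,
           .rp_once(depth, dose, sm, imax, ist, 1.5 * tangent_window, background)$rp)
  alt <- alt[is.finite(alt)]
  unc <- if (length(alt)) (max(c(alt, r_p)) - min(c(alt, r_p))) / 2 else NA_real_

  i50 <- which(post & sm < 50)[1]
  r_50 <- if (!is.na(i50) && i50 > 1)
    stats::approx(dose[c(i50 - 1, i50)], depth[c(i50 - 1, i50)], xout = 50,
                  ties = "ordered")$y else NA_real_
  if (!is.finite(r_50)) r_50 <- depth[i50]

  structure(list(r_p = r_p, r_50 = r_50, z_max = depth[imax],
                 tangent = list(slope = main$slope, anchor_depth = depth[ist]),
                 background = background, uncertainty = unc),
            class = "range_result")
}

#' @export
print.range_result <- function(x, ...) {
  cat(sprintf("<range_result> Rp = %.3f cm (+/- %.3f), R50 = %.3f cm, zmax = %.3f cm\n",
              x$r_p, ifelse(is.na(x$uncertainty), 0, x$uncertainty), x$r_50, x$z_max))
  cat(sprintf("  tangent slope %.1f %%/cm at %.3f cm; background %.2f %%\n",
              x$tangent$slope, x$tangent$anchor_depth, x$background))
  invisible(x)
}

#' Pixel-to-physical calibration factor
#'
#' @param image_extent_px Extent of a known object in pixels (> 0).
#' @param container_extent_cm The same extent in cm (> 0).
#' @return Calibration in cm per pixel.
#' @export
pixel_calibration <- function(image_extent_px, container_extent_cm) {
  stopifnot(image_extent_px > 0, container_extent_cm > 0)
  container_extent_cm / image_extent_px
}

#' Refraction correction of an apparent depth axis
#'
#' Camera-side refraction at the container wall compresses or stretches the
#' apparent depth scale. The correction is a single multiplicative factor on
#' the depth coordinates (dose values unchanged); by default the factor is 1
#' (off) because the exact mapping from the refractive indices depends on the
#' unmodelled camera geometry and is supplied by the user.
#'
#' @param curve A [depth_dose_curve].
#' @param n_medium,n_air Refractive indices (metadata; >= 1).
#' @param factor Depth-scale factor; defaults to 1 (identity).
#' @return The corrected [depth_dose_curve].
#' @export
refraction_correct <- function(curve, n_medium = 1, n_air = 1, factor = NULL) {
  stopifnot(inherits(curve, "depth_dose"), n_medium >= 1, n_air >= 1)
  if (is.null(factor)) factor <- 1
  stopifnot(factor > 0)
  depth_dose_curve(curve$depth * factor, curve$dose,
                   provenance = attr(curve, "provenance"))
}

#' Write / read a depth-dose curve as CSV
#'
#' Columns `depth_cm`, `dose_percent`.
#'
#' @param curve A [depth_dose_curve].
#' @param path CSV path.
#' @return `path` invisibly; `read_depth_dose` returns the curve.
#' @export
write_depth_dose <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose"))
  utils::write.csv(data.frame(depth_cm = curve$depth, dose_percent = curve$dose),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_dose
#' @param provenance Provenance tag for the curve read back.
#' @export
read_depth_dose <- function(path, provenance = "synthetic") {
  d <- utils::read.csv(path)
  depth_dose_curve(d$depth_cm, d$dose_percent, provenance = provenance)
}

#' Range-result report as JSON
#'
#' @param result A `range_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_range_result <- function(result, path) {
  stopifnot(inherits(result, "range_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
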