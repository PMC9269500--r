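# Condensed-history Monte Carlo of electron (and simplified photon) beams in a
# rectangular scintillator container, scoring deposited energy on a 2D
# depth x lateral grid (the out-of-plane axis is integrated out, matching what
# a camera photograph of the fluorescence integrates).
#
# Electron scheme: class II condensed history. Per step the path length is set
# by a fractional energy loss; the continuous (restricted) collision loss is
# deposited uniformly along the step; Moller knock-on electrons above the
# transport cutoff are produced explicitly and transported as secondary
# histories (this supplies the energy-loss straggling that shapes the distal
# falloff of the depth-dose curve); the direction is deflected by a Gaussian
# multiple-scattering angle from the Highland formula.

#' Beam specification
#'
#' @param particle `"electron"` or `"photon"`.
#' @param energy Monoenergetic kinetic energy in MeV (> 0).
#' @param field_width Square field side in cm (default 6, the clinical
#'   electron applicator used with the scintillator container).
#' @param n_histories Number of primary histories (>= 1).
#' @param seed RNG seed (integer).
#' @return A `beam_spec` object.
#' @export
beam_spec <- function(particle = c("electron", "photon"), energy,
                      field_width = 6, n_histories = 1e5, seed = 1L) {
  particle <- match.arg(particle)
  stopifnot(energy > 0, field_width > 0, n_histories >= 1)
  structure(list(particle = particle, energy = energy,
                 field_width = field_width,
                 n_histories = as.integer(n_histories), seed = as.integer(seed)),
            class = "beam_spec")
}

#' Container geometry specification
#'
#' Defaults mirror the rectangular acrylic container of the experiment:
#' 10 cm along the depth (beam) axis, 10 cm laterally in the camera plane and
#' 5 cm along the viewing axis.
#'
#' @param depth Extent along the beam axis, cm.
#' @param lateral Extent in the camera plane perpendicular to the beam, cm.
#' @param width Extent along the viewing (out-of-plane) axis, cm.
#' @param cell_size Scoring cell size, cm; `depth` and `lateral` must be
#'   multiples of it.
#' @param material A [material] object filling the container.
#' @return A `geometry_spec` object.
#' @export
geometry_spec <- function(depth = 10, lateral = 10, width = 5,
                          cell_size = 0.05, material = abls_material()) {
  stopifnot(depth > 0, lateral > 0, width > 0, cell_size > 0,
            inherits(material, "material"))
  if (abs(depth / cell_size - round(depth / cell_size)) > 1e-9 ||
      abs(lateral / cell_size - round(lateral / cell_size)) > 1e-9)
    stop("extents must be positive multiples of cell_size", call. = FALSE)
  structure(list(depth = depth, lateral = lateral, width = width,
                 cell_size = cell_size, material = material),
            class = "geometry_spec")
}

# radiation length of the mixture, g/cm^2 (PDG elemental approximation)
.radiation_length <- function(comp) {
  e <- comp$elements
  x0i <- 716.408 * e$A / (e$Z * (e$Z + 1) * log(287 / sqrt(e$Z)))
  1 / sum(e$w / x0i)
}

# rotate unit vectors (ux,uy,uz) by polar angle th about a uniform azimuth ph
.deflect <- function(ux, uy, uz, th, ph) {
  st <- sin(th); ct <- cos(th); sp <- sin(ph); cp <- cos(ph)
  sz <- sqrt(pmax(1 - uz^2, 0))
  near_pole <- sz < 1e-8
  nx <- ifelse(near_pole, st * cp, ux * ct + st * (ux * uz * cp - uy * sp) / sz)
  ny <- ifelse(near_pole, st * sp, uy * ct + st * (uy * uz * cp + ux * sp) / sz)
  nz <- ifelse(near_pole, sign(uz) * ct, uz * ct - sz * st * cp)
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  list(ux = nx / nn, uy = ny / nn, uz = nz / nn)
}

# Transport a batch of electrons through the scoring state `st` (an
# environment holding grid/escaped), returning the updated state. Positions
# in cm; E in MeV (per-particle). Secondaries are accumulated on a stack and
# transported afterwards, generation by generation.
.transport_electrons <- function(st, x, y, z, ux, uy, uz, E,
                                 geom, opts) {
  cell <- geom$cell_size; nz_ <- st$nz; nx_ <- st$nx
  rho <- geom$material$density
  za <- .z_over_a(geom$material)
  X0 <- .radiation_length(geom$material)
  cut <- opts$cutoff; frac <- opts$step_fraction

  deposit <- function(w, zm, xm, ym) {
    ok <- zm >= 0 & zm <= geom$depth & abs(xm) <= geom$lateral / 2 &
      abs(ym) <= geom$width / 2
    st$escaped <- st$escaped + sum(w[!ok])
    if (any(ok)) {
      iz <- pmin(floor(zm[ok] / cell) + 1L, nz_)
      ix <- pmin(floor((xm[ok] + geom$lateral / 2) / cell) + 1L, nx_)
      id <- (ix - 1L) * nz_ + iz
      s <- rowsum(w[ok], id)
      at <- as.integer(rownames(s))
      st$grid[at] <- st$grid[at] + as.numeric(s)
    }
    invisible(NULL)
  }

  # particles entering outside the container never interact
  act <- abs(x) <= geom$lateral / 2 & abs(y) <= geom$width / 2 &
    z >= 0 & z <= geom$depth & E > 0
  st$escaped <- st$escaped + sum(E[!act])
  low0 <- act & E <= cut                     # below cutoff already: deposit locally
  if (any(low0)) { deposit(E[low0], z[low0], x[low0], y[low0]); act[low0] <- FALSE }

  sx <- sy <- sz2 <- sux <- suy <- suz <- sE <- numeric(0)
  nstep <- 0L
  while (any(act) && nstep < opts$max_steps) {
    nstep <- nstep + 1L
    i <- which(act)
    Ei <- E[i]
    dE <- frac * Ei
    s_col <- st$f_scol(log(Ei)) * rho        # MeV/cm, unrestricted
    s_tot <- st$f_stot(log(Ei)) * rho
    s_rad <- s_tot - s_col
    ds <- dE / s_tot
    beta2 <- Ei * (Ei + 2 * .MEC2) / (Ei + .MEC2)^2

    if (opts$deltas) {
      tmax <- Ei / 2
      can <- tmax > cut
      lam <- ifelse(can, .KBETHE * za * rho / beta2 * (1 / cut - 1 / tmax), 0)
      s_del <- ifelse(can, .KBETHE * za * rho / beta2 * log(tmax / cut), 0)
      s_res <- pmax(s_col - s_del, 0.2 * s_col)
    } else {
      lam <- numeric(length(i)); s_res <- s_col
    }

    # continuous collision deposit, spread uniformly along the step
    w <- s_res * ds
    uu <- stats::runif(length(i))
    deposit(w, z[i] + uz[i] * ds * uu, x[i] + ux[i] * ds * uu,
            y[i] + uy[i] * ds * uu)

    # radiative loss: photons escape the grid (default) or deposit on-track
    wr <- s_rad * ds
    if (opts$radiative == "deposit") {
      deposit(wr, z[i] + uz[i] * ds * uu, x[i] + ux[i] * ds * uu,
              y[i] + uy[i] * ds * uu)
    } else st$escaped <- st$escaped + sum(wr)

    eloss <- s_res * ds + wr

    # explicit Moller knock-on electron (simplified 1/T^2 spectrum, <=1/step)
    if (opts$deltas) {
      has <- which(stats::rpois(length(i), lam * ds) > 0)
      if (length(has)) {
        ii <- i[has]; Eh <- E[ii]; tm <- Eh / 2
        Td <- cut / (1 - stats::runif(length(has)) * (1 - cut / tm))
        cth <- sqrt(Td * (Eh + 2 * .MEC2) / (Eh * (Td + 2 * .MEC2)))
        d <- .deflect(ux[ii], uy[ii], uz[ii],
                      acos(pmin(cth, 1)), stats::runif(length(has), 0, 2 * pi))
        sx <- c(sx, x[ii] + ux[ii] * ds[has] / 2)
        sy <- c(sy, y[ii] + uy[ii] * ds[has] / 2)
        sz2 <- c(sz2, z[ii] + uz[ii] * ds[has] / 2)
        sux <- c(sux, d$ux); suy <- c(suy, d$uy); suz <- c(suz, d$uz)
        sE <- c(sE, Td)
        eloss[has] <- eloss[has] + Td
      }
    }

    x[i] <- x[i] + ux[i] * ds
    y[i] <- y[i] + uy[i] * ds
    z[i] <- z[i] + uz[i] * ds
    E[i] <- pmax(Ei - eloss, 0)

    out <- z[i] < 0 | z[i] > geom$depth | abs(x[i]) > geom$lateral / 2 |
      abs(y[i]) > geom$width / 2
    if (any(out)) {
      st$escaped <- st$escaped + sum(E[i][out])
      act[i[out]] <- FALSE
    }
    i2 <- which(act)
    low <- E[i2] <= cut
    if (any(low)) {
      deposit(E[i2][low], z[i2][low], x[i2][low], y[i2][low])
      act[i2[low]] <- FALSE
    }

    if (opts$scattering) {
      i3 <- which(act)
      if (length(i3)) {
        Ei3 <- E[i3]
        p <- sqrt(Ei3 * (Ei3 + 2 * .MEC2))
        beta <- p / (Ei3 + .MEC2)
        tt <- ds[match(i3, i)] * rho / X0
        th0 <- 13.6 / (beta * p) * sqrt(tt) * pmax(1 + 0.038 * log(tt), 0.25)
        th <- th0 * sqrt(-2 * log(stats::runif(length(i3))))
        d <- .deflect(ux[i3], uy[i3], uz[i3], th,
                      stats::runif(length(i3), 0, 2 * pi))
        ux[i3] <- d$ux; uy[i3] <- d$uy; uz[i3] <- d$uz
      }
    }
  }
  if (any(act)) {  # step-capped stragglers: deposit locally to conserve energy
    i <- which(act)
    deposit(E[i], z[i], x[i], y[i])
  }
  list(sx = sx, sy = sy, sz = sz2, sux = sux, suy = suy, suz = suz, sE = sE)
}

.new_score_state <- function(geom) {
  st <- new.env(parent = emptyenv())
  st$nz <- as.integer(round(geom$depth / geom$cell_size))
  st$nx <- as.integer(round(geom$lateral / geom$cell_size))
  st$grid <- matrix(0, st$nz, st$nx)
  st$escaped <- 0
  # stopping-power interpolators on a log grid covering the transport range
  Eg <- exp(seq(log(5e-3), log(110), length.out = 500))
  s_col <- collision_stopping_power(Eg, geom$material)
  s_tot <- s_col + radiative_stopping_power(Eg, geom$material)
  st$f_scol <- stats::approxfun(log(Eg), s_col, rule = 2)
  st$f_stot <- stats::approxfun(log(Eg), s_tot, rule = 2)
  st
}

.run_electron_generations <- function(st, x, y, z, ux, uy, uz, E, geom, opts) {
  gen <- 0L
  repeat {
    sec <- .transport_electrons(st, x, y, z, ux, uy, uz, E, geom, opts)
    gen <- gen + 1L
    if (length(sec$sE) == 0L || gen > opts$max_generations) {
      if (length(sec$sE)) st$escaped <- st$escaped + sum(sec$sE)
      break
    }
    x <- sec$sx; y <- sec$sy; z <- sec$sz
    ux <- sec$sux; uy <- sec$suy; uz <- sec$suz; E <- sec$sE
  }
  invisible(st)
}

.mc_opts <- function(step_fraction = 0.02, cutoff = 0.1, scattering = TRUE,
                     deltas = TRUE, radiative = c("escape", "deposit"),
                     max_steps = 5000L, max_generations = 8L) {
  list(step_fraction = step_fraction, cutoff = cutoff, scattering = scattering,
       deltas = deltas, radiative = match.arg(radiative),
       max_steps = max_steps, max_generations = max_generations)
}

.as_dose_grid <- function(st, beam, geom) {
  out <- list(deposited = st$grid, cell_size = geom$cell_size, beam = beam,
              geometry = geom, escaped_energy = st$escaped, relative = FALSE)
  class(out) <- "dose_grid"
  out
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid>", nrow(x$deposited), "x", ncol(x$deposited),
      "cells of", x$cell_size, "cm\n")
  if (!isTRUE(x$relative))
    cat("  deposited", signif(sum(x$deposited), 6), "MeV; escaped",
        signif(x$escaped_energy, 6), "MeV\n")
  invisible(x)
}

#' Simulate a monoenergetic electron beam
#'
#' Condensed-history transport (see the package vignette for the scheme).
#' Histories start uniformly across the square field at depth 0 travelling
#' down the depth axis; the scored grid is depth x lateral with the viewing
#' axis integrated out. The result is bit-reproducible for a fixed
#' `beam$seed`.
#'
#' @param beam A [beam_spec] with `particle = "electron"`.
#' @param geom A [geometry_spec].
#' @param step_fraction Fractional energy loss per condensed-history step.
#' @param cutoff Electron transport cutoff in MeV; residual energy is
#'   deposited locally.
#' @param scattering Apply Highland multiple scattering (disable to reduce the
#'   walk to deterministic slowing-down).
#' @param deltas Produce explicit Moller knock-on electrons above `cutoff`
#'   (class II scheme). Disable together with `scattering` for the
#'   deterministic limiting case.
#' @param radiative `"escape"` (bremsstrahlung photons leave the grid;
#'   default) or `"deposit"` (radiative loss deposited on-track).
#' @return A `dose_grid` object: `deposited` (MeV per cell, depth rows x
#'   lateral columns), `cell_size`, `beam`, `escaped_energy`.
#' @export
simulate_electron_beam <- function(beam, geom, step_fraction = 0.02,
                                   cutoff = 0.1, scattering = TRUE,
                                   deltas = TRUE,
                                   radiative = c("escape", "deposit")) {
  stopifnot(inherits(beam, "beam_spec"), inherits(geom, "geometry_spec"))
  if (beam$particle != "electron") stop("beam particle must be 'electron'", call. = FALSE)
  opts <- .mc_opts(step_fraction, cutoff, scattering, deltas, radiative)
  st <- .new_score_state(geom)
  set.seed(beam$seed)
  n <- beam$n_histories
  fw <- beam$field_width
  x <- stats::runif(n, -fw / 2, fw / 2)
  y <- stats::runif(n, -fw / 2, fw / 2)
  .run_electron_generations(st, x, y, rep(0, n),
                            rep(0, n), rep(0, n), rep(1, n),
                            rep(beam$energy, n), geom, opts)
  grid_range <- specific_to_linear_range(
    csda_range(beam$energy, geom$material), geom$material$density)
  if (grid_range > geom$depth)
    warning("grid shallower than the CSDA range; escaping energy is accounted",
            call. = FALSE)
  .as_dose_grid(st, beam, geom)
}

# ---- photons ----------------------------------------------------------------

# Klein-Nishina total cross-section per electron, cm^2 (k = E/mec2)
.kn_total <- function(k) {
  re2 <- 7.940787e-26  # classical electron radius squared, cm^2
  t1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  2 * pi * re2 * (t1 + log(1 + 2 * k) / (2 * k) -
                    (1 + 3 * k) / (1 + 2 * k)^2)
}

# crude photoelectric mass attenuation (cm^2/g): ~ Zeff^4.5 / E^3, scaled to
# water at 0.1 MeV; negligible at the MeV energies used here
.photoelectric_mu <- function(E, comp) {
  3.2e-10 * effective_atomic_number(comp)^4.5 / E^3
}

#' Total photon attenuation coefficient of a material
#'
#' Compton (Klein-Nishina on the electron density) plus a small parameterized
#' photoelectric term; adequate for the MeV photons used here.
#'
#' @param E Photon energy in MeV.
#' @param comp A [material] object.
#' @return Linear attenuation coefficient in 1/cm.
#' @export
photon_attenuation <- function(E, comp) {
  stopifnot(inherits(comp, "material"))
  mu_c <- .kn_total(E / .MEC2) * electron_density(comp) * comp$density
  mu_c + .photoelectric_mu(E, comp) * comp$density
}

# Kahn's rejection sampling of the Klein-Nishina scattering angle; returns
# the scattered/incident energy ratio for each photon.
.kn_sample_ratio <- function(k) {
  n <- length(k)
  r <- numeric(n)
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo) && guard < 1000L) {
    guard <- guard + 1L
    kk <- k[todo]
    r1 <- stats::runif(length(todo)); r2 <- stats::runif(length(todo))
    r3 <- stats::runif(length(todo))
    branch <- r1 <= (1 + 2 * kk) / (9 + 2 * kk)
    x <- ifelse(branch, 1 + 2 * kk * r2, (1 + 2 * kk) / (1 + 2 * kk * r2))
    cth <- 1 - (x - 1) / kk
    acc <- ifelse(branch,
                  r3 <= 4 * (1 / x - 1 / x^2),
                  r3 <= 0.5 * (cth^2 + 1 / x))
    ok <- acc & abs(cth) <= 1
    r[todo[ok]] <- 1 / x[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) r[todo] <- 1  # pathological guard; forward no-loss
  r
}

#' Simulate a monoenergetic photon beam (simplified transport)
#'
#' Photons travel with exponential free paths from the total attenuation
#' coefficient; each Compton interaction transfers a Klein-Nishina-sampled
#' energy fraction to an electron (transported with the condensed-history
#' engine) while the scattered photon continues with the deflected direction.
#' A monoenergetic source stands in for the clinical 6 MV bremsstrahlung
#' spectrum.
#'
#' @param beam A [beam_spec] with `particle = "photon"`.
#' @param geom A [geometry_spec].
#' @param cutoff_photon Photon cutoff in MeV (absorbed locally below it).
#' @param mu_override Optional fixed linear attenuation coefficient (1/cm),
#'   e.g. `Inf` to force all interactions at the surface.
#' @param return_interactions Record first-interaction depths (attribute
#'   `interaction_depths` on the result) for attenuation checks.
#' @param ... Electron-transport options passed on (see
#'   [simulate_electron_beam()]).
#' @return A `dose_grid` object.
#' @export
simulate_photon_beam <- function(beam, geom, cutoff_photon = 0.01,
                                 mu_override = NULL,
                                 return_interactions = FALSE, ...) {
  stopifnot(inherits(beam, "beam_spec"), inherits(geom, "geometry_spec"))
  if (beam$particle != "photon") stop("beam particle must be 'photon'", call. = FALSE)
  opts <- .mc_opts(...)
  st <- .new_score_state(geom)
  set.seed(beam$seed)
  n <- beam$n_histories
  fw <- beam$field_width
  px <- stats::runif(n, -fw / 2, fw / 2)
  py <- stats::runif(n, -fw / 2, fw / 2)
  pz <- rep(0, n)
  ux <- rep(0, n); uy <- rep(0, n); uz <- rep(1, n)
  Ek <- rep(beam$energy, n)
  inside <- abs(px) <= geom$lateral / 2 & abs(py) <= geom$width / 2
  st$escaped <- st$escaped + sum(Ek[!inside])
  alive <- inside
  first_depth <- rep(NA_real_, n)
  ex <- ey <- ez <- eux <- euy <- euz <- eE <- numeric(0)
  it <- 0L
  while (any(alive) && it < 200L) {
    it <- it + 1L
    i <- which(alive)
    mu <- if (is.null(mu_override)) photon_attenuation(Ek[i], geom$material) else
      rep(mu_override, length(i))
    step <- ifelse(is.infinite(mu), 0, stats::rexp(length(i), rate = mu))
    px[i] <- px[i] + ux[i] * step
    py[i] <- py[i] + uy[i] * step
    pz[i] <- pz[i] + uz[i] * step
    out <- pz[i] < 0 | pz[i] > geom$depth | abs(px[i]) > geom$lateral / 2 |
      abs(py[i]) > geom$width / 2
    st$escaped <- st$escaped + sum(Ek[i][out])
    alive[i[out]] <- FALSE
    i <- which(alive)
    if (!length(i)) break
    if (it == 1L) first_depth[i] <- pz[i]
    # Compton interaction
    k <- Ek[i] / .MEC2
    ratio <- .kn_sample_ratio(k)
    Te <- Ek[i] * (1 - ratio)
    # electron direction: kinematic polar angle about the photon direction
    cth_e <- ifelse(Te > 0,
                    (1 + k) * sqrt(pmax(Te, 0) / (Te + 2 * .MEC2)) / k, 1)
    cth_e <- pmin(pmax(cth_e, -1), 1)
    phi_e <- stats::runif(length(i), 0, 2 * pi)
    de <- .deflect(ux[i], uy[i], uz[i], acos(cth_e), phi_e)
    ex <- c(ex, px[i]); ey <- c(ey, py[i]); ez <- c(ez, pz[i])
    eux <- c(eux, de$ux); euy <- c(euy, de$uy); euz <- c(euz, de$uz)
    eE <- c(eE, Te)
    # scattered photon continues, deflected by the Compton angle
    cth_g <- pmin(pmax(1 - (1 / ratio - 1) / k, -1), 1)
    dg <- .deflect(ux[i], uy[i], uz[i], acos(cth_g), phi_e + pi)
    ux[i] <- dg$ux; uy[i] <- dg$uy; uz[i] <- dg$uz
    Ek[i] <- Ek[i] * ratio
    low <- Ek[i] <= cutoff_photon
    if (any(low)) {
      ii <- i[low]
      ok <- pz[ii] >= 0 & pz[ii] <= geom$depth & abs(px[ii]) <= geom$lateral / 2 &
        abs(py[ii]) <= geom$width / 2
      iz <- pmin(floor(pz[ii][ok] / geom$cell_size) + 1L, st$nz)
      ix <- pmin(floor((px[ii][ok] + geom$lateral / 2) / geom$cell_size) + 1L, st$nx)
      id <- (ix - 1L) * st$nz + iz
      s <- rowsum(Ek[ii][ok], id)
      at <- as.integer(rownames(s))
      st$grid[at] <- st$grid[at] + as.numeric(s)
      st$escaped <- st$escaped + sum(Ek[ii][!ok])
      alive[ii] <- FALSE
    }
  }
  if (any(alive)) st$escaped <- st$escaped + sum(Ek[alive])
  if (length(eE))
    .run_electron_generations(st, ex, ey, ez, eux, euy, euz, eE, geom, opts)
  out <- .as_dose_grid(st, beam, geom)
  if (return_interactions) attr(out, "interaction_depths") <- first_depth
  out
}

#' Percent depth dose from a 2D dose grid
#'
#' Sums each depth row over the lateral axis and normalizes the maximum to
#' 100%.
#'
#' @param grid A `dose_grid`.
#' @return A [depth_dose_curve] with provenance `"mc"` (or `"image"` for
#'   relative grids from the image pipeline).
#' @export
pdd_from_dose_grid <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  tot <- rowSums(grid$deposited)
  if (max(tot) <= 0) stop("all-zero dose grid", call. = FALSE)
  depth <- (seq_along(tot) - 0.5) * grid$cell_size
  prov <- if (isTRUE(grid$relative)) "image" else "mc"
  depth_dose_curve(depth, tot / max(tot) * 100, provenance = prov)
}

#' Write / read a dose grid as CSV plus a JSON sidecar
#'
#' The deposited-energy matrix goes to `<path>` as headerless CSV; cell size,
#' beam parameters and the escaped-energy account go to `<path>.json`.
#'
#' @param grid A `dose_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`read_dose_grid` returns the `dose_grid`).
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  utils::write.table(grid$deposited, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(cell_size = grid$cell_size,
               escaped_energy = grid$escaped_energy,
               relative = isTRUE(grid$relative),
               beam = if (!is.null(grid$beam)) unclass(grid$beam))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  beam <- if (!is.null(side$beam)) structure(as.list(side$beam), class = "beam_spec")
  structure(list(deposited = m, cell_size = side$cell_size, beam = beam,
                 geometry = NULL, escaped_energy = side$escaped_energy,
                 relative = isTRUE(side$relative)),
            class = "dose_grid")
}
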