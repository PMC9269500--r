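test_that("scattering-free transport reduces to deterministic slowing-down", {
  geom <- geometry_spec()
  beam <- beam_spec("electron", 6, n_histories = 300, seed = 11)
  g <- simulate_electron_beam(beam, geom, scattering = FALSE, deltas = FALSE,
                              radiative = "deposit")
  pdd <- rowSums(g$deposited)
  max_depth <- max(which(pdd > 0)) * g$cell_size
  csda_cm <- specific_to_linear_range(csda_range(6, geom$material),
                                      geom$material$density)
  expect_lt(abs(max_depth - csda_cm), g$cell_size)    # within one cell
})

test_that("energy bookkeeping and seeded determinism hold exactly", {
  geom <- geometry_spec()
  beam <- beam_spec("electron", 6, n_histories = 500, seed = 5)
  g1 <- simulate_electron_beam(beam, geom)
  expect_equal(sum(g1$deposited) + g1$escaped_energy, 500 * 6,
               tolerance = 1e-9)
  g2 <- simulate_electron_beam(beam, geom)
  expect_identical(g1$deposited, g2$deposited)
  expect_identical(g1$escaped_energy, g2$escaped_energy)
  # photon transport conserves energy too
  pb <- beam_spec("photon", 2, n_histories = 400, seed = 6)
  gp <- simulate_photon_beam(pb, geom)
  expect_equal(sum(gp$deposited) + gp$escaped_energy, 400 * 2,
               tolerance = 1e-9)
})

test_that("statistical error tightens as 1/sqrt(histories)", {
  geom <- geometry_spec(cell_size = 0.1)
  run <- function(n, seed) {
    g <- simulate_electron_beam(beam_spec("electron", 6, n_histories = n,
                                          seed = seed), geom)
    list(pdd = rowSums(g$deposited) / n,
         rp = practical_range(pdd_from_dose_grid(g))$r_p)
  }
  r1 <- lapply(1:12, function(s) run(800, s))
  r2 <- lapply(1:12, function(s) run(1600, 200 + s))
  p1 <- sapply(r1, `[[`, "pdd"); p2 <- sapply(r2, `[[`, "pdd")
  keep <- rowMeans(p1) > 0.1 * max(rowMeans(p1))
  # pooled per-depth-bin standard error: doubling n should shrink it ~1/sqrt(2)
  ratio <- sqrt(sum(apply(p2[keep, ], 1, stats::var)) /
                  sum(apply(p1[keep, ], 1, stats::var)))
  expect_gt(ratio, 0.55)
  expect_lt(ratio, 0.88)
  # the extracted range does not get noisier with more histories
  expect_lt(stats::sd(sapply(r2, `[[`, "rp")),
            1.25 * stats::sd(sapply(r1, `[[`, "rp")))
})

test_that("pdd_from_dose_grid normalizes and flags degenerate grids", {
  g <- structure(list(deposited = matrix(0, 10, 4), cell_size = 0.1,
                      beam = NULL, geometry = NULL, escaped_energy = 0,
                      relative = FALSE), class = "dose_grid")
  expect_error(pdd_from_dose_grid(g), "all-zero")
  g$deposited[4, 2] <- 5
  curve <- pdd_from_dose_grid(g)
  expect_equal(curve$dose[4], 100)
  expect_equal(sum(curve$dose > 0), 1)                 # delta curve
  expect_equal(curve$depth[4], 0.35)                   # cell-centre depth
  g$deposited[] <- 1
  expect_true(all(pdd_from_dose_grid(g)$dose == 100))  # uniform grid is flat
})

test_that("electron depth dose builds up to a sub-surface maximum", {
  g <- cached_mc(6, 2e4, seed = 21)
  curve <- pdd_from_dose_grid(g)
  rr <- practical_range(curve)
  expect_gt(rr$z_max, 0.5)       # build-up: maximum well below the surface
  expect_lt(rr$z_max, 2.5)
  expect_true(rr$z_max <= rr$r_50 && rr$r_50 <= rr$r_p)
})

test_that("photon beam attenuates exponentially and crosses the container", {
  geom <- geometry_spec()
  pb <- beam_spec("photon", 2, n_histories = 4000, seed = 9)
  gp <- simulate_photon_beam(pb, geom, return_interactions = TRUE)
  depths <- attr(gp, "interaction_depths")
  depths <- depths[!is.na(depths) & depths > 0 & depths <= 10]
  mu <- photon_attenuation(2, geom$material)
  # ML estimate for an exponential truncated at the container depth
  negll <- function(m) -sum(stats::dexp(depths, m, log = TRUE) -
                              stats::pexp(10, m, log.p = TRUE))
  mu_hat <- stats::optimize(negll, c(0.005, 0.5))$minimum
  expect_equal(mu_hat, mu, tolerance = 0.15)
  # 2 MeV photons deposit throughout the container, unlike 6 MeV electrons
  pdd_p <- rowSums(gp$deposited)
  expect_gt(sum(pdd_p[151:200]) / sum(pdd_p), 0.10)
  ge <- cached_mc(6, 2e4, seed = 21)
  pdd_e <- rowSums(ge$deposited)
  expect_equal(sum(pdd_e[101:200]), 0)
  # infinite attenuation: everything absorbed at the surface
  gs <- simulate_photon_beam(beam_spec("photon", 2, n_histories = 300, seed = 2),
                             geom, mu_override = 1e9)
  expect_gt(sum(gs$deposited[1:10, ]) / sum(gs$deposited), 0.85)
})

test_that("dose grids survive the CSV + sidecar round trip", {
  g <- cached_mc(6, 2e4, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_grid(g, path)
  back <- read_dose_grid(path)
  expect_equal(back$deposited, g$deposited, tolerance = 1e-12)
  expect_equal(back$cell_size, g$cell_size)
  expect_equal(back$escaped_energy, g$escaped_energy, tolerance = 1e-9)
})
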