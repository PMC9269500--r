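test_that("formula parsing and mixture composition give correct mass fractions", {
  # water from H2O: oracle = atomic masses 2*1.008 / 18.015, 15.999 / 18.015
  w <- compose_mixture(c(H2O = 1), basis = "mass", final_density = 1.0)
  expect_equal(sort(w$elements$symbol), c("H", "O"))
  expect_equal(w$elements$w[w$elements$symbol == "H"], 2 * 1.008 / (2 * 1.008 + 15.999),
               tolerance = 1e-12)
  expect_equal(w$elements$w[w$elements$symbol == "O"], 15.999 / (2 * 1.008 + 15.999),
               tolerance = 1e-12)

  # single-component mixture is the pure compound
  ee1 <- compose_mixture(c(C4H10O2 = 1), basis = "mass", final_density = 0.93)
  ee5 <- compose_mixture(c(C4H10O2 = 5), basis = "mass", final_density = 0.93)
  expect_equal(ee1$elements$w, ee5$elements$w)

  # 7:3 by volume with densities 0.930 / 0.998: arithmetic oracle for the
  # 2-ethoxyethanol mass share
  ab <- abls_material()
  share <- 7 * 0.930 / (7 * 0.930 + 3 * 0.998)
  expect_equal(share, 0.685, tolerance = 1e-3)
  M_ee <- 4 * 12.011 + 10 * 1.008 + 2 * 15.999
  expect_equal(ab$elements$w[ab$elements$symbol == "C"],
               share * 4 * 12.011 / M_ee, tolerance = 1e-12)
  expect_equal(sum(ab$elements$w), 1, tolerance = 1e-12)
  expect_equal(ab$density, 0.945)

  expect_error(parse_formula("Xx2O"), "unknown element")
  expect_error(compose_mixture(c(H2O = -1), basis = "mass", final_density = 1),
               "proportions")
  expect_error(compose_mixture(c(H2O = 1), basis = "volume", final_density = 1),
               "densit")
})

test_that("effective atomic number follows the electron-fraction power law", {
  carbon <- material(c(C = 1), density = 2.0)
  for (m in c(1.5, 2.94, 4)) expect_equal(effective_atomic_number(carbon, m), 6)

  # water, m = 2.94: direct evaluation of the power-law sum over H, O
  w <- water_material()
  aH <- 0.111907 * 1 / 1.008; aO <- 0.888093 * 8 / 15.999
  s <- aH + aO
  oracle <- ((aH / s) * 1^2.94 + (aO / s) * 8^2.94)^(1 / 2.94)
  expect_equal(effective_atomic_number(w), oracle, tolerance = 1e-4)
  expect_equal(effective_atomic_number(w), 7.42, tolerance = 0.01)

  # bounded by the min and max Z present, for a spread of compositions
  set.seed(42)
  for (i in 1:20) {
    fr <- stats::runif(3); fr <- fr / sum(fr)
    comp <- material(c(H = fr[1], C = fr[2], O = fr[3]), density = 1)
    for (m in c(1.2, 2.94, 5)) {
      z <- effective_atomic_number(comp, m)
      expect_gte(z, 1); expect_lte(z, 8)
    }
  }
  expect_error(effective_atomic_number(w, exponent = -1), "exponent")
})

test_that("mean excitation energy obeys Bragg additivity and its bounds", {
  carbon <- material(c(C = 1), density = 2.0)
  expect_equal(mean_excitation_energy(carbon), 81.0)

  # water: hand evaluation of the additivity formula (condensed-phase I's)
  w <- water_material()
  uH <- 0.111907 / 1.008; uO <- 0.888093 * 8 / 15.999
  oracle <- exp((uH * log(19.2) + uO * log(106)) / (uH + uO))
  expect_equal(mean_excitation_energy(w), oracle, tolerance = 1e-6)
  expect_gt(mean_excitation_energy(w), 74)
  expect_lt(mean_excitation_energy(w), 76)

  # mixture I lies between the elemental extremes
  set.seed(7)
  for (i in 1:10) {
    fr <- stats::runif(3); fr <- fr / sum(fr)
    comp <- material(c(H = fr[1], C = fr[2], O = fr[3]), density = 1)
    I <- mean_excitation_energy(comp)
    expect_gt(I, 19.2); expect_lt(I, 106)
  }
})

test_that("electron density and composition invariants", {
  h <- material(c(H = 1), density = 0.07)
  expect_equal(electron_density(h), 6.02214076e23 / 1.008, tolerance = 1e-9)
  expect_equal(electron_density(water_material()), 3.343e23, tolerance = 1e-3)
  # fractions not summing to 1 are rejected
  expect_error(material(c(H = 0.2, O = 0.2), density = 1), "sum to 1")
  expect_error(material(c(H = 2, O = -1), density = 1), "\\[0, 1\\]")
})

test_that("material JSON round trip preserves the composition", {
  path <- withr::local_tempfile(fileext = ".json")
  ab <- abls_material()
  write_material(ab, path)
  back <- read_material(path)
  expect_equal(back$density, ab$density)
  expect_equal(back$elements$w[order(back$elements$symbol)],
               ab$elements$w[order(ab$elements$symbol)], tolerance = 1e-12)
})
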