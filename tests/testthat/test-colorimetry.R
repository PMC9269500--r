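test_that("sRGB transfer functions match the standard", {
  expect_equal(srgb_decode(0), 0)
  expect_equal(srgb_decode(1), 1)
  expect_equal(srgb_decode(0.5), 0.2140, tolerance = 5e-4)  # EOTF at mid-gray
  x <- seq(0, 1, length.out = 101)
  expect_equal(srgb_encode(srgb_decode(x)), x, tolerance = 1e-12)
  img <- rgb_image(array(0.5, c(2, 2, 3)), "linear")
  expect_warning(srgb_decode(img), "already linear")
})

test_that("XYZ decomposition hits the D65 white point and normalizes chromaticity", {
  px <- array(0, c(2, 3, 3))
  px[1, 1, ] <- 1                      # white
  px[1, 2, ] <- c(0, 0, 1)             # pure blue
  img <- rgb_image(px, "linear")
  d <- rgb_to_xyz(img)
  expect_equal(c(d$X[1, 1], d$Y[1, 1], d$Z[1, 1]), c(0.9505, 1.0000, 1.0890),
               tolerance = 1e-4)
  expect_equal(c(d$X[2, 1], d$x[2, 1]), c(0, 0))       # black stays 0
  expect_equal(c(d$x[1, 2], d$y[1, 2]), c(0.150, 0.060), tolerance = 1e-3)
  expect_gt(d$z[1, 2], 0.75)                            # z-dominant blue

  set.seed(3)
  rnd <- rgb_image(array(stats::runif(5 * 4 * 3), c(5, 4, 3)), "linear")
  dd <- rgb_to_xyz(rnd)
  expect_equal(as.numeric(dd$x + dd$y + dd$z), rep(1, 20), tolerance = 1e-6)
  expect_error(rgb_to_xyz(rgb_image(array(0.5, c(2, 2, 3)), "sRGB")), "linear")
})

test_that("hexcone HSV matches hand values and the grDevices oracle", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(0, 0, 1)
  px[1, 2, ] <- c(0.4, 0.4, 0.4)
  px[1, 3, ] <- c(0.25, 0.5, 1.0)
  hsv <- rgb_to_hsv_image(rgb_image(px, "sRGB"))
  expect_equal(c(hsv$H[1, 1], hsv$S[1, 1], hsv$V[1, 1]), c(240, 1, 1))
  expect_equal(c(hsv$H[1, 2], hsv$S[1, 2], hsv$V[1, 2]), c(0, 0, 0.4))
  expect_equal(c(hsv$H[1, 3], hsv$S[1, 3], hsv$V[1, 3]), c(220, 0.75, 1.0))

  # independent oracle: grDevices::rgb2hsv on 1000 random colors
  set.seed(11)
  m <- matrix(stats::runif(3000), nrow = 3)
  ours <- rgb_to_hsv_image(rgb_image(array(t(m), c(1000, 1, 3)), "sRGB"))
  ref <- grDevices::rgb2hsv(m, maxColorValue = 1)
  expect_equal(as.numeric(ours$H), ref["h", ] * 360, tolerance = 1e-9)
  expect_equal(as.numeric(ours$S), ref["s", ], tolerance = 1e-9)
  expect_equal(as.numeric(ours$V), ref["v", ], tolerance = 1e-9)
})

test_that("HSV -> RGB inverts the decomposition on a color grid", {
  g <- seq(0.02, 0.98, length.out = 10)
  grid <- as.matrix(expand.grid(g, g, g))           # 10^3 sampled colors
  img <- rgb_image(array(grid, c(nrow(grid), 1, 3)), "sRGB")
  back <- hsv_to_rgb_image(rgb_to_hsv_image(img))
  expect_lt(max(abs(unclass(back) - unclass(img))), 1e-9)
})

test_that("V histogram counts and V-cut masks behave as specified", {
  V <- matrix(0.5, 4, 5)
  hsv <- structure(list(H = V * 0, S = V * 0, V = V), class = "hsv_image")
  vh <- v_histogram(hsv, 10)
  expect_equal(sum(vh$count), 20)
  expect_equal(sum(vh$count > 0), 1)                 # constant image: one bin

  V2 <- matrix(c(rep(0.3, 5), rep(0.6, 15)), 4, 5)
  hsv2 <- structure(list(H = V2 * 0, S = V2 * 0, V = V2), class = "hsv_image")
  vh2 <- v_histogram(hsv2, 10)
  expect_equal(sort(vh2$count[vh2$count > 0]), c(5, 15))  # 25% / 75% split

  expect_equal(sum(v_threshold(hsv2, 0)$mask), 20)   # cut 0 keeps all
  expect_equal(sum(v_threshold(hsv2, 0.7)$mask), 0)  # cut above max keeps none
  vm <- v_threshold(hsv2, 0.4)
  expect_equal(sum(vm$mask), 15)                     # exactly the 0.6 pixels
  expect_equal(unique(vm$masked_V[vm$mask]), 0.6)
  # mask size non-increasing in v_cut
  sizes <- vapply(seq(0, 1, by = 0.1),
                  function(v) sum(v_threshold(hsv2, v)$mask), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("gamma-style image is bimodal and the 0.6 cut separates the populations", {
  img <- render_gamma_style_image()
  hsv <- rgb_to_hsv_image(img)
  peaks <- histogram_peaks(v_histogram(hsv, 50), floor_frac = 0.005)
  expect_gte(length(peaks), 2)
  expect_true(any(abs(peaks - 0.31) < 0.08))         # reflection population
  expect_true(any(peaks > 0.55 & peaks < 0.75))      # direct emission

  band_rows <- attr(img, "band_rows")
  signal_rows <- attr(img, "signal_rows")
  vm6 <- v_threshold(hsv, 0.6)
  expect_lt(mean(vm6$mask[band_rows, ]), 0.01)       # glare removed
  expect_gte(mean(vm6$mask[signal_rows, ]), 0.95)    # signal retained
  vm3 <- v_threshold(hsv, 0.3)
  expect_gt(mean(vm3$mask[band_rows, ]), mean(vm6$mask[band_rows, ]))
})

test_that("dose maps recover the underlying grid and drop sub-cut reflections", {
  g <- cached_mc(6, 2e4, seed = 21)
  clean_cam <- camera_model(psf_sigma = 0, noise_sd = 0, seed = 1)
  img <- render_fluorescence_image(g, clean_cam)
  dm <- dose_map_from_image(img, v_cut = 0, calibration = g$cell_size)
  expect_gt(stats::cor(as.numeric(dm$deposited), as.numeric(g$deposited)), 0.999)
  expect_equal(max(dm$deposited), 100)

  # uniform image maps to a uniform grid
  uimg <- render_fluorescence_image(matrix(1, 20, 20), clean_cam)
  udm <- dose_map_from_image(uimg, v_cut = 0.1, calibration = 0.05)
  expect_lt(stats::sd(udm$deposited) / mean(udm$deposited), 1e-6)

  # generator-injected reflection bands below the cut are removed at 0.3
  cam <- camera_model(psf_sigma = 0, noise_sd = 0, seed = 2,
                      reflection_bands = list(list(rows = c(190, 200), v = 0.25)))
  img2 <- render_fluorescence_image(g, cam)
  hsv2 <- rgb_to_hsv_image(img2)
  expect_gt(mean(hsv2$V[195:200, ]), 0.2)            # bands present pre-cut
  dm2 <- dose_map_from_image(img2, v_cut = 0.3, calibration = g$cell_size)
  expect_equal(sum(dm2$deposited[195:200, ]), 0)     # and gone post-cut

  dark <- rgb_image(array(0.1, c(4, 4, 3)), "sRGB")
  expect_error(dose_map_from_image(dark, v_cut = 0.5, calibration = 1),
               "empty mask")
})
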