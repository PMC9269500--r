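test_that("forward projection of a uniform disk matches 2*mu*sqrt(R^2 - s^2)", {
  N <- 128; R <- 40; mu <- 1
  xs <- seq_len(N) - (N + 1) / 2
  disk <- matrix(0, N, N)
  disk[outer(xs, xs, function(a, b) a^2 + b^2) <= R^2] <- mu
  angles <- seq(0, 165, by = 15)
  sg <- forward_radon(disk, angles)
  analytic <- 2 * mu * sqrt(pmax(R^2 - xs^2, 0))
  for (a in seq_along(angles)) {
    # discretization at the rim dominates; bound the error by 2 detector bins
    err <- abs(sg$intensities[a, ] - analytic)
    expect_lt(stats::median(err), 0.5)
    expect_lt(max(err) / max(analytic), 2 / (2 * R))
  }
  # mass conservation: total intensity equal across angles within 0.1%
  mass <- rowSums(sg$intensities)
  expect_lt((max(mass) - min(mass)) / mean(mass), 1e-3)
})

test_that("a single bright pixel projects to a near-constant profile and a sinusoid", {
  N <- 101
  img <- matrix(0, N, N); img[51, 51] <- 1           # centred point
  sg <- forward_radon(img, seq(0, 179, by = 7))
  # a point has no extent: its projected mass varies only through the
  # interpolation footprint, and its peak stays at the centre bin
  expect_lt(stats::sd(rowSums(sg$intensities)) / mean(rowSums(sg$intensities)),
            0.15)
  expect_true(all(abs(apply(sg$intensities, 1, which.max) - 51) <= 1))
  # off-centre point: detector trace is a sinusoid with amplitude = radius
  img2 <- matrix(0, N, N); img2[51, 71] <- 1         # 20 px along +x
  angles <- seq(0, 350, by = 10)
  sg2 <- forward_radon(img2, angles)
  com <- apply(sg2$intensities, 1, function(p) sum(p * seq_len(N)) / sum(p)) - 51
  fit <- stats::lm(com ~ cos(angles * pi / 180) + sin(angles * pi / 180) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  expect_equal(amp, 20, tolerance = 0.05)
  expect_lt(max(abs(stats::residuals(fit))), 1)
})

test_that("translated images shift traces by the projected offset", {
  N <- 101
  base <- matrix(0, N, N); base[41, 46] <- 1
  shifted <- matrix(0, N, N); shifted[41, 66] <- 1   # +20 along x
  angles <- c(0, 30, 60, 90)
  s1 <- forward_radon(base, angles); s2 <- forward_radon(shifted, angles)
  for (a in seq_along(angles)) {
    c1 <- sum(s1$intensities[a, ] * seq_len(N)) / sum(s1$intensities[a, ])
    c2 <- sum(s2$intensities[a, ] * seq_len(N)) / sum(s2$intensities[a, ])
    expect_equal(c2 - c1, 20 * cos(angles[a] * pi / 180), tolerance = 0.1)
  }
})

test_that("FBP round trip on the T-bar phantom and filter behavior", {
  truth <- phantom_slice_truth(t_bar_phantom(), 160)
  sg <- forward_radon(truth, seq(0, 179, length.out = 180))
  rec <- inverse_radon_fbp(sg)
  expect_lt(nrmse_in_circle(rec$image, truth), 0.1)

  # reconstruction scales linearly with input intensity
  sg3 <- sinogram(sg$intensities * 3, sg$angles)
  rec3 <- inverse_radon_fbp(sg3)
  expect_equal(rec3$image, rec$image * 3, tolerance = 1e-9)

  # unfiltered back-projection is blurred: lower normalized contrast
  rec0 <- inverse_radon_fbp(sg, filter = "none")
  contrast <- function(m) (max(m) - min(m)) / mean(abs(m))
  expect_lt(contrast(rec0$image), contrast(rec$image))

  # a point phantom is recovered within one pixel
  pt <- matrix(0, 101, 101); pt[71, 41] <- 1
  rp <- inverse_radon_fbp(forward_radon(pt, seq(0, 179, length.out = 90)))
  at <- which(rp$image == max(rp$image), arr.ind = TRUE)
  expect_lte(max(abs(at - c(71, 41))), 1)

  # angular coverage below 180 degrees is rejected
  half <- sg$angles < 90
  expect_error(inverse_radon_fbp(sinogram(sg$intensities[half, ], sg$angles[half])),
               "insufficient angular coverage")
})

test_that("sinograms from frame stacks follow the angle and averaging rules", {
  f <- array(stats::runif(8 * 8), c(8, 8, 4))
  f[, , 2] <- f[, , 1]; f[, , 3] <- f[, , 1]; f[, , 4] <- f[, , 1]
  st <- frame_stack(f, rotation_period = 4, baseline_row = 5)
  sg <- sinogram_from_frames(st)
  expect_equal(sg$angles, c(0, 90, 180, 270))
  expect_equal(sg$intensities[1, ], sg$intensities[3, ])  # identical frames

  # multiple revolutions are averaged per angle
  f2 <- array(0, c(4, 4, 8))
  f2[2, , seq(1, 8, by = 4)] <- 1           # angle 0 frames: rows 1 and 5
  f2[2, , seq(2, 8, by = 4)] <- 3
  st2 <- frame_stack(f2, rotation_period = 4, baseline_row = 2)
  sg2 <- sinogram_from_frames(st2)
  expect_equal(unique(sg2$intensities[1, ]), 1)
  expect_equal(unique(sg2$intensities[2, ]), 3)

  expect_error(frame_stack(list(matrix(0, 3, 3), matrix(0, 4, 4)), 2, 1),
               "mixed size")
  expect_error(frame_stack(f, rotation_period = 9, baseline_row = 1),
               "revolution")
})

test_that("phantom truth, generated frames and forward projection are consistent", {
  expect_equal(phantom_slice_truth(NULL, 32), matrix(0, 32, 32))
  vial <- t_bar_phantom(bar_radius = 1e-3, bar_center = c(0, 0),
                        holes = list(), mu = list(glass = 1, liquid = 0.4,
                                                  bar = 0.4, hole = 0))
  img <- phantom_slice_truth(vial, 64)
  expect_equal(sort(unique(as.numeric(img))), c(0, 0.4, 1))  # annulus + interior

  spec <- rot_phantom_spec(n_frames = 120, frames_per_rev = 120, width = 160,
                           height = 12, baseline_row = 6)
  stack <- render_rotation_frames(spec)
  sino <- sinogram_from_frames(stack, as_optical_density = TRUE, i0 = 1)
  truth <- phantom_slice_truth(spec$phantom, spec$width)
  ref <- forward_radon(truth, sino$angles)
  nr <- sqrt(mean((sino$intensities - ref$intensities)^2)) /
    (max(ref$intensities) - min(ref$intensities))
  expect_lt(nr, 0.05)

  # rotating bright point: sinusoid amplitude equals its radius (in pixels)
  pt <- t_bar_phantom(bar_radius = 0.04, bar_center = c(0.5, 0),
                      holes = list(),
                      mu = list(glass = 0, liquid = 0, bar = 3, hole = 0),
                      vial_wall = 0)
  specp <- rot_phantom_spec(phantom = pt, n_frames = 90, frames_per_rev = 90,
                            width = 120, height = 6, baseline_row = 3)
  sp <- sinogram_from_frames(render_rotation_frames(specp),
                             as_optical_density = TRUE, i0 = 1)
  com <- apply(sp$intensities, 1, function(p) sum(p * seq_len(120)) / sum(p)) -
    (120 + 1) / 2
  th <- sp$angles * pi / 180
  fit <- stats::lm(com ~ cos(th) + sin(th) - 1)
  expect_equal(sqrt(sum(stats::coef(fit)^2)), 0.5 * 60, tolerance = 0.05)
})

test_that("zero-attenuation phantoms render constant frames", {
  empty <- t_bar_phantom(mu = list(glass = 0, liquid = 0, bar = 0, hole = 0))
  spec <- rot_phantom_spec(phantom = empty, n_frames = 10, frames_per_rev = 10,
                           width = 32, height = 6, baseline_row = 3)
  stack <- render_rotation_frames(spec)
  expect_equal(max(stack$frames) - min(stack$frames), 0)
  expect_equal(unique(as.numeric(stack$frames)), 1)
})
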