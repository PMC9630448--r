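test_that("disc thickness maps have the right value, support and area", {
  tm <- disc_thickness(128, radius_px = 30, thickness = 6e-3,
                       upsample = 5)
  n <- 128 * 5
  expect_equal(dim(tm$values), c(n, n))
  expect_equal(tm$values[n / 2, n / 2], 6e-3)   # centre
  expect_identical(tm$values[1, 1], 0)          # corner
  area <- sum(tm$values) / 6e-3
  expect_lt(abs(area / (pi * (30 * 5)^2) - 1), 1e-3)
  expect_error(disc_thickness(64, radius_px = 40), "radius")
})

test_that("contact intensity follows the attenuation law", {
  opt <- pmma24()
  t0 <- matrix(0, 8, 8)
  expect_equal(contact_intensity(t0, opt, I0 = 2)$intensity,
               matrix(2, 8, 8))
  nomu <- material_optics(delta = 1e-7, mu = 0, energy = 24)
  tmap <- matrix(5e-3, 8, 8)
  expect_equal(contact_intensity(tmap, nomu)$intensity, matrix(1, 8, 8))
  # doubling the thickness squares the transmission factor
  i1 <- contact_intensity(tmap, opt)$intensity[1, 1]
  i2 <- contact_intensity(2 * tmap, opt)$intensity[1, 1]
  expect_equal(i2, i1^2)
  # the phase map scales with delta * T
  ph <- contact_intensity(tmap, opt)$phase[1, 1]
  expect_equal(ph, -2 * pi / opt$wavelength * opt$delta * 5e-3)
})

test_that("TIE propagation is the identity at zero distance and on flats", {
  opt <- water24()
  img <- smooth_image(32)
  expect_identical(tie_propagate(img, opt, 0, 25e-6), img)
  u <- matrix(0.7, 32, 32)
  expect_equal(tie_propagate(u, opt, 0.05, 25e-6), u, tolerance = 1e-13)
  # flux conservation (unit DC gain)
  p <- tie_propagate(img, opt, 0.05, 25e-6)
  expect_lt(abs(sum(p) / sum(img) - 1), 1e-10)
})

test_that("edge fringes grow with propagation distance", {
  opt <- water24()
  sim1 <- simulate_disc_projection(opt, shape = 128, radius_px = 50,
                                   distance = 5e-3, upsample = 2)
  sim2 <- simulate_disc_projection(opt, shape = 128, radius_px = 50,
                                   distance = 20e-3, upsample = 2)
  over1 <- max(sim1$propagated) - 1
  over2 <- max(sim2$propagated) - 1
  expect_gt(over1, 0)
  expect_gt(over2 / over1, 1)
})

test_that("gaussian blur conserves flux and has the stated width", {
  img <- smooth_image(32)
  expect_identical(gaussian_blur(img, 0), img)
  b <- gaussian_blur(img, 2.5)
  expect_lt(abs(sum(b) / sum(img) - 1), 1e-10)
  # blurred point source: fitted FWHM within 1 %
  n <- 64
  delta_img <- matrix(0, n, n)
  delta_img[n / 2, n / 2] <- 1
  for (fw in c(3, 5)) {
    psf <- gaussian_blur(delta_img, fw)
    fit <- fit_pearson7(seq_len(n), psf[, n / 2])
    expect_lt(abs(fit$fwhm / fw - 1), 0.01)
  }
})

test_that("block downsampling and rebinning are mean-preserving", {
  expect_equal(downsample_block(matrix(1, 2, 2), 2),
               matrix(1, 1, 1))
  set.seed(5)
  m <- matrix(runif(64 * 64), 64)
  d <- downsample_block(m, 4)
  expect_identical(dim(d), c(16L, 16L))
  expect_lt(abs(mean(d) - mean(m)), 1e-12)
  expect_error(downsample_block(m, 3), "divisible")
  # composition of block means
  expect_lt(max(abs(rebin(rebin(m, 2), 2) - rebin(m, 4))), 1e-12)
  expect_identical(rebin(m, 1), m)
  # geometry bookkeeping: W scales up, PSF (in px) and Nyquist scale down
  geom <- imaging_geometry(6.5e-6, 2, 2.4, 64)
  g2 <- rebin(geom, 2)
  expect_equal(g2$pixel_size, 13e-6)
  expect_equal(g2$psf_fwhm, 1.2)
  expect_equal(g2$shape, c(32L, 32L))
  expect_equal((pi / g2$pixel_size) * 2, pi / geom$pixel_size)
})

test_that("the projection pipeline is deterministic and collapses when
           phase contrast is absent", {
  # delta = 0 and no detector PSF: pc, pm, gpm all equal the blurred
  # attenuation disc
  opt0 <- material_optics(delta = 0, mu = 51.1, energy = 24)
  res <- simulate_fig2_case(0, opt0, shape = 64, radius_px = 24,
                            distance = 8e-3, upsample = 2)
  expect_equal(res$pc, res$pm, tolerance = 1e-13)
  expect_equal(res$pc, res$gpm, tolerance = 1e-13)
  # bit-identical reruns (no randomness anywhere)
  opt <- water24()
  r1 <- simulate_fig2_case(1, opt, shape = 64, radius_px = 24,
                           distance = 8e-3, upsample = 2)
  r2 <- simulate_fig2_case(1, opt, shape = 64, radius_px = 24,
                           distance = 8e-3, upsample = 2)
  expect_identical(r1$gpm, r2$gpm)
})

test_that("matched-kernel retrieval inverts the upsampled forward model", {
  opt <- water24()
  sim <- simulate_disc_projection(opt, shape = 64, radius_px = 24,
                                  distance = 8e-3, upsample = 2)
  # redo the forward step on the upsampled grid and invert it there
  tm <- disc_thickness(64, 24, 6e-3, 2)
  tv <- pmax(gaussian_blur(tm$values, 2), 0)
  contact <- contact_intensity(tv, opt)$intensity
  up_geom <- imaging_geometry(25e-6 / 2, 8e-3, 0, 128)
  for (kern in c("pm", "gpm")) {
    prop <- tie_propagate(contact, opt, 8e-3, 25e-6 / 2, kernel = kern)
    back <- phase_retrieve(prop, 1, opt, up_geom, kern)
    expect_lt(max(abs(back - contact)), 1e-10)
  }
})

test_that("the tuned distance produces a just-visible fringe", {
  opt <- water24()
  d <- tune_distance(opt, 25e-6)
  expect_gt(d, 0)
  sim <- simulate_disc_projection(opt, shape = 128, radius_px = 50,
                                  distance = d, upsample = 4)
  step <- 1 - exp(-opt$mu * 6e-3)
  overshoot <- (max(sim$propagated) - 1) / step
  expect_gt(overshoot, 0.02)
  expect_lt(overshoot, 0.06)
})

test_that("rebinned retrieval improves more at larger rebin factors", {
  tr <- rebin_resolution_trend(factors = c(1L, 4L), shape = 256L,
                               radius_px = 100.25, upsample = 2L)
  expect_true(all(tr$gamma_gpm <= tr$gamma_pm))
  expect_gt(tr$improvement[2], tr$improvement[1])
})
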