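test_that("squared-frequency maps match their closed forms", {
  g <- frequency_grid(8, 1)
  k2p <- k_perp2_pm(g)
  k2g <- k_perp2_gpm(g)
  # DC and Nyquist values
  expect_identical(k2p[1, 1], 0)
  expect_identical(k2g[1, 1], 0)
  expect_equal(k2p[5, 1], pi^2)
  expect_equal(k2g[5, 1], 4)
  expect_true(max(k2g) <= 8 + 1e-12)
  # symmetry under (kx, ky) -> (ky, kx)
  expect_equal(k2p, t(k2p))
  expect_equal(k2g, t(k2g))
  # index-negation symmetry up to DFT wrap
  n <- 8
  for (i in 2:(n - 1)) {
    expect_equal(k2p[i + 1, 1], k2p[n - i + 1, 1])
    expect_equal(k2g[1, i + 1], k2g[1, n - i + 1])
  }
})

test_that("the discrete kernel converges to the continuous one near DC", {
  # Wk = 1e-3: relative agreement better than 1e-6
  n <- 6284L  # first non-DC sample at Wk = 2*pi/n ~ 1e-3
  g <- frequency_grid(c(n, 2L), 1)
  wk <- g$kx[2]
  expect_lt(wk, 1.1e-3)
  rel <- abs(k_perp2_gpm(g)[2, 1] - k_perp2_pm(g)[2, 1]) / wk^2
  expect_lt(rel, 1e-6)
  # W -> 0 at fixed physical k: Wk = 1e-4 agrees to 1e-7
  n2 <- 62832L
  g2 <- frequency_grid(c(n2, 2L), 1e-6)
  rel2 <- abs(k_perp2_gpm(g2)[2, 1] / k_perp2_pm(g2)[2, 1] - 1)
  expect_lt(rel2, 1e-7)
})

test_that("transfer functions evaluate the Lorentzian filters", {
  g <- frequency_grid(8, 1)
  hp <- transfer_function(g, delta = 10, mu = 1, distance = 1, "pm")
  hg <- transfer_function(g, delta = 10, mu = 1, distance = 1, "gpm")
  expect_equal(hp[1, 1], 1)
  expect_equal(hg[1, 1], 1)
  expect_equal(hg[5, 1], 1 / 41)
  expect_equal(hp[5, 1], 1 / (1 + 10 * pi^2))
  expect_true(all(hp > 0 & hp <= 1))
  expect_true(all(hg > 0 & hg <= 1))
  # delta = 0 collapses to the identity
  expect_equal(transfer_function(g, 0, 1, 1, "pm"),
               matrix(1, 8, 8))
  expect_error(transfer_function(g, 1, 0, 1, "pm"), "invalid material")
})

test_that("the Gaussian CTF is a unit-DC monotone attenuator", {
  g <- frequency_grid(16, 25e-6)
  expect_equal(gaussian_ctf(g, 0), matrix(1, 16, 16))
  g1 <- gaussian_ctf(g, 1)
  g3 <- gaussian_ctf(g, 3)
  expect_equal(g1[1, 1], 1)
  expect_true(all(g3[-1] < g1[-1]))
  # monotone decreasing with |k| along the axis (0 .. Nyquist)
  expect_true(all(diff(g1[1:9, 1]) < 0))
})

test_that("fractional difference and ratio follow the filter algebra", {
  g <- frequency_grid(8, 1)
  d <- fractional_difference(g, 10, 1, 1)
  r <- transfer_ratio(g, 10, 1, 1)
  expect_equal(d[1, 1], 0)
  expect_equal(r[1, 1], 1)
  expect_equal(d[5, 1], (1 + 10 * pi^2) / 41 - 1)
  expect_equal(r[5, 1], (1 + 10 * pi^2) / 41)
  expect_true(all(d >= 0))
  expect_true(all(r >= 1))
  # with a PSF the difference is G * D, so it can only shrink
  db <- fractional_difference(g, 10, 1, 1, psf_fwhm = 3)
  expect_true(all(db <= d + 1e-15))
  expect_equal(db, gaussian_ctf(g, 3) * d)
  # normalized diagonal abscissa reaches past pi in the corners
  kr <- g$pixel_size * sqrt(outer(g$kx^2, g$ky^2, "+"))
  expect_gt(max(diag(kr)), pi)
})

test_that("the ratio is non-decreasing along the frequency axis", {
  # brute-force scan over a dense 1-D grid
  g <- frequency_grid(c(4096L, 2L), 1)
  r <- transfer_ratio(g, 10, 1, 1)[, 1]
  half <- 1:(4096L / 2 + 1)  # 0 .. Nyquist
  expect_true(all(diff(r[half]) >= -1e-14))
})

test_that("kernel dominance holds across random filter strengths", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(8:48, 1)
    W <- 10^runif(1, -6, -4)
    coef <- 10^runif(1, -2, 4) * W^2  # delta*Delta/mu, spanning decades
    g <- frequency_grid(n, W)
    expect_true(all(k_perp2_gpm(g) <= k_perp2_pm(g) + 1e-9 / W^2))
    hp <- 1 / (1 + coef * k_perp2_pm(g))
    hg <- 1 / (1 + coef * k_perp2_gpm(g))
    expect_true(all(hg >= hp))
  }
})

test_that("phase retrieval preserves DC and inverts the forward filter", {
  opt <- water24()
  geom <- imaging_geometry(25e-6, 9e-3, 0, 32)
  # uniform in, uniform out (only DC)
  u <- matrix(3, 32, 32)
  expect_equal(phase_retrieve(u, 1.5, opt, geom, "pm"),
               matrix(2, 32, 32))
  # delta = 0: the image/I0 passes through unchanged
  opt0 <- material_optics(delta = 0, mu = opt$mu, energy = 24)
  img <- smooth_image(32)
  expect_equal(phase_retrieve(img, 1, opt0, geom, "gpm"), img,
               tolerance = 1e-12)
  # exact Fourier inversion round trip with the matched kernel
  prop <- tie_propagate(img, opt, geom$distance, geom$pixel_size)
  expect_lt(max(abs(phase_retrieve(prop, 1, opt, geom, "pm") - img)),
            1e-10)
  # mean preservation (unit DC gain)
  expect_equal(mean(phase_retrieve(img, 1, opt, geom, "gpm")), mean(img))
})

test_that("phase retrieval is linear in image/I0", {
  opt <- water24()
  geom <- imaging_geometry(25e-6, 9e-3, 0, 16)
  set.seed(7)
  X <- matrix(runif(256, 0.5, 1.5), 16)
  Y <- matrix(runif(256, 0.5, 1.5), 16)
  for (kern in c("pm", "gpm")) {
    lhs <- phase_retrieve(2 * X + 3 * Y, 1, opt, geom, kern)
    rhs <- 2 * phase_retrieve(X, 1, opt, geom, kern) +
      3 * phase_retrieve(Y, 1, opt, geom, kern)
    expect_lt(max(abs(lhs - rhs)), 1e-12)
  }
})

test_that("retrieval agrees with a direct discrete-Fourier-sum oracle", {
  set.seed(11)
  img <- matrix(runif(64, 0.5, 1.5), 8, 8)
  opt <- water24()
  geom <- imaging_geometry(25e-6, 9e-3, 0, 8)
  coef <- opt$delta * geom$distance / opt$mu
  for (kern in c("pm", "gpm")) {
    got <- phase_retrieve(img, 1, opt, geom, kern)
    want <- naive_retrieve(img, coef, geom$pixel_size, kern)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("retrieval validates its inputs", {
  opt <- water24()
  geom <- imaging_geometry(25e-6, 9e-3, 0, 8)
  img <- matrix(1, 8, 8)
  expect_error(phase_retrieve(img, matrix(1, 4, 4), opt, geom),
               "shape mismatch")
  expect_error(phase_retrieve(img, 0, opt, geom), "strictly positive")
  bad <- img; bad[3, 3] <- NA
  expect_error(phase_retrieve(bad, 1, opt, geom), "non-finite")
  fixed <- phase_retrieve(bad, 1, opt, geom, repair = TRUE)
  expect_true(all(is.finite(fixed)))
  # padded filtering returns the original dimensions
  expect_identical(dim(phase_retrieve(img, 1, opt, geom, pad = TRUE)),
                   c(8L, 8L))
})

test_that("two-material retrieval reduces to the single-material filter", {
  geom <- imaging_geometry(55e-6, 2, 0, 16)
  al <- builtin_material("aluminium", 40)
  pm40 <- builtin_material("pmma", 40)
  img <- smooth_image(16, seed = 3)
  # equal decrements: zero coefficient, image unchanged
  same_delta <- material_optics(delta = al$delta, mu = 10, energy = 40)
  expect_equal(beltran_retrieve(img, 1,
                                material_optics(al$delta, mu = 99,
                                                energy = 40),
                                same_delta, geom, "pm"),
               img, tolerance = 1e-12)
  # vacuum as material 1 reduces to phase_retrieve
  vac <- material_optics(delta = 0, mu = 0)
  expect_equal(beltran_retrieve(img, 1, vac, al, geom, "gpm"),
               phase_retrieve(img, 1, al, geom, "gpm"),
               tolerance = 1e-12)
  # kernels differ only above DC; means agree
  bpm <- beltran_retrieve(img, 1, pm40, al, geom, "pm")
  bgp <- beltran_retrieve(img, 1, pm40, al, geom, "gpm")
  expect_lt(abs(mean(bpm) - mean(bgp)), 1e-12)
  expect_gt(max(abs(bpm - bgp)), 0)
  expect_error(beltran_retrieve(img, 1, al, al, geom), "degenerate")
})
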