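# Shared fixtures and independent oracles, all generated in code.

water24 <- function() builtin_material("water", 24)
pmma24 <- function() builtin_material("pmma", 24)

# Brute-force O(N^4) discrete-Fourier-sum retrieval, independent of the
# package's FFT path: forward DFT by direct summation, division by the
# Lorentzian filter (kernel formulas written out), inverse sum.
naive_retrieve <- function(image, coef, W, kernel) {
  n1 <- nrow(image)
  n2 <- ncol(image)
  idx <- function(n) {
    h <- n %/% 2
    if (n %% 2 == 0) c(0:h, -((h - 1):1)) else c(0:h, -(h:1))
  }
  kx <- 2 * pi * idx(n1) / (n1 * W)
  ky <- 2 * pi * idx(n2) / (n2 * W)
  k2 <- if (kernel == "pm") {
    outer(kx^2, ky^2, "+")
  } else {
    (-2 / W^2) * outer(cos(W * kx) - 1, cos(W * ky) - 1, "+")
  }
  F <- matrix(0 + 0i, n1, n2)
  for (u in 0:(n1 - 1)) for (v in 0:(n2 - 1)) {
    s <- 0 + 0i
    for (x in 0:(n1 - 1)) for (y in 0:(n2 - 1))
      s <- s + image[x + 1, y + 1] *
        exp(-2i * pi * (u * x / n1 + v * y / n2))
    F[u + 1, v + 1] <- s / (1 + coef * k2[u + 1, v + 1])
  }
  out <- matrix(0, n1, n2)
  for (x in 0:(n1 - 1)) for (y in 0:(n2 - 1)) {
    s <- 0 + 0i
    for (u in 0:(n1 - 1)) for (v in 0:(n2 - 1))
      s <- s + F[u + 1, v + 1] *
        exp(2i * pi * (u * x / n1 + v * y / n2))
    out[x + 1, y + 1] <- Re(s) / (n1 * n2)
  }
  out
}

# Analytic circular step edge of radius R blurred by a Gaussian of the
# given FWHM, sampled at pixel centres: I(r) = Phi((r - R) / sigma).
blurred_disc_edge <- function(n, radius, fwhm) {
  centre <- n / 2 + 0.5
  rr <- sqrt(outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, "+"))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  list(image = pnorm((rr - radius) / sigma),
       centre = c(centre, centre), radius = radius)
}

# Smooth strictly positive test image (sum of Gaussian bumps).
smooth_image <- function(n, seed = 1) {
  set.seed(seed)
  xx <- outer(seq(-1, 1, length.out = n), rep(1, n))
  yy <- t(xx)
  img <- matrix(1, n, n)
  for (i in 1:4) {
    cx <- runif(1, -0.5, 0.5)
    cy <- runif(1, -0.5, 0.5)
    img <- img + runif(1, -0.2, 0.3) *
      exp(-((xx - cx)^2 + (yy - cy)^2) / runif(1, 0.02, 0.2))
  }
  img
}
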