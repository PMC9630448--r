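# Minimal parallel-beam CT support: flat/dark correction, an analytic
# disc sinogram fixture, and ramp-filtered back projection.

#' Flat-field and dark-current correction
#'
#' (raw - dark) / (flat - dark), elementwise.
#'
#' @param raw,flat,dark Numeric matrices of one shape (`flat > dark`
#'   everywhere); `flat` and `dark` may also be scalars.
#' @return Normalised intensity matrix.
#' @export
flat_dark_correct <- function(raw, flat, dark = 0) {
  raw <- .as_matrix_image(raw, "raw")
  denom <- flat - dark
  if (any(denom <= 0)) stop("`flat` must exceed `dark` everywhere")
  (raw - dark) / denom
}

#' Analytic sinogram of a uniform disc
#'
#' Parallel projections of a centred uniform disc: the chord length
#' 2 * value * sqrt(r^2 - s^2) for |s| <= r, identical at every angle.
#' Used as an analytic fixture for reconstruction tests.
#'
#' @param radius Disc radius in detector pixels.
#' @param value Disc density (reconstruction target value).
#' @param n_angles Number of projection angles, uniformly spaced over
#'   [0, 180) degrees.
#' @param n_det Number of detector pixels (`radius < n_det/2`).
#' @param pixel_size Detector pixel size (defaults to 1; all radii in
#'   pixel units).
#' @return An object of class `sinogram`: list with `values`
#'   (n_angles x n_det matrix), `angles` (degrees) and `pixel_size`.
#' @export
disc_sinogram <- function(radius, value, n_angles, n_det,
                          pixel_size = 1) {
  stopifnot(radius > 0, n_angles >= 1, n_det >= 2)
  if (radius >= n_det / 2)
    stop("disc radius must be smaller than the detector half-width")
  s <- seq_len(n_det) - (n_det + 1) / 2
  chord <- 2 * value * sqrt(pmax(radius^2 - s^2, 0))
  structure(list(values = matrix(chord, n_angles, n_det, byrow = TRUE),
                 angles = seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)],
                 pixel_size = pixel_size),
            class = "sinogram")
}

#' Sinogram constructor
#'
#' @param values Numeric matrix, angles in rows and detector pixels in
#'   columns.
#' @param angles Strictly increasing projection angles in degrees over
#'   [0, 180).
#' @param pixel_size Detector pixel size.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, angles, pixel_size = 1) {
  values <- .as_matrix_image(values, "values")
  stopifnot(length(angles) == nrow(values), all(diff(angles) > 0),
            all(is.finite(values)), all(angles >= 0), all(angles < 180))
  structure(list(values = values, angles = angles,
                 pixel_size = pixel_size),
            class = "sinogram")
}

#' Filtered back projection with a ramp filter
#'
#' Parallel-beam reconstruction: each projection is convolved with the
#' discrete ramp (Ram-Lak) kernel via FFT on a zero-padded axis, then
#' back-projected with linear interpolation onto a grid equal to the
#' detector-pixel grid.  The operator is linear and maps a zero sinogram
#' to a zero slice.  Angles must be uniformly spaced.
#'
#' @param sino A `sinogram` (see [disc_sinogram()], [sinogram()]).
#' @param axis_shift Sub-pixel shift of the rotation axis from the
#'   centred detector column, in pixels.
#' @return Reconstructed slice matrix (n_det x n_det), in units of
#'   density per pixel.
#' @export
fbp_reconstruct <- function(sino, axis_shift = 0) {
  stopifnot(inherits(sino, "sinogram"))
  p <- sino$values
  n_ang <- nrow(p)
  n_det <- ncol(p)
  if (n_ang < 2) stop("at least 2 angles are required")
  dth <- diff(sino$angles)
  if (max(abs(dth - dth[1])) > 1e-9 * dth[1])
    stop("non-uniform angle spacing is not supported")
  # discrete Ram-Lak kernel (detector spacing = 1 pixel unit)
  m <- 2^ceiling(log2(2 * n_det))
  n <- c(0:(m / 2), -(m / 2 - 1):-1)
  h <- numeric(m)
  h[n == 0] <- 1 / 4
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2)
  Hf <- Re(fft(h))
  filt <- matrix(0, n_ang, m)
  filt[, seq_len(n_det)] <- p
  filt <- t(apply(filt, 1, function(row)
    Re(fft(fft(row) * Hf, inverse = TRUE)) / m))[, seq_len(n_det),
                                                 drop = FALSE]
  # back projection on the detector-pixel grid
  ax <- (n_det + 1) / 2 + axis_shift
  x <- seq_len(n_det) - ax          # slice columns
  y <- seq_len(n_det) - ax          # slice rows
  recon <- matrix(0, n_det, n_det)
  th <- sino$angles * pi / 180
  X <- outer(rep(1, n_det), x)
  Y <- outer(y, rep(1, n_det))
  for (a in seq_len(n_ang)) {
    s <- X * cos(th[a]) + Y * sin(th[a]) + ax
    j0 <- floor(s)
    w <- s - j0
    inside <- j0 >= 1 & j0 < n_det
    v <- numeric(length(s))
    jj <- j0[inside]
    v[inside] <- (1 - w[inside]) * filt[a, jj] + w[inside] * filt[a, jj + 1]
    recon <- recon + v
  }
  recon * pi / n_ang
}
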