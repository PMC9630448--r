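# Frequency-space kernels and transfer functions for single-distance
# TIE phase retrieval, in the continuous (PM) and discrete-Laplacian
# (GPM) forms, plus their combination with a Gaussian detector CTF.

#' Squared frequency map of the continuous (PM) kernel
#'
#' The perpendicular wavevector magnitude squared, kx^2 + ky^2, as used
#' by the classical Lorentzian retrieval filter derived with the
#' continuous Fourier derivative theorem.
#'
#' @param grid A [frequency_grid].
#' @return Matrix of kx^2 + ky^2 in rad^2/m^2, zero at DC.
#' @seealso [k_perp2_gpm()]
#' @export
k_perp2_pm <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  outer(grid$kx^2, grid$ky^2, "+")
}

#' Squared frequency map of the discrete (GPM) kernel
#'
#' The cosine kernel -(2/W^2) * (cos(W*kx) + cos(W*ky) - 2) arising from
#' the five-point finite-difference Laplacian, which replaces kx^2 + ky^2
#' when the Fourier derivative theorem is written for sampled images.
#' It agrees with [k_perp2_pm()] near DC and is bounded by 8/W^2.
#'
#' @inheritParams k_perp2_pm
#' @return Matrix in rad^2/m^2, zero at DC.
#' @export
k_perp2_gpm <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  W <- grid$pixel_size
  cx <- cos(W * grid$kx) - 1
  cy <- cos(W * grid$ky) - 1
  (-2 / W^2) * outer(cx, cy, "+")
}

.kernel_choice <- function(kernel) {
  match.arg(tolower(kernel), c("pm", "gpm"))
}

.k_perp2 <- function(grid, kernel) {
  switch(.kernel_choice(kernel),
         pm = k_perp2_pm(grid),
         gpm = k_perp2_gpm(grid))
}

.filter_coef <- function(delta, mu, distance) {
  stopifnot(is.numeric(delta), delta >= 0, is.numeric(distance),
            distance >= 0)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("invalid material: `mu` must be a single positive number")
  delta * distance / mu
}

#' Phase-retrieval transfer function
#'
#' The per-frequency amplification H = 1 / (1 + (delta*Delta/mu) * k2)
#' applied to the flat-corrected image by the retrieval filter, with k2
#' the squared-frequency map of the chosen kernel.  H is 1 at DC and
#' lies in (0, 1].
#'
#' @param grid A [frequency_grid].
#' @param delta Refractive-index decrement.
#' @param mu Linear attenuation coefficient in 1/m (`> 0`).
#' @param distance Propagation distance in metres.
#' @param kernel `"pm"` or `"gpm"`.
#' @return Matrix of amplifications in (0, 1].
#' @export
transfer_function <- function(grid, delta, mu, distance,
                              kernel = c("pm", "gpm")) {
  coef <- .filter_coef(delta, mu, distance)
  1 / (1 + coef * .k_perp2(grid, kernel))
}

#' Gaussian detector contrast transfer function
#'
#' Fourier transform of a unit-integral, azimuthally symmetric real-space
#' Gaussian point spread function of full width at half maximum
#' `psf_fwhm` pixels: G = exp(-sigma^2 (kx^2+ky^2) / 2) with
#' sigma = psf_fwhm * W / (2 sqrt(2 ln 2)).  G(0,0) = 1 and G decreases
#' monotonically with |k|; a zero-width PSF gives the identity.
#'
#' @param grid A [frequency_grid].
#' @param psf_fwhm PSF full width at half maximum, in pixels (`>= 0`).
#' @return Matrix of attenuations in (0, 1].
#' @export
gaussian_ctf <- function(grid, psf_fwhm) {
  stopifnot(is.numeric(psf_fwhm), length(psf_fwhm) == 1L, psf_fwhm >= 0)
  if (psf_fwhm == 0)
    return(matrix(1, grid$shape[1], grid$shape[2]))
  sigma <- psf_fwhm * grid$pixel_size / (2 * sqrt(2 * log(2)))
  exp(-sigma^2 * k_perp2_pm(grid) / 2)
}

#' Fractional difference between the GPM and PM transfer functions
#'
#' Without a PSF, D = (H_GPM - H_PM) / H_PM, which is zero at DC and
#' non-negative everywhere because the discrete kernel suppresses high
#' frequencies less.  With a PSF of width `psf_fwhm`, the blurred
#' transfer functions Hbar = H * G are compared but the denominator stays
#' the unblurred H_PM, so the result equals G * D.
#'
#' @inheritParams transfer_function
#' @param psf_fwhm Detector PSF FWHM in pixels, or `NULL` for no PSF.
#' @return Matrix of fractional differences, `>= 0`.
#' @export
fractional_difference <- function(grid, delta, mu, distance,
                                  psf_fwhm = NULL) {
  hp <- transfer_function(grid, delta, mu, distance, "pm")
  hg <- transfer_function(grid, delta, mu, distance, "gpm")
  d <- (hg - hp) / hp
  if (!is.null(psf_fwhm)) d <- gaussian_ctf(grid, psf_fwhm) * d
  d
}

#' Ratio of the GPM to the PM transfer function
#'
#' R = H_GPM / H_PM, equal to 1 at DC and `>= 1` everywhere on the grid.
#'
#' @inheritParams transfer_function
#' @return Matrix of ratios, `>= 1`.
#' @export
transfer_ratio <- function(grid, delta, mu, distance) {
  transfer_function(grid, delta, mu, distance, "gpm") /
    transfer_function(grid, delta, mu, distance, "pm")
}

# Shared Fourier filtering core for the retrieval operators.
# coef = delta*Delta/mu (or its two-material analogue), in m^2.
.retrieve_with_coef <- function(image, I0, coef, pixel_size, kernel,
                                pad = FALSE, repair = FALSE) {
  image <- .as_matrix_image(image)
  if (is.matrix(I0)) {
    if (!all(dim(I0) == dim(image)))
      stop("shape mismatch between `image` and `I0` map")
  } else {
    stopifnot(is.numeric(I0), length(I0) == 1L)
  }
  if (any(I0 <= 0)) stop("`I0` must be strictly positive")
  ratio <- image / I0
  bad <- !is.finite(ratio) | ratio <= 0
  if (any(bad)) {
    if (!repair)
      stop("non-finite or non-positive pixels in image/I0; ",
           "set repair = TRUE to clip them")
    eps <- 1e-12 * stats::median(ratio[!bad])
    ratio[bad] <- eps
  }
  if (pad) {
    d0 <- dim(ratio)
    ratio <- .mirror_pad(ratio)
  }
  grid <- frequency_grid(dim(ratio), pixel_size)
  filt <- 1 / (1 + coef * .k_perp2(grid, kernel))
  out <- Re(fft(fft(ratio) * filt, inverse = TRUE)) / length(ratio)
  if (pad) out <- out[seq_len(d0[1]), seq_len(d0[2]), drop = FALSE]
  out
}

# Symmetric (mirror) extension to twice the size along both axes, making
# the periodic extension continuous for wraparound-sensitive inputs.
.mirror_pad <- function(m) {
  m2 <- rbind(m, m[rev(seq_len(nrow(m))), , drop = FALSE])
  cbind(m2, m2[, rev(seq_len(ncol(m))), drop = FALSE])
}

#' Single-material phase retrieval (PM or GPM)
#'
#' Reconstructs the contact-plane intensity from a single propagation
#' distance image of a homogeneous object: the flat-corrected image is
#' divided in Fourier space by 1 + (delta*Delta/mu) * k2 with k2 either
#' the continuous kernel (`"pm"`) or the discrete cosine kernel
#' (`"gpm"`).  The operation is linear in `image/I0` and preserves the
#' image mean (unit DC gain).
#'
#' @param image Numeric matrix of measured intensities at distance Delta.
#' @param I0 Incident (flat) intensity: scalar or matrix of `image`'s
#'   shape; strictly positive.
#' @param optics A [material_optics] for the (single) object material.
#' @param geom An [imaging_geometry] supplying the pixel size and
#'   propagation distance.
#' @param kernel `"pm"` or `"gpm"`.
#' @param pad If `TRUE`, apply the filter on a symmetric (mirror)
#'   extension of the image to suppress wraparound.
#' @param repair If `TRUE`, clip non-finite or non-positive pixels of
#'   `image/I0` to 1e-12 of the median instead of erroring.
#' @return Matrix of retrieved contact-plane intensities (relative to
#'   `I0`).
#' @examples
#' geom <- imaging_geometry(25e-6, 4e-3)
#' opt <- builtin_material("water", 24)
#' img <- matrix(1, 16, 16); img[6:10, 6:10] <- 0.9
#' ret <- phase_retrieve(img, 1, opt, geom, "gpm")
#' all.equal(mean(ret), mean(img))
#' @export
phase_retrieve <- function(image, I0, optics, geom,
                           kernel = c("pm", "gpm"), pad = FALSE,
                           repair = FALSE) {
  stopifnot(inherits(optics, "material_optics"),
            inherits(geom, "imaging_geometry"))
  coef <- .filter_coef(optics$delta, optics$mu, geom$distance)
  .retrieve_with_coef(image, I0, coef, geom$pixel_size,
                      .kernel_choice(kernel), pad = pad, repair = repair)
}

#' Two-material phase retrieval (PM or GPM form)
#'
#' Low-pass filter matched to the fringe enhancement at the boundary
#' between two known materials, with filter coefficient
#' (delta2 - delta1) * Delta / (mu2 - mu1).  With material 1 set to
#' vacuum (delta1 = mu1 = 0) this reduces to [phase_retrieve()] for
#' material 2.
#'
#' @inheritParams phase_retrieve
#' @param optics1,optics2 [material_optics] of the two materials meeting
#'   at the interface; `mu1 != mu2`.
#' @return Matrix of retrieved contact-plane intensities.
#' @export
beltran_retrieve <- function(image, I0, optics1, optics2, geom,
                             kernel = c("pm", "gpm"), pad = FALSE,
                             repair = FALSE) {
  stopifnot(inherits(optics1, "material_optics"),
            inherits(optics2, "material_optics"),
            inherits(geom, "imaging_geometry"))
  dmu <- optics2$mu - optics1$mu
  if (dmu == 0)
    stop("degenerate material pair: mu1 == mu2")
  coef <- (optics2$delta - optics1$delta) * geom$distance / dmu
  if (coef < 0)
    warning("negative filter coefficient (delta and mu contrasts of ",
            "opposite sign); the filter amplifies high frequencies")
  .retrieve_with_coef(image, I0, coef, geom$pixel_size,
                      .kernel_choice(kernel), pad = pad, repair = repair)
}
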