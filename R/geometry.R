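# Core containers: imaging geometry, material optics, frequency grids.
# All lengths are in metres unless an argument name says otherwise
# (psf_fwhm and phantom radii are in detector pixels, energies in keV).

#' Imaging geometry of a propagation-based imaging setup
#'
#' Bundles the detector pixel size, the sample-to-detector propagation
#' distance and the detector point-spread-function width that together
#' (with the material optics) determine the phase-retrieval filter.
#'
#' @param pixel_size Detector pixel size W in metres (e.g. `25e-6`).
#' @param distance Propagation distance Delta in metres; `>= 0`.
#' @param psf_fwhm Detector PSF full width at half maximum, in pixels.
#' @param shape Integer grid dimensions `c(rows, cols)`; a scalar is
#'   recycled to a square grid.
#' @return An object of class `imaging_geometry`.
#' @examples
#' imaging_geometry(25e-6, 4e-3, psf_fwhm = 1, shape = 512)
#' @export
imaging_geometry <- function(pixel_size, distance = 0, psf_fwhm = 0,
                             shape = NULL) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
            is.numeric(distance), length(distance) == 1L, distance >= 0,
            is.numeric(psf_fwhm), length(psf_fwhm) == 1L, psf_fwhm >= 0)
  if (!is.null(shape)) {
    if (length(shape) == 1L) shape <- c(shape, shape)
    shape <- as.integer(shape)
    stopifnot(length(shape) == 2L, all(shape >= 2L))
  }
  structure(list(pixel_size = pixel_size, distance = distance,
                 psf_fwhm = psf_fwhm, shape = shape),
            class = "imaging_geometry")
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat(sprintf(
    "<imaging_geometry> W = %g um, distance = %g m, PSF FWHM = %g px%s\n",
    x$pixel_size * 1e6, x$distance, x$psf_fwhm,
    if (is.null(x$shape)) "" else sprintf(", shape = %dx%d",
                                          x$shape[1], x$shape[2])))
  invisible(x)
}

#' Optical constants of a material at one X-ray energy
#'
#' The complex refractive index is n = 1 - delta + i*beta and the linear
#' attenuation coefficient is related to beta by mu = 4*pi*beta/lambda.
#' Any two of `mu`, `beta` may be given; when both are supplied they must
#' be consistent to a relative tolerance of 1e-10.
#'
#' @param delta Refractive-index decrement (dimensionless, `>= 0`).
#' @param mu Linear attenuation coefficient in 1/m.
#' @param beta Imaginary part of the refractive index (dimensionless).
#' @param energy Photon energy in keV (used to derive the wavelength).
#' @param wavelength X-ray wavelength in metres; derived from `energy`
#'   when missing.
#' @param name Optional material label.
#' @return An object of class `material_optics`.
#' @examples
#' material_optics(delta = 3.99e-7, mu = 57.2, energy = 24)
#' @export
material_optics <- function(delta, mu = NULL, beta = NULL, energy = NULL,
                            wavelength = NULL, name = NULL) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  if (is.null(wavelength) && !is.null(energy)) {
    stopifnot(energy > 0)
    wavelength <- .hc_kev_m / energy
  }
  if (is.null(mu) && is.null(beta))
    stop("one of `mu` or `beta` must be supplied")
  if (is.null(mu)) {
    if (is.null(wavelength))
      stop("`wavelength` or `energy` needed to derive mu from beta")
    mu <- 4 * pi * beta / wavelength
  } else if (is.null(beta)) {
    if (!is.null(wavelength)) beta <- mu * wavelength / (4 * pi)
  } else if (!is.null(wavelength)) {
    mu_chk <- 4 * pi * beta / wavelength
    if (abs(mu_chk - mu) > 1e-10 * max(mu, mu_chk))
      stop("inconsistent `mu` and `beta`: mu = 4*pi*beta/lambda violated")
  }
  stopifnot(mu >= 0, is.null(beta) || beta >= 0)
  structure(list(delta = delta, beta = beta, mu = mu,
                 wavelength = wavelength, energy = energy, name = name),
            class = "material_optics")
}

#' @export
print.material_optics <- function(x, ...) {
  cat(sprintf("<material_optics>%s delta = %.4g, mu = %.4g /m%s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name, ":"),
              x$delta, x$mu,
              if (is.null(x$energy)) "" else sprintf(" at %g keV", x$energy)))
  invisible(x)
}

# delta and mu for the phantom materials used throughout, from standard
# optical-constant physics: delta = r_e lambda^2 rho_e / (2 pi) with
# densities water 0.998, PMMA 1.19, Al 2.699 g/cm^3; mu from tabulated
# mass attenuation coefficients (log-log interpolated).  Tabulated
# approximations, adequate because only delta*Delta/mu enters the filters.
.builtin_materials <- list(
  "water@24"     = list(delta = 3.99e-7,  mu = 57.2,  density = 0.998),
  "pmma@24"      = list(delta = 4.63e-7,  mu = 51.1,  density = 1.19),
  "pmma@30"      = list(delta = 2.96e-7,  mu = 36.1,  density = 1.19),
  "pmma@40"      = list(delta = 1.67e-7,  mu = 27.9,  density = 1.19),
  "aluminium@30" = list(delta = 6.00e-7,  mu = 304.5, density = 2.699),
  "aluminium@40" = list(delta = 3.37e-7,  mu = 153.4, density = 2.699)
)

#' Built-in material optical constants
#'
#' Tabulated refractive-index decrements and attenuation coefficients for
#' the phantom materials used in the simulations (water, PMMA, aluminium)
#' at selected energies.
#'
#' @param name One of `"water"`, `"pmma"`, `"aluminium"`.
#' @param energy Photon energy in keV; available combinations are water
#'   at 24 keV, PMMA at 24/30/40 keV and aluminium at 30/40 keV.
#' @return A [material_optics] object.
#' @examples
#' builtin_material("water", 24)
#' @export
builtin_material <- function(name = c("water", "pmma", "aluminium"),
                             energy = 24) {
  name <- match.arg(name)
  key <- sprintf("%s@%g", name, energy)
  entry <- .builtin_materials[[key]]
  if (is.null(entry))
    stop(sprintf("no tabulated constants for %s at %g keV; available: %s",
                 name, energy,
                 paste(names(.builtin_materials), collapse = ", ")))
  material_optics(delta = entry$delta, mu = entry$mu, energy = energy,
                  name = name)
}

#' Angular DFT frequency grid
#'
#' Signed angular spatial frequencies k = 2*pi*n/(N*W) for DFT sample
#' index n, so |W*k| <= pi with the Nyquist frequency at pi/W.  On
#' even-sized axes the single unpaired Nyquist sample is assigned +pi/W;
#' all kernels built from the grid are even in k, so the sign only fixes
#' a convention.
#'
#' @param shape Integer grid dimensions `c(rows, cols)` (scalar recycled).
#' @param pixel_size Pixel size W in metres.
#' @return An object of class `frequency_grid` with per-axis frequency
#'   vectors `kx` (rows) and `ky` (columns), in rad/m.
#' @examples
#' g <- frequency_grid(8, 25e-6)
#' range(g$kx) * g$pixel_size / pi
#' @export
frequency_grid <- function(shape, pixel_size) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 2L),
            is.numeric(pixel_size), pixel_size > 0)
  structure(list(shape = shape, pixel_size = pixel_size,
                 kx = fft_freq(shape[1], pixel_size),
                 ky = fft_freq(shape[2], pixel_size)),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %dx%d, W = %g um, Nyquist = %.4g rad/m\n",
              x$shape[1], x$shape[2], x$pixel_size * 1e6, pi / x$pixel_size))
  invisible(x)
}

#' Signed angular DFT sample frequencies for one axis
#'
#' @param n Number of samples.
#' @param d Sample spacing in metres.
#' @return Numeric vector of length `n`, in rad/m, ordered as the DFT
#'   output (DC first); for even `n` the unpaired Nyquist sample is
#'   `+pi/d`.
#' @export
fft_freq <- function(n, d = 1) {
  n <- as.integer(n)
  stopifnot(n >= 1L, d > 0)
  idx <- if (n %% 2L == 0L) c(0:(n %/% 2L), -((n %/% 2L - 1L):1L))
         else c(0:((n - 1L) %/% 2L), -(((n - 1L) %/% 2L):1L))
  if (n == 1L) idx <- 0L
  2 * pi * idx / (n * d)
}

# keV * m per photon: lambda = .hc_kev_m / E[keV]
.hc_kev_m <- 1.23984198e-9

.as_matrix_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg))
  image
}
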