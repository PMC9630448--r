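# Synthetic phantom generation and forward linearised-TIE propagation.
# The generator is fully deterministic: no random numbers are used.

#' End-on cylinder (disc) projected-thickness map
#'
#' Builds the projected thickness of an end-on cylinder of uniform
#' thickness on an upsampled grid: `thickness` at upsampled pixel centres
#' strictly inside the circle, zero outside.  The circle is centred on
#' the array centre; with `radius_px` ending in .5 the edge falls between
#' detector pixel centres.
#'
#' @param shape Detector grid dimensions `c(rows, cols)` (scalar
#'   recycled).
#' @param radius_px Disc radius in detector pixels.
#' @param thickness Cylinder thickness in metres (projected value inside
#'   the disc).
#' @param upsample Positive integer upsampling factor; the returned map
#'   has dimensions `shape * upsample`.
#' @return An object of class `thickness_map`: list with `values`
#'   (upsampled matrix, metres), `upsample`, and `radius_px`.
#' @examples
#' tm <- disc_thickness(64, radius_px = 20, thickness = 6e-3, upsample = 2)
#' max(tm$values)
#' @export
disc_thickness <- function(shape, radius_px, thickness = 6e-3,
                           upsample = 5L) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  shape <- as.integer(shape)
  upsample <- as.integer(upsample)
  stopifnot(all(shape >= 2L), upsample >= 1L, radius_px > 0,
            thickness >= 0)
  if (radius_px >= min(shape) / 2)
    stop("disc radius must be smaller than half the grid extent")
  n1 <- shape[1] * upsample
  n2 <- shape[2] * upsample
  r_up <- radius_px * upsample
  # pixel-centre coordinates relative to the array centre
  x <- (seq_len(n1) - 0.5) - n1 / 2
  y <- (seq_len(n2) - 0.5) - n2 / 2
  inside <- outer(x^2, y^2, "+") < r_up^2
  values <- matrix(0, n1, n2)
  values[inside] <- thickness
  structure(list(values = values, upsample = upsample,
                 radius_px = radius_px),
            class = "thickness_map")
}

#' Contact-plane intensity and phase under the projection approximation
#'
#' I = I0 * exp(-mu * T) for the attenuation part of the projection
#' approximation; the phase map phi = -(2*pi/lambda) * delta * T is
#' retained alongside for propagation.
#'
#' @param tmap A [disc_thickness()] result, or a numeric matrix of
#'   projected thicknesses in metres.
#' @param optics A [material_optics].
#' @param I0 Incident intensity (scalar).
#' @return List with `intensity` and `phase` matrices (phase is `NULL`
#'   when the optics carry no wavelength).
#' @export
contact_intensity <- function(tmap, optics, I0 = 1) {
  stopifnot(inherits(optics, "material_optics"), I0 > 0)
  values <- if (inherits(tmap, "thickness_map")) tmap$values else
    .as_matrix_image(tmap, "tmap")
  stopifnot(all(is.finite(values)), all(values >= 0))
  phase <- if (!is.null(optics$wavelength))
    -(2 * pi / optics$wavelength) * optics$delta * values else NULL
  list(intensity = I0 * exp(-optics$mu * values), phase = phase)
}

#' Forward linearised-TIE propagation of a homogeneous-object image
#'
#' Applies the forward single-material TIE operator in Fourier space:
#' DFT(I/I0) is multiplied by 1 + (delta*Delta/mu) * k2.  The default
#' continuous (`"pm"`) kernel is the adjoint of the classical retrieval
#' filter; `"gpm"` uses the discrete cosine kernel instead.  Zero
#' distance is the identity, and the image mean is preserved.
#'
#' @param intensity Contact-plane intensity matrix (or the list returned
#'   by [contact_intensity()], whose `intensity` element is used).
#' @param optics A [material_optics] with `mu > 0`.
#' @param distance Propagation distance in metres.
#' @param pixel_size Pixel size of `intensity`'s grid in metres (for an
#'   upsampled grid, the upsampled pixel size).
#' @param I0 Incident intensity (scalar or matrix).
#' @param kernel `"pm"` (continuous, default) or `"gpm"`.
#' @return Matrix of propagated intensities (same units as `intensity`).
#' @export
tie_propagate <- function(intensity, optics, distance, pixel_size,
                          I0 = 1, kernel = c("pm", "gpm")) {
  if (is.list(intensity) && !is.null(intensity$intensity))
    intensity <- intensity$intensity
  intensity <- .as_matrix_image(intensity, "intensity")
  stopifnot(inherits(optics, "material_optics"), distance >= 0,
            pixel_size > 0)
  coef <- .filter_coef(optics$delta, optics$mu, distance)
  if (coef == 0) return(intensity)
  ratio <- intensity / I0
  grid <- frequency_grid(dim(ratio), pixel_size)
  filt <- 1 + coef * .k_perp2(grid, kernel)
  I0 * Re(fft(fft(ratio) * filt, inverse = TRUE)) / length(ratio)
}

#' Gaussian blur by a unit-integral kernel of given FWHM
#'
#' FFT-based convolution with an isotropic Gaussian whose full width at
#' half maximum is `fwhm_px` pixels of the supplied image.  The image
#' sum is preserved (DC gain 1); zero width is the identity.
#'
#' @param image Numeric matrix.
#' @param fwhm_px Gaussian FWHM in pixels of `image`'s grid (`>= 0`).
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(image, fwhm_px) {
  image <- .as_matrix_image(image)
  stopifnot(is.numeric(fwhm_px), length(fwhm_px) == 1L, fwhm_px >= 0)
  if (fwhm_px == 0) return(image)
  grid <- frequency_grid(dim(image), 1)
  g <- gaussian_ctf(grid, fwhm_px)
  Re(fft(fft(image) * g, inverse = TRUE)) / length(image)
}

#' Block-mean downsampling
#'
#' Averages `factor` x `factor` tiles; the image mean is preserved
#' exactly.
#'
#' @param image Numeric matrix with both dimensions divisible by
#'   `factor`.
#' @param factor Positive integer.
#' @return Matrix of dimensions `dim(image) / factor`.
#' @export
downsample_block <- function(image, factor) {
  image <- .as_matrix_image(image)
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(image)
  d <- dim(image)
  if (any(d %% factor != 0L))
    stop("image dimensions must be divisible by `factor`")
  m <- matrix(colMeans(matrix(image, nrow = factor)), d[1] %/% factor, d[2])
  t(matrix(colMeans(matrix(t(m), nrow = factor)),
           d[2] %/% factor, d[1] %/% factor))
}

#' Rebin an image (and optionally its geometry) by n
#'
#' Block-mean rebinning by `n` along each axis, the flux-consistent
#' choice for flat-corrected intensities.  Applied to an
#' [imaging_geometry], rebinning multiplies the pixel size by `n` and
#' divides the PSF width expressed in pixels by `n`.
#'
#' @param x Numeric matrix or [imaging_geometry].
#' @param n Positive integer rebin factor.
#' @param ... Unused.
#' @return Same type as `x`.
#' @export
rebin <- function(x, n, ...) UseMethod("rebin")

#' @rdname rebin
#' @export
rebin.matrix <- function(x, n, ...) downsample_block(x, n)

#' @rdname rebin
#' @export
rebin.imaging_geometry <- function(x, n, ...) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  shape <- x$shape
  if (!is.null(shape)) {
    if (any(shape %% n != 0L))
      stop("geometry shape must be divisible by `n`")
    shape <- shape %/% n
  }
  imaging_geometry(pixel_size = x$pixel_size * n, distance = x$distance,
                   psf_fwhm = x$psf_fwhm / n, shape = shape)
}

#' Tune the propagation distance to the single-fringe criterion
#'
#' Increases the propagation distance until the bright fringe overshoot
#' at the disc edge of a small test simulation exceeds a set fraction of
#' the attenuation edge step, i.e. until a single phase-contrast fringe
#' is clearly visible in the propagated intensity.
#'
#' @param optics A [material_optics].
#' @param pixel_size Detector pixel size in metres.
#' @param overshoot Target fringe overshoot as a fraction of the edge
#'   step; the default 0.03 marks the smallest clearly discernible
#'   fringe (a few grey levels of an 8-bit display).
#' @param shape,radius_px,thickness,upsample,pre_blur_px Test phantom
#'   parameters (a small grid suffices; only the dimensionless group
#'   delta*Delta/(mu*W^2) matters).
#' @return Propagation distance in metres.
#' @export
tune_distance <- function(optics, pixel_size, overshoot = 0.03,
                          shape = 128L, radius_px = 50, thickness = 6e-3,
                          upsample = 4L, pre_blur_px = 1) {
  measured <- function(distance) {
    sim <- simulate_disc_projection(optics, shape = shape,
                                    radius_px = radius_px,
                                    thickness = thickness,
                                    pixel_size = pixel_size,
                                    distance = distance,
                                    upsample = upsample,
                                    pre_blur_px = pre_blur_px)
    img <- sim$propagated
    step <- 1 - exp(-optics$mu * thickness)
    (max(img) - 1) / step
  }
  lo <- 0
  hi <- pixel_size^2 * optics$mu / optics$delta  # delta*Delta/(mu W^2) = 1
  while (measured(hi) < overshoot) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e3) stop("single-fringe criterion not reachable")
  }
  for (i in 1:16) {
    mid <- (lo + hi) / 2
    if (measured(mid) < overshoot) lo <- mid else hi <- mid
  }
  hi
}

#' Forward-simulate a propagated disc projection
#'
#' Deterministic pipeline shared by the resolution studies: disc
#' thickness map on an upsampled grid, pre-propagation Gaussian blur (to
#' suppress pixelated-rim artefacts), projection-approximation contact
#' intensity, forward linearised-TIE propagation with the continuous
#' kernel on the upsampled grid, and block-mean downsampling to the
#' detector grid.  Detector blur and retrieval are applied afterwards by
#' [detect_and_retrieve()].
#'
#' @param optics A [material_optics].
#' @param shape Detector grid dimensions (scalar recycled).
#' @param radius_px Disc radius in detector pixels.
#' @param thickness Cylinder thickness in metres.
#' @param pixel_size Detector pixel size W in metres.
#' @param distance Propagation distance in metres; `NULL` (default)
#'   tunes it to the single-fringe visibility criterion with
#'   [tune_distance()].
#' @param upsample Integer upsampling factor for phantom creation and
#'   propagation.
#' @param pre_blur_px Pre-propagation blur FWHM in detector pixels,
#'   applied to the thickness map on the upsampled grid.
#' @param I0 Incident intensity.
#' @return List with `propagated` (detector-grid intensity, relative to
#'   `I0` = 1), `contact` (detector-grid contact intensity for
#'   reference), and `geometry`.
#' @export
simulate_disc_projection <- function(optics, shape = 2048L,
                                     radius_px = 900.5, thickness = 6e-3,
                                     pixel_size = 25e-6, distance = NULL,
                                     upsample = 5L, pre_blur_px = 1,
                                     I0 = 1) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  shape <- as.integer(shape)
  upsample <- as.integer(upsample)
  if (is.null(distance))
    distance <- tune_distance(optics, pixel_size, thickness = thickness,
                              pre_blur_px = pre_blur_px)
  tmap <- disc_thickness(shape, radius_px, thickness, upsample)
  tv <- tmap$values
  if (pre_blur_px > 0) {
    tv <- gaussian_blur(tv, pre_blur_px * upsample)
    tv <- pmax(tv, 0)  # FFT blur leaves O(1e-19) negative ringing
  }
  contact <- contact_intensity(tv, optics, I0 = 1)
  prop <- tie_propagate(contact$intensity, optics, distance,
                        pixel_size / upsample, I0 = 1, kernel = "pm")
  list(propagated = I0 * downsample_block(prop, upsample),
       contact = I0 * downsample_block(contact$intensity, upsample),
       geometry = imaging_geometry(pixel_size, distance, 0, shape))
}

#' Apply a detector PSF and retrieve with both kernels
#'
#' Blurs a detector-grid phase-contrast image with a Gaussian PSF of
#' FWHM `psf_fwhm` pixels and retrieves the contact image with both the
#' PM and GPM filters.
#'
#' @param propagated Detector-grid propagated intensity matrix.
#' @param optics A [material_optics].
#' @param geom An [imaging_geometry] (pixel size and distance).
#' @param psf_fwhm Detector PSF FWHM in pixels.
#' @param I0 Incident intensity.
#' @return List with `pc` (blurred phase-contrast image), `pm` and `gpm`
#'   (retrieved images), and `psf_fwhm`.
#' @export
detect_and_retrieve <- function(propagated, optics, geom, psf_fwhm,
                                I0 = 1) {
  pc <- gaussian_blur(propagated, psf_fwhm)
  list(pc = pc,
       pm = phase_retrieve(pc, I0, optics, geom, "pm"),
       gpm = phase_retrieve(pc, I0, optics, geom, "gpm"),
       psf_fwhm = psf_fwhm)
}

#' One case of the projection resolution study
#'
#' End-to-end deterministic pipeline: disc thickness map, pre-blur,
#' projection-approximation contact image, forward TIE propagation on
#' the upsampled grid, downsampling, detector blur, and retrieval with
#' both kernels.
#'
#' @inheritParams simulate_disc_projection
#' @param psf_fwhm Detector PSF FWHM in pixels.
#' @return List with `pc`, `pm`, `gpm` image matrices, `geometry`, and
#'   the simulation parameters.
#' @export
simulate_fig2_case <- function(psf_fwhm, optics = builtin_material("water", 24),
                               shape = 2048L, radius_px = 900.5,
                               thickness = 6e-3, pixel_size = 25e-6,
                               distance = NULL, upsample = 5L,
                               pre_blur_px = 1, I0 = 1) {
  if (is.null(distance))
    distance <- tune_distance(optics, pixel_size, thickness = thickness,
                              pre_blur_px = pre_blur_px)
  sim <- simulate_disc_projection(optics, shape, radius_px, thickness,
                                  pixel_size, distance, upsample,
                                  pre_blur_px, I0)
  geom <- imaging_geometry(pixel_size, distance, psf_fwhm,
                           sim$geometry$shape)
  out <- detect_and_retrieve(sim$propagated, optics, geom, psf_fwhm, I0)
  c(out, list(geometry = geom,
              params = list(radius_px = radius_px, thickness = thickness,
                            upsample = upsample, pre_blur_px = pre_blur_px,
                            distance = distance)))
}

#' Resolution-improvement sweep over detector PSF widths
#'
#' Runs the projection resolution study for a set of detector PSF
#' widths, sharing the (expensive) upsampled propagation across cases,
#' and measures the Pearson VII LSF width of the disc edge in the PM-
#' and GPM-retrieved images, plus the fractional improvement.
#'
#' @inheritParams simulate_disc_projection
#' @param psf_fwhms Numeric vector of detector PSF FWHMs in pixels.
#' @param fit_half_width Radial half-width of the edge-fit window, in
#'   detector pixels.
#' @param bin_width Radial bin width for the azimuthal profile, in
#'   detector pixels.
#' @return Data frame with one row per PSF width: `psf_fwhm`,
#'   `gamma_pc`, `gamma_pm`, `gamma_gpm` (fitted FWHMs, pixels),
#'   `improvement` (fraction) and `improvement_se`.
#' @export
fig2_resolution_sweep <- function(psf_fwhms = c(1, 2, 3),
                                  optics = builtin_material("water", 24),
                                  shape = 2048L, radius_px = 900.5,
                                  thickness = 6e-3, pixel_size = 25e-6,
                                  distance = NULL, upsample = 5L,
                                  pre_blur_px = 1, fit_half_width = 15,
                                  bin_width = 0.1) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  shape <- as.integer(shape)
  if (is.null(distance))
    distance <- tune_distance(optics, pixel_size, thickness = thickness,
                              pre_blur_px = pre_blur_px)
  sim <- simulate_disc_projection(optics, shape, radius_px, thickness,
                                  pixel_size, distance, upsample,
                                  pre_blur_px)
  centre <- shape / 2 + 0.5
  fit_edge <- function(img) {
    measure_edge_fwhm(img, centre = centre, radius = radius_px,
                      half_width = fit_half_width, bin_width = bin_width)
  }
  rows <- lapply(psf_fwhms, function(g) {
    geom <- imaging_geometry(pixel_size, distance, g, shape)
    ret <- detect_and_retrieve(sim$propagated, optics, geom, g)
    fpc <- fit_edge(ret$pc)
    fpm <- fit_edge(ret$pm)
    fgp <- fit_edge(ret$gpm)
    imp <- improvement(fpm$fwhm, fgp$fwhm,
                       se_pm = fpm$fwhm_se, se_gpm = fgp$fwhm_se)
    data.frame(psf_fwhm = g, gamma_pc = fpc$fwhm, gamma_pm = fpm$fwhm,
               gamma_gpm = fgp$fwhm, improvement = imp$improvement,
               improvement_se = imp$uncertainty)
  })
  do.call(rbind, rows)
}

#' Rebinning resolution-improvement trend
#'
#' Simulates a propagated PMMA disc edge at indirect-detector conditions
#' (native detector PSF of a few pixels), rebins the phase-contrast
#' image by a set of factors, retrieves with both kernels at the
#' rebinned geometry, and measures the fractional resolution improvement
#' at each rebin level.  Rebinning enlarges the effective pixel and
#' shrinks the PSF expressed in pixels, so the improvement grows with
#' the rebin factor.
#'
#' The phantom edge is given a finite intrinsic width (`pre_blur_px`,
#' in native pixels) large enough that the linearised forward
#' propagation stays within its validity at these strong-filter
#' conditions (non-negative intensity, a single moderate fringe).
#'
#' @param factors Integer rebin factors (native `shape` must be
#'   divisible by each).
#' @param optics A [material_optics].
#' @param shape Native detector grid size (scalar recycled).
#' @param radius_px Disc radius in native detector pixels.
#' @param thickness Cylinder thickness in metres.
#' @param pixel_size Native detector pixel size in metres.
#' @param distance Propagation distance in metres.
#' @param psf_fwhm Native detector PSF FWHM in pixels.
#' @param upsample Upsampling factor for phantom creation/propagation.
#' @param pre_blur_px Intrinsic edge width (Gaussian FWHM, native
#'   pixels).
#' @param bin_width Radial bin width for the edge fits, in rebinned
#'   pixels.
#' @return Data frame with one row per factor: `factor`, `gamma_pm`,
#'   `gamma_gpm` (rebinned pixels), `improvement` (fraction), and
#'   `dbar_nyquist` (analytic blurred fractional difference at the
#'   rebinned Nyquist frequency).
#' @export
rebin_resolution_trend <- function(factors = c(1L, 2L, 4L, 8L),
                                   optics = builtin_material("pmma", 24),
                                   shape = 1024L, radius_px = 420.25,
                                   thickness = 6e-3, pixel_size = 6.5e-6,
                                   distance = 2, psf_fwhm = 2.4,
                                   upsample = 2L, pre_blur_px = 16,
                                   bin_width = 0.25) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  shape <- as.integer(shape)
  sim <- simulate_disc_projection(optics, shape, radius_px, thickness,
                                  pixel_size, distance, upsample,
                                  pre_blur_px)
  pc <- gaussian_blur(sim$propagated, psf_fwhm)
  geom0 <- imaging_geometry(pixel_size, distance, psf_fwhm, shape)
  rows <- lapply(as.integer(factors), function(n) {
    img <- rebin(pc, n)
    geom <- rebin(geom0, n)
    centre <- dim(img) / 2 + 0.5
    rad <- radius_px / n
    hw <- min(pre_blur_px * 2.5 / n + 12, rad / 4)
    fpm <- measure_edge_fwhm(phase_retrieve(img, 1, optics, geom, "pm"),
                             centre, rad, half_width = hw,
                             bin_width = bin_width)
    fgp <- measure_edge_fwhm(phase_retrieve(img, 1, optics, geom, "gpm"),
                             centre, rad, half_width = hw,
                             bin_width = bin_width)
    gridn <- frequency_grid(c(64L, 64L), pixel_size * n)
    dbar <- fractional_difference(gridn, optics$delta, optics$mu,
                                  distance, psf_fwhm = psf_fwhm / n)
    data.frame(factor = n, gamma_pm = fpm$fwhm, gamma_gpm = fgp$fwhm,
               improvement = (fpm$fwhm - fgp$fwhm) / fpm$fwhm,
               dbar_nyquist = dbar[33, 1])
  })
  do.call(rbind, rows)
}
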