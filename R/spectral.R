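# Dual-energy decomposition into photoelectric and projected electron
# density maps from the linearised TIE, using the Alvarez-Macovski
# attenuation basis with either frequency kernel.
#
# Unit system: energies in keV, lengths in metres.  chi has units m^4
# (so chi * k_perp^2 is m^2, like the Klein-Nishina cross section); the
# projected electron density is in electrons/m^2 and the photoelectric
# coefficient P in keV^3 (its E^-3-basis natural units).

#' Physical constants used by the spectral module
#'
#' CODATA-style values, fixed and test-pinned: Planck constant h
#' (keV s), speed of light c (m/s), classical electron radius r_e (m),
#' Thomson cross section sigma_T (m^2) and the electron rest energy
#' (keV).
#'
#' @return Named list of constants.
#' @export
physical_constants <- function() {
  list(h = 4.135667696e-18,        # keV s
       c = 299792458,              # m/s
       r_e = 2.8179403262e-15,     # m
       sigma_T = 6.6524587321e-29, # m^2
       electron_rest_kev = 510.99895)
}

#' Total Klein-Nishina cross section per electron
#'
#' Standard closed form of the total Compton-scattering cross section at
#' photon energy E, strictly decreasing in E and converging to the
#' Thomson cross section as E -> 0.
#'
#' @param energy Photon energy in keV (`> 0`); vectorised.
#' @return Cross section(s) in m^2 per electron.
#' @examples
#' klein_nishina(0.1) / physical_constants()$sigma_T
#' @export
klein_nishina <- function(energy) {
  if (any(energy <= 0)) stop("`energy` must be positive")
  pc <- physical_constants()
  g <- energy / pc$electron_rest_kev
  lg <- log1p(2 * g)
  2 * pi * pc$r_e^2 *
    ((1 + g) / g^2 * (2 * (1 + g) / (1 + 2 * g) - lg / g) +
       lg / (2 * g) - (1 + 3 * g) / (1 + 2 * g)^2)
}

#' Phase-attenuation coupling coefficient chi
#'
#' chi = h^2 c^2 r_e Delta / (2 pi E^2), the factor that couples the
#' projected electron density to the propagation term of the linearised
#' TIE.  Units: m^4 (with E in keV and Delta in m).
#'
#' @param energy Photon energy in keV (`> 0`).
#' @param distance Propagation distance in metres (`>= 0`).
#' @return chi in m^4.
#' @export
chi_coupling <- function(energy, distance) {
  if (any(energy <= 0)) stop("`energy` must be positive")
  stopifnot(distance >= 0)
  pc <- physical_constants()
  (pc$h * pc$c)^2 * pc$r_e * distance / (2 * pi * energy^2)
}

#' Forward dual-energy model: -ln I(E) from (P, rho_e)
#'
#' Evaluates the linearised-TIE forward model in frequency space:
#' F[-ln I(E)] = E^-3 F[P] + (sigma_KN(E) + chi(E, Delta) k2) F[rho_e],
#' with k2 the squared-frequency map of the chosen kernel.  Used for
#' synthetic generation and round-trip tests.
#'
#' @param P Photoelectric-coefficient map (keV^3), numeric matrix.
#' @param rho_e Projected electron-density map (electrons/m^2), same
#'   shape as `P`.
#' @param energy Photon energy in keV.
#' @param distance Propagation distance in metres.
#' @param geom An [imaging_geometry] (pixel size).
#' @param kernel `"pm"` or `"gpm"`.
#' @return Matrix of -ln I(E) values.
#' @export
forward_dual_energy <- function(P, rho_e, energy, distance, geom,
                                kernel = c("pm", "gpm")) {
  P <- .as_matrix_image(P, "P")
  rho_e <- .as_matrix_image(rho_e, "rho_e")
  if (!all(dim(P) == dim(rho_e)))
    stop("`P` and `rho_e` must share one grid")
  stopifnot(inherits(geom, "imaging_geometry"))
  grid <- frequency_grid(dim(P), geom$pixel_size)
  k2 <- .k_perp2(grid, .kernel_choice(kernel))
  b <- klein_nishina(energy) + chi_coupling(energy, distance) * k2
  Fm <- energy^-3 * fft(P) + b * fft(rho_e)
  Re(fft(Fm, inverse = TRUE)) / length(Fm)
}

#' Dual-energy pair of normalised intensity images
#'
#' @param I_A,I_B Strictly positive normalised intensity matrices of one
#'   shape, recorded at energies `energy_a` and `energy_b`.
#' @param energy_a,energy_b Photon energies in keV (`energy_a !=
#'   energy_b`).
#' @param geom An [imaging_geometry].
#' @return An object of class `dual_energy_pair`.
#' @export
dual_energy_pair <- function(I_A, I_B, energy_a, energy_b, geom) {
  I_A <- .as_matrix_image(I_A, "I_A")
  I_B <- .as_matrix_image(I_B, "I_B")
  if (!all(dim(I_A) == dim(I_B)))
    stop("`I_A` and `I_B` must share one grid")
  if (energy_a == energy_b)
    stop("singular pair: the two energies must differ")
  stopifnot(inherits(geom, "imaging_geometry"))
  structure(list(I_A = I_A, I_B = I_B, energy_a = energy_a,
                 energy_b = energy_b, geom = geom),
            class = "dual_energy_pair")
}

#' Dual-energy decomposition into (P, projected electron density)
#'
#' Solves, per spatial frequency, the 2x2 Alvarez-Macovski system
#' linking the DFTs of -ln I at the two energies to the photoelectric
#' coefficient P and the projected electron density, with the phase term
#' chi(E, Delta) k2 entering through the chosen kernel.  Frequencies
#' where the determinant magnitude falls below 1e-12 of its DC value are
#' clamped (and counted in the `n_clamped` attribute).
#'
#' @param pair A [dual_energy_pair()].
#' @param distance Propagation distance in metres (defaults to the
#'   pair's geometry).
#' @param kernel `"pm"` or `"gpm"`.
#' @return List of class `decomposition_result` with matrices `P`
#'   (keV^3) and `rho_e` (electrons/m^2); attribute `n_clamped`.
#' @export
dual_energy_decompose <- function(pair, distance = NULL,
                                  kernel = c("pm", "gpm")) {
  stopifnot(inherits(pair, "dual_energy_pair"))
  if (is.null(distance)) distance <- pair$geom$distance
  if (any(pair$I_A <= 0) || any(pair$I_B <= 0))
    stop("intensities must be strictly positive")
  grid <- frequency_grid(dim(pair$I_A), pair$geom$pixel_size)
  k2 <- .k_perp2(grid, .kernel_choice(kernel))
  eA <- pair$energy_a
  eB <- pair$energy_b
  a1 <- eA^-3
  a2 <- eB^-3
  b1 <- klein_nishina(eA) + chi_coupling(eA, distance) * k2
  b2 <- klein_nishina(eB) + chi_coupling(eB, distance) * k2
  mA <- fft(-log(pmax(pair$I_A, 1e-12 * stats::median(pair$I_A))))
  mB <- fft(-log(pmax(pair$I_B, 1e-12 * stats::median(pair$I_B))))
  det <- a1 * b2 - a2 * b1
  det_dc <- abs(a1 * klein_nishina(eB) - a2 * klein_nishina(eA))
  small <- abs(det) < 1e-12 * det_dc
  n_clamped <- sum(small)
  if (n_clamped > 0)
    det[small] <- sign(det[small] + (det[small] == 0)) * 1e-12 * det_dc
  FP <- (b2 * mA - b1 * mB) / det
  Fr <- (a1 * mB - a2 * mA) / det
  out <- list(P = Re(fft(FP, inverse = TRUE)) / length(FP),
              rho_e = Re(fft(Fr, inverse = TRUE)) / length(Fr))
  attr(out, "n_clamped") <- n_clamped
  class(out) <- "decomposition_result"
  out
}
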