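#' Closed-form DLS physics
#'
#' The observable in a DLS experiment is the fluctuating intensity of
#' coherent light scattered by diffusing particles. Three closed-form
#' relations connect the particle's hydrodynamic diameter to measurable
#' quantities:
#'
#' * the scattering vector modulus `q = 4 pi n / lambda * sin(theta/2)`,
#'   which sets the probed spatial frequency;
#' * the Einstein-Stokes diffusion coefficient
#'   `D = kB T / (3 pi eta d)`;
#' * the Lorentzian half-width of the intensity power spectrum,
#'   `a1 = 2 D q^2` (rad/s), whose inverse gives the autocorrelation
#'   decay time.
#'
#' `halfwidth_from_diameter()` and `diameter_from_halfwidth()` are exact
#' algebraic inverses of one another.
#'
#' @param setup An [optical_setup()].
#' @param diameter Hydrodynamic diameter (m), > 0.
#' @param a1 Lorentzian half-width (rad/s), > 0.
#' @return A numeric scalar (or vector, the functions are vectorised in
#'   `diameter` / `a1`): `scattering_vector_modulus()` in 1/m,
#'   `diffusion_coefficient()` in m^2/s, `halfwidth_from_diameter()` in
#'   rad/s, `diameter_from_halfwidth()` in m.
#' @examples
#' setup <- optical_setup()
#' q <- scattering_vector_modulus(setup)        # ~1.87e7 1/m
#' D <- diffusion_coefficient(setup, 100e-9)    # ~4.55e-12 m^2/s
#' a1 <- halfwidth_from_diameter(setup, 100e-9) # 2 D q^2
#' diameter_from_halfwidth(setup, a1)           # 100e-9 again
#' @export
scattering_vector_modulus <- function(setup) {
  validate_optical_setup(setup)
  4 * pi * setup$refractive_index / setup$wavelength_vacuum *
    sin(setup$scattering_angle / 2)
}

#' @rdname scattering_vector_modulus
#' @export
diffusion_coefficient <- function(setup, diameter) {
  validate_optical_setup(setup)
  if (!is.numeric(diameter) || any(!is.finite(diameter)) ||
      any(diameter <= 0)) {
    stop("`diameter` must be a positive finite length in metres",
         call. = FALSE)
  }
  K_BOLTZMANN * setup$temperature / (3 * pi * setup$viscosity * diameter)
}

#' @rdname scattering_vector_modulus
#' @export
halfwidth_from_diameter <- function(setup, diameter) {
  q <- scattering_vector_modulus(setup)
  2 * diffusion_coefficient(setup, diameter) * q^2
}

#' @rdname scattering_vector_modulus
#' @export
diameter_from_halfwidth <- function(setup, a1) {
  validate_optical_setup(setup)
  if (!is.numeric(a1) || any(!is.finite(a1)) || any(a1 <= 0)) {
    stop("`a1` must be a positive finite half-width in rad/s",
         call. = FALSE)
  }
  q <- scattering_vector_modulus(setup)
  2 * K_BOLTZMANN * setup$temperature * q^2 /
    (3 * pi * setup$viscosity * a1)
}

#' Lorentzian power spectrum of DLS intensity fluctuations
#'
#' `S(f) = a0 * a1 / ((2 pi f)^2 + a1^2)`: the spectral density of the
#' scattered-intensity fluctuations of mono-dispersed Brownian
#' particles. It peaks at `a0 / a1` at zero frequency, falls to half
#' that value at `f = a1 / (2 pi)`, and integrates to `a0 / 4` over
#' positive frequencies.
#'
#' @param a0 Amplitude scale (arbitrary units), > 0. The overall scale
#'   cancels in the normalized autocorrelation, so its exact value does
#'   not affect sizing.
#' @param a1 Half-width (rad/s), > 0.
#' @param frequency Frequency (Hz), >= 0; vectorised.
#' @return Spectral density values (arbitrary units).
#' @examples
#' lorentzian_spectrum(50, 1000, 0)  # a0 / a1
#' @export
lorentzian_spectrum <- function(a0, a1, frequency) {
  if (!is.numeric(a0) || length(a0) != 1L || !is.finite(a0) || a0 <= 0) {
    stop("`a0` must be a positive finite scalar", call. = FALSE)
  }
  if (!is.numeric(a1) || length(a1) != 1L || !is.finite(a1) || a1 <= 0) {
    stop("`a1` must be a positive finite scalar", call. = FALSE)
  }
  if (any(frequency < 0)) {
    stop("`frequency` must be >= 0", call. = FALSE)
  }
  a0 * a1 / ((2 * pi * frequency)^2 + a1^2)
}
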