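#' Optical and thermodynamic configuration of a DLS experiment
#'
#' Bundles the quantities that fix the scattering vector and the
#' diffusion coefficient: vacuum wavelength, solvent refractive index,
#' scattering angle, absolute temperature, dynamic viscosity and the
#' sampling frequency of the data acquisition system. All fields are in
#' SI units; the angle is stored in radians (see `angle_unit` to pass
#' degrees).
#'
#' Defaults describe a typical bench setup: a 633 nm He-Ne laser at a
#' 90 degree scattering angle into water at 22 degrees C (n = 1.331,
#' eta = 9.5e-4 Pa s), digitised at 16 kHz. The viscosity of a real
#' sample medium (e.g. sucrose syrup) is higher than water's; since the
#' inferred diameter scales as 1/eta, all reported diameters rescale
#' proportionally if the true viscosity differs.
#'
#' @param wavelength_vacuum Laser wavelength in vacuum (m).
#' @param refractive_index Solvent refractive index (>= 1).
#' @param scattering_angle Scattering angle; radians unless
#'   `angle_unit = "degree"`. Must lie strictly in (0, pi).
#' @param temperature Absolute temperature (K).
#' @param viscosity Dynamic viscosity of the solvent (Pa s).
#' @param sampling_frequency Acquisition rate of the detector (Hz).
#' @param angle_unit Either `"radian"` (default) or `"degree"`.
#'
#' @return An object of class `optical_setup` (a named list).
#' @examples
#' setup <- optical_setup()
#' scattering_vector_modulus(setup)
#' @export
optical_setup <- function(wavelength_vacuum = 633e-9,
                          refractive_index = 1.331,
                          scattering_angle = pi / 2,
                          temperature = 295.15,
                          viscosity = 9.5e-4,
                          sampling_frequency = 16000,
                          angle_unit = c("radian", "degree")) {
  angle_unit <- match.arg(angle_unit)
  if (angle_unit == "degree") {
    scattering_angle <- scattering_angle * pi / 180
  }
  setup <- structure(
    list(
      wavelength_vacuum = as.numeric(wavelength_vacuum),
      refractive_index = as.numeric(refractive_index),
      scattering_angle = as.numeric(scattering_angle),
      temperature = as.numeric(temperature),
      viscosity = as.numeric(viscosity),
      sampling_frequency = as.numeric(sampling_frequency)
    ),
    class = "optical_setup"
  )
  validate_optical_setup(setup)
  setup
}

validate_optical_setup <- function(setup) {
  check <- function(cond, field, what) {
    if (!isTRUE(cond)) {
      stop(sprintf("invalid optical setup: `%s` %s", field, what),
           call. = FALSE)
    }
  }
  for (f in c("wavelength_vacuum", "refractive_index", "scattering_angle",
              "temperature", "viscosity", "sampling_frequency")) {
    check(is.numeric(setup[[f]]) && length(setup[[f]]) == 1L &&
            is.finite(setup[[f]]), f, "must be a finite scalar")
  }
  check(setup$wavelength_vacuum > 0, "wavelength_vacuum", "must be > 0")
  check(setup$refractive_index >= 1, "refractive_index", "must be >= 1")
  check(setup$scattering_angle > 0 && setup$scattering_angle < pi,
        "scattering_angle", "must lie in (0, pi)")
  check(setup$temperature > 0, "temperature", "must be > 0")
  check(setup$viscosity > 0, "viscosity", "must be > 0")
  check(setup$sampling_frequency > 0, "sampling_frequency", "must be > 0")
  invisible(setup)
}

#' @export
print.optical_setup <- function(x, ...) {
  cat("<optical_setup>\n")
  cat(sprintf("  wavelength   : %.1f nm\n", x$wavelength_vacuum * 1e9))
  cat(sprintf("  refr. index  : %.4f\n", x$refractive_index))
  cat(sprintf("  angle        : %.2f deg\n", x$scattering_angle * 180 / pi))
  cat(sprintf("  temperature  : %.2f K\n", x$temperature))
  cat(sprintf("  viscosity    : %.3g Pa s\n", x$viscosity))
  cat(sprintf("  sampling     : %.0f Hz\n", x$sampling_frequency))
  cat(sprintf("  q            : %.4g 1/m\n", scattering_vector_modulus(x)))
  invisible(x)
}

#' Read / write an optical setup as a flat YAML config
#'
#' The file holds one key per field, SI units. The angle may instead be
#' supplied in degrees under the key `scattering_angle_deg`.
#'
#' @param path File path.
#' @return `read_optical_setup()` returns an `optical_setup`;
#'   `write_optical_setup()` returns `path` invisibly.
#' @export
read_optical_setup <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg[["scattering_angle_deg"]])) {
    if (!is.null(cfg[["scattering_angle"]])) {
      stop("config gives both `scattering_angle` and `scattering_angle_deg`",
           call. = FALSE)
    }
    cfg[["scattering_angle"]] <- cfg[["scattering_angle_deg"]] * pi / 180
    cfg[["scattering_angle_deg"]] <- NULL
  }
  known <- c("wavelength_vacuum", "refractive_index", "scattering_angle",
             "temperature", "viscosity", "sampling_frequency")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown optical setup keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(optical_setup, cfg)
}

#' @rdname read_optical_setup
#' @param setup An `optical_setup`.
#' @export
write_optical_setup <- function(setup, path) {
  validate_optical_setup(setup)
  yaml::write_yaml(unclass(setup), path, precision = 15L)
  invisible(path)
}
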