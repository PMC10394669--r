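# Physical constants and closed-form conversions between hydrodynamic radius,
# diffusion coefficient, decay rate and the two correlation functions.

#' Boltzmann constant (exact SI value), J/K
#' @keywords internal
.kB <- 1.380649e-23

#' Describe a DLS instrument and solvent
#'
#' Bundles everything needed to convert between hydrodynamic radius, diffusion
#' coefficient and autocorrelation decay rate: laser wavelength, detection
#' angle, temperature, and the solvent's refractive index and viscosity.
#' Values are accepted in the units instrument software reports (nm, degrees,
#' degrees Celsius) and stored in SI internally.
#'
#' @param wavelength_nm Laser (vacuum) wavelength in nanometres.
#' @param angle_deg Detection angle in degrees, strictly between 0 and 180.
#' @param temperature_C Sample temperature in degrees Celsius.
#' @param refractive_index Solvent refractive index (>= 1).
#' @param viscosity_Pa_s Solvent dynamic viscosity in Pa s.
#' @return An object of class `dls_setup` with fields `wavelength` (m),
#'   `angle` (rad), `temperature` (K), `refractive_index`, `viscosity` (Pa s).
#' @examples
#' plate_reader <- dls_setup()                        # 817 nm, 150 degrees
#' cuvette <- dls_setup(wavelength_nm = 658, angle_deg = 90)
#' @export
dls_setup <- function(wavelength_nm = 817, angle_deg = 150, temperature_C = 20,
                      refractive_index = 1.33, viscosity_Pa_s = 0.00089) {
  check_scalar <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  check_scalar(wavelength_nm, "wavelength_nm")
  check_scalar(angle_deg, "angle_deg")
  check_scalar(temperature_C, "temperature_C")
  check_scalar(refractive_index, "refractive_index")
  check_scalar(viscosity_Pa_s, "viscosity_Pa_s")
  if (wavelength_nm <= 0) stop("'wavelength_nm' must be > 0", call. = FALSE)
  if (angle_deg <= 0 || angle_deg >= 180)
    stop("'angle_deg' must lie strictly between 0 and 180", call. = FALSE)
  temperature_K <- temperature_C + 273.15
  if (temperature_K <= 0) stop("'temperature_C' must be above absolute zero", call. = FALSE)
  if (refractive_index < 1) stop("'refractive_index' must be >= 1", call. = FALSE)
  if (viscosity_Pa_s <= 0) stop("'viscosity_Pa_s' must be > 0", call. = FALSE)
  structure(list(
    wavelength = wavelength_nm * 1e-9,
    angle = angle_deg * pi / 180,
    temperature = temperature_K,
    refractive_index = refractive_index,
    viscosity = viscosity_Pa_s
  ), class = "dls_setup")
}

#' @export
print.dls_setup <- function(x, ...) {
  cat("DLS instrument setup\n")
  cat(sprintf("  wavelength       : %.1f nm\n", x$wavelength * 1e9))
  cat(sprintf("  detection angle  : %.1f deg\n", x$angle * 180 / pi))
  cat(sprintf("  temperature      : %.2f K (%.2f C)\n", x$temperature, x$temperature - 273.15))
  cat(sprintf("  refractive index : %.4f\n", x$refractive_index))
  cat(sprintf("  viscosity        : %.5f Pa s\n", x$viscosity))
  cat(sprintf("  q                : %.4g 1/m\n", bragg_wavevector(x)))
  invisible(x)
}

.assert_setup <- function(setup) {
  if (!inherits(setup, "dls_setup"))
    stop("'setup' must be a dls_setup object (see dls_setup())", call. = FALSE)
}

#' Bragg scattering wavevector magnitude
#'
#' q = 4 pi n sin(theta / 2) / lambda, the momentum-transfer magnitude probed
#' at the detection angle.  Sets the timescale on which diffusive motion
#' decorrelates the scattered field.
#'
#' @param setup A [dls_setup()] object.
#' @return q in 1/m.
#' @examples
#' bragg_wavevector(dls_setup())  # ~1.976e7 1/m
#' @export
bragg_wavevector <- function(setup) {
  .assert_setup(setup)
  4 * pi * setup$refractive_index * sin(setup$angle / 2) / setup$wavelength
}

#' Stokes-Einstein conversions between radius and diffusion coefficient
#'
#' `diffusion_from_radius()` evaluates D = kB T / (6 pi mu Rh) for a hard
#' sphere; `radius_from_diffusion()` is its exact inverse.
#'
#' @param r_nm Hydrodynamic radius in nm (> 0), vectorized.
#' @param d Translational diffusion coefficient in m^2/s (> 0), vectorized.
#' @param setup A [dls_setup()] object supplying temperature and viscosity.
#' @return Diffusion coefficient in m^2/s, or radius in nm.
#' @examples
#' diffusion_from_radius(2, dls_setup())  # ~1.21e-10 m^2/s
#' @export
diffusion_from_radius <- function(r_nm, setup) {
  .assert_setup(setup)
  if (any(!is.finite(r_nm)) || any(r_nm <= 0))
    stop("radius must be finite and > 0", call. = FALSE)
  .kB * setup$temperature / (6 * pi * setup$viscosity * r_nm * 1e-9)
}

#' @rdname diffusion_from_radius
#' @export
radius_from_diffusion <- function(d, setup) {
  .assert_setup(setup)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diffusion coefficient must be finite and > 0", call. = FALSE)
  .kB * setup$temperature / (6 * pi * setup$viscosity * d) * 1e9
}

#' Inverse decay rate of the field autocorrelation for a given radius
#'
#' A particle of hydrodynamic radius Rh contributes exp(-tau / s) to g1(tau)
#' with s = 1 / (D q^2); larger particles diffuse more slowly and decay later.
#'
#' @inheritParams diffusion_from_radius
#' @return Inverse decay rate s in seconds, same length as `r_nm`.
#' @examples
#' inverse_decay_from_radius(2, dls_setup())  # ~2.12e-5 s
#' @export
inverse_decay_from_radius <- function(r_nm, setup) {
  q <- bragg_wavevector(setup)
  1 / (diffusion_from_radius(r_nm, setup) * q^2)
}

#' Siegert relation between first- and second-order autocorrelation
#'
#' `siegert_forward()` maps the field autocorrelation g1 to the measured
#' intensity autocorrelation, g2 = 1 + beta g1^2, where beta is the coherence
#' factor of the optical train.  `siegert_invert()` recovers
#' g1 = sqrt((g2 - 1) / beta) and requires g2 >= 1.
#'
#' @param g1 First-order autocorrelation values in \[0, 1\].
#' @param g2 Second-order autocorrelation values (>= 1 for inversion).
#' @param beta Coherence factor, expected in (0, 1].
#' @return The transformed autocorrelation vector.
#' @examples
#' siegert_forward(1, 0.2)        # 1.2
#' siegert_invert(1.05, 0.2)      # 0.5
#' @export
siegert_forward <- function(g1, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a positive scalar", call. = FALSE)
  if (beta > 1)
    warning("coherence factor beta > 1 is unphysical for a single detection mode")
  1 + beta * g1^2
}

#' @rdname siegert_forward
#' @export
siegert_invert <- function(g2, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a positive scalar", call. = FALSE)
  if (any(g2 < 1))
    stop("g2 < 1 cannot be inverted; truncate the curve before the first g2 < 1",
         call. = FALSE)
  sqrt((g2 - 1) / beta)
}
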