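# Mie scattering for homogeneous spheres: scattered intensity at the
# detection angle, used by the simulator to turn number-weighted particle
# populations into the intensity weights DLS actually measures.
#
# Standard series solution with Riccati-Bessel functions psi, chi computed by
# upward recurrence and the logarithmic derivative of psi(mx) by downward
# recurrence; expansion order follows the usual x + 4 x^(1/3) + 2 rule.

.mie_amplitudes <- function(m, x, mu) {
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  nstart <- nmax + 16L
  mx <- m * x
  D <- numeric(nstart + 1L)          # D[n+1] = logarithmic derivative at order n
  for (n in nstart:1) D[n] <- n / mx - 1 / (D[n + 1L] + n / mx)
  psi0 <- cos(x); psi1 <- sin(x)     # psi_{-1}, psi_0
  chi0 <- -sin(x); chi1 <- cos(x)    # chi_{-1}, chi_0
  S1 <- 0+0i; S2 <- 0+0i
  p0 <- 0; p1 <- 1                   # angular functions pi_0, pi_1
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    xi1 <- complex(real = psi1, imaginary = -chi1)
    da <- D[n + 1L] / m + n / x
    db <- D[n + 1L] * m + n / x
    an <- (da * psi - psi1) / (da * xi - xi1)
    bn <- (db * psi - psi1) / (db * xi - xi1)
    tau_n <- n * mu * p1 - (n + 1) * p0
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (an * p1 + bn * tau_n)
    S2 <- S2 + f * (an * tau_n + bn * p1)
    p_new <- ((2 * n + 1) * mu * p1 - (n + 1) * p0) / n
    p0 <- p1; p1 <- p_new
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
  }
  if (!is.finite(Mod(S1)) || !is.finite(Mod(S2)))
    stop("Mie series did not converge (m = ", m, ", x = ", x, ")", call. = FALSE)
  list(S1 = S1, S2 = S2)
}

#' Mie scattered intensity of a sphere at the detection angle
#'
#' Relative intensity of unpolarized light scattered at the setup's detection
#' angle by a homogeneous sphere of radius `r_nm` suspended in the solvent:
#' (|S1|^2 + |S2|^2) / 2 from the Mie series, with size parameter
#' x = 2 pi n_med r / lambda and relative refractive index
#' m = n_particle / n_med.  In the Rayleigh limit (x << 1) the intensity
#' scales as r^6, which is why large aggregates dominate the DLS signal.
#'
#' @param r_nm Particle radius in nm (vectorized, >= 0; zero radius scatters
#'   nothing).
#' @param setup A [dls_setup()] (wavelength, angle, solvent index).
#' @param particle_refractive_index Refractive index of the particle
#'   material; 1.45 (protein-like) by default.
#' @return Relative scattered intensity, same length as `r_nm`
#'   (dimensionless; meaningful up to a common factor).
#' @export
mie_intensity <- function(r_nm, setup, particle_refractive_index = 1.45) {
  .assert_setup(setup)
  if (any(!is.finite(r_nm)) || any(r_nm < 0))
    stop("radius must be finite and >= 0", call. = FALSE)
  m <- particle_refractive_index / setup$refractive_index
  if (!is.finite(m) || m <= 0)
    stop("invalid relative refractive index", call. = FALSE)
  mu <- cos(setup$angle)
  x_all <- 2 * pi * setup$refractive_index * (r_nm * 1e-9) / setup$wavelength
  vapply(x_all, function(x) {
    if (x == 0) return(0)
    amp <- .mie_amplitudes(m, x, mu)
    (Mod(amp$S1)^2 + Mod(amp$S2)^2) / 2
  }, numeric(1))
}
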