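# Forward electromagnetic model for reflection-mode terahertz imaging of
# tissue held on a dielectric (sapphire) substrate, referenced to the
# reflection from an ideal metal plate.
#
# All media are described by a complex refractive index n^ = n - j*kappa.
# The interface coefficients are the normal-incidence Fresnel amplitudes;
# the measured geometry has a maximum incidence angle of 10 degrees, for
# which the normal-incidence forms are in error by < 1.5% — accepted and
# documented rather than modelled.

#' Build a complex refractive index n - j*kappa
#'
#' @param n real refractive index (dimensionless), recycled against `kappa`.
#' @param kappa extinction coefficient (dimensionless, >= 0).
#' @return a complex vector representing n^ = n - j*kappa.
#' @examples
#' complex_index(2.3, 0.2)
#' @export
complex_index <- function(n, kappa = 0) {
  stopifnot(is.numeric(n), is.numeric(kappa))
  if (any(kappa < 0)) stop_thz("kappa must be >= 0", "thz_domain_error")
  if (any(n <= 0)) stop_thz("n must be positive", "thz_domain_error")
  complex(real = n, imaginary = -kappa)
}

#' Substrate description: thickness plus complex index spectrum
#'
#' A constant index (frequencies = NULL) is valid at every frequency;
#' a tabulated spectrum is linearly interpolated and must cover any
#' frequency at which it is queried.
#'
#' @param thickness substrate thickness in metres (> 0).
#' @param n,kappa real index and extinction coefficient; scalars for a
#'   constant index, or vectors parallel to `frequencies`.
#' @param frequencies optional frequency axis in Hz (strictly increasing).
#' @return an object of class `substrate_spec`.
#' @export
substrate_spec <- function(thickness, n, kappa = 0, frequencies = NULL) {
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0)
    stop_thz("thickness must be a positive scalar (metres)", "thz_domain_error")
  if (!is.null(frequencies)) {
    stopifnot(length(frequencies) == length(n))
    if (length(kappa) == 1) kappa <- rep(kappa, length(n))
    stopifnot(length(kappa) == length(n))
    if (is.unsorted(frequencies, strictly = TRUE))
      stop_thz("frequencies must be strictly increasing", "thz_domain_error")
  } else {
    stopifnot(length(n) == 1, length(kappa) == 1)
  }
  structure(list(thickness = thickness, n = n, kappa = kappa,
                 frequencies = frequencies),
            class = "substrate_spec")
}

#' Nominal C-cut sapphire substrate (synthetic stand-in values)
#'
#' 2-mm thick sapphire holder with a frequency-flat n = 3.07, kappa = 0.005.
#' The true dispersion curve is an instrument-specific calibration input;
#' these constants are a synthetic stand-in of realistic magnitude, not a
#' literature assertion.
#'
#' @return a `substrate_spec`.
#' @export
default_sapphire <- function() substrate_spec(2e-3, n = 3.07, kappa = 0.005)

#' Complex substrate index at given frequencies
#' @param substrate a `substrate_spec`.
#' @param frequency frequency in Hz (vectorized).
#' @return complex vector n^ at each frequency.
#' @export
substrate_index <- function(substrate, frequency) {
  if (is.null(substrate$frequencies)) {
    return(rep(complex_index(substrate$n, substrate$kappa), length(frequency)))
  }
  rng <- range(substrate$frequencies)
  if (any(frequency < rng[1] | frequency > rng[2]))
    stop_thz("substrate index not defined at requested frequency",
             "thz_domain_error")
  n <- stats::approx(substrate$frequencies, substrate$n, xout = frequency)$y
  k <- stats::approx(substrate$frequencies, substrate$kappa, xout = frequency)$y
  complex_index(n, k)
}

#' Normal-incidence Fresnel transmission amplitude
#'
#' T_ab = 2 n^_a / (n^_a + n^_b) for a wave passing from medium a into b.
#'
#' @param a,b complex refractive indices (see [complex_index()]).
#' @return complex transmission amplitude(s).
#' @export
fresnel_transmission <- function(a, b) {
  s <- a + b
  if (any(s == 0)) stop_thz("degenerate media: n^_a + n^_b = 0",
                            "thz_degenerate_media")
  2 * a / s
}

#' Normal-incidence Fresnel reflection amplitude
#'
#' R_ab = (n^_a - n^_b) / (n^_a + n^_b) at the interface from a to b.
#'
#' @inheritParams fresnel_transmission
#' @return complex reflection amplitude(s).
#' @export
fresnel_reflection <- function(a, b) {
  s <- a + b
  if (any(s == 0)) stop_thz("degenerate media: n^_a + n^_b = 0",
                            "thz_degenerate_media")
  (a - b) / s
}

#' Plane-wave propagation factor through a slab
#'
#' P_a(omega, d) = exp(-j omega d n^_a / c). Lossless media (kappa = 0)
#' give |P| = 1; absorbing media give |P| < 1.
#'
#' @param a complex refractive index of the medium.
#' @param d path length in metres (>= 0).
#' @param omega angular frequency in rad/s (> 0).
#' @return complex propagation factor(s).
#' @export
propagation <- function(a, d, omega) {
  if (any(d < 0)) stop_thz("path length must be >= 0", "thz_domain_error")
  if (any(omega <= 0)) stop_thz("omega must be > 0", "thz_domain_error")
  exp(-1i * omega * d * a / .c_light)
}

#' Candidate transfer function of tissue on a substrate
#'
#' Models the time-gated substrate-tissue echo normalized by the metal-plate
#' reference: air-to-substrate transmission, reflection at the
#' substrate-tissue interface, substrate-to-air transmission, and a
#' double pass through the substrate, divided by the ideal-mirror reference
#' response (`mirror_sign`, default -1).
#'
#' @param tissue complex index of the tissue half-space (vectorized).
#' @param substrate a `substrate_spec`.
#' @param omega angular frequency in rad/s (scalar or parallel to `tissue`).
#' @param mirror_sign reference mirror reflection coefficient, -1 (default,
#'   ideal conductor convention) or +1. Only flips a global phase.
#' @return complex transfer value(s).
#' @export
candidate_transfer <- function(tissue, substrate, omega, mirror_sign = -1) {
  air <- complex(real = 1, imaginary = 0)
  ns <- substrate_index(substrate, omega / (2 * pi))
  t_as <- fresnel_transmission(air, ns)
  r_st <- fresnel_reflection(ns, tissue)
  t_sa <- fresnel_transmission(ns, air)
  p2 <- propagation(ns, substrate$thickness, omega)^2
  (t_as * r_st * t_sa * p2) / mirror_sign
}

#' Transfer function of the bare substrate (air behind it)
#'
#' Same echo path as [candidate_transfer()] with the tissue medium replaced
#' by air; used to characterize the substrate from a no-sample measurement.
#'
#' @param ns complex substrate index candidate(s).
#' @param thickness substrate thickness in metres.
#' @param omega angular frequency in rad/s.
#' @param mirror_sign reference convention, see [candidate_transfer()].
#' @return complex transfer value(s).
#' @export
bare_transfer <- function(ns, thickness, omega, mirror_sign = -1) {
  air <- complex(real = 1, imaginary = 0)
  t_as <- fresnel_transmission(air, ns)
  r_sa <- fresnel_reflection(ns, air)
  t_sa <- fresnel_transmission(ns, air)
  p2 <- propagation(ns, thickness, omega)^2
  (t_as * r_sa * t_sa * p2) / mirror_sign
}
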