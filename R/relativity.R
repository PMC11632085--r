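## Active Lorentz boosts along z for axial plane-wave states: Doppler
## mapping of wavenumbers and the forward/inverse transformation of
## scattered amplitudes. Helicity is boost-invariant, so in the helicity
## basis only wavenumbers (and one overall amplitude scale, taken as 1;
## see the methods vignette) change.

#' Active z-boost
#'
#' Speed fraction `beta = v/c` with rapidity `xi = artanh(beta)` for an
#' active Lorentz boost along the z-axis (the molecule moves towards the
#' observer in -z; the passive description is obtained by `beta -> -beta`).
#'
#' @param beta speed fraction, `0 <= beta < 1`.
#' @return object of class `"boost_z"` with fields `beta`, `xi`.
#' @export
boost_z <- function(beta) {
  if (!.is_number(beta) || beta < 0 || beta >= 1) {
    stop("boost_z: beta must satisfy 0 <= beta < 1 (got ", format(beta), ")")
  }
  structure(list(beta = beta, xi = atanh(beta)), class = "boost_z")
}

#' @export
print.boost_z <- function(x, ...) {
  cat("<boost_z> beta=", format(x$beta), "  xi=", format(x$xi), "\n", sep = "")
  invisible(x)
}

#' Axial Doppler factor
#'
#' Wavenumber scale factor for a plane wave propagating along -z under an
#' active z-boost: the forward sense (lab frame F to molecule frame F')
#' gives \eqn{e^{-\xi} = \sqrt{(1-\beta)/(1+\beta)}} (redshift: the molecule
#' recedes from the source), the inverse sense gives \eqn{e^{+\xi}}. The two
#' multiply to 1.
#'
#' @param boost a [boost_z()].
#' @param sense `"forward"` (F -> F') or `"inverse"` (F' -> F).
#' @param propagation_sign propagation direction along z; only `-1`
#'   (the -z geometry of the pipeline) is supported.
#' @return positive scalar.
#' @examples
#' doppler_factor(boost_z(0.6), "forward")  # exactly 1/2
#' @export
doppler_factor <- function(boost, sense = c("forward", "inverse"),
                           propagation_sign = -1) {
  stopifnot(inherits(boost, "boost_z"))
  sense <- match.arg(sense)
  if (!identical(as.numeric(propagation_sign), -1)) {
    stop("doppler_factor: only -z propagation (propagation_sign = -1) is ",
         "supported")
  }
  if (sense == "forward") exp(-boost$xi) else exp(boost$xi)
}

#' Boost the incident plane wave into the molecule frame
#'
#' Active z-boost of an axial (-z) plane wave of pure helicity: the helicity
#' label is invariant (the opposite-helicity channel stays exactly empty),
#' the propagation direction is unchanged, and the wavenumber is multiplied
#' by the forward Doppler factor `exp(-xi)`.
#'
#' @param wave a [plane_wave()] propagating along -z (`theta_k = pi`).
#' @param boost a [boost_z()].
#' @return the boosted `"plane_wave"`.
#' @export
boost_incident <- function(wave, boost) {
  stopifnot(inherits(wave, "plane_wave"), inherits(boost, "boost_z"))
  .check_axial(wave)
  wave$k <- wave$k * doppler_factor(boost, "forward")
  wave
}

#' Inverse-boost forward scattered amplitudes to the lab frame
#'
#' Maps the forward (-z) plane-wave amplitudes obtained in the molecule
#' frame F' back to the lab frame F. Helicity labels are preserved and the
#' wavenumber is scaled by `exp(+xi)`; every amplitude is multiplied by one
#' common helicity-independent factor `s(beta)`, taken to be 1 since it
#' cancels identically in the TCD ratio (the pipeline's observables are
#' amplitude-ratio quantities; see the methods vignette).
#'
#' @param amplitudes a [forward_field_pair()] in the molecule frame.
#' @param k_prime wavenumber in the molecule frame (rad/m).
#' @param boost a [boost_z()].
#' @return list with elements `amplitudes` (the lab-frame
#'   `"forward_field_pair"`) and `k_lab`.
#' @export
inverse_boost_scattered <- function(amplitudes, k_prime, boost) {
  stopifnot(inherits(amplitudes, "forward_field_pair"),
            .is_number(k_prime), k_prime > 0, inherits(boost, "boost_z"))
  s_beta <- 1  # common amplitude scale; provably cancels in the TCD ratio
  amplitudes$scattered <- amplitudes$scattered * s_beta
  amplitudes$incoming <- amplitudes$incoming * s_beta
  k_lab <- k_prime * doppler_factor(boost, "inverse")
  amplitudes$k <- k_lab
  list(amplitudes = amplitudes, k_lab = k_lab)
}

.check_axial <- function(wave) {
  if (abs(wave$theta_k - pi) > 1e-12) {
    stop("unsupported geometry: only -z propagation (theta_k = pi) is ",
         "implemented; got theta_k = ", format(wave$theta_k))
  }
  invisible(TRUE)
}
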