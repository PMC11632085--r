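## Scattering in the molecule frame: spherical-wave expansion of the axial
## plane wave, application of the (rotated) helicity T-matrix, forward
## far-field amplitudes, transmissions and TCD, and rotationally averaged
## absorption/ACD spectra from the same T-matrices.

#' Incident plane wave of pure helicity
#'
#' @param lam helicity, +1 or -1.
#' @param k wavenumber (rad/m), `k > 0`.
#' @param theta_k,phi_k propagation direction (radians); the pipeline's
#'   geometry is `theta_k = pi`, `phi_k = 0` (propagation along -z).
#' @param amplitude complex amplitude (default 1).
#' @return object of class `"plane_wave"`.
#' @export
plane_wave <- function(lam, k, theta_k = pi, phi_k = 0, amplitude = 1 + 0i) {
  stopifnot(lam %in% c(1, -1), .is_number(k), k > 0,
            .is_number(theta_k), .is_number(phi_k),
            length(amplitude) == 1L, is.finite(Re(amplitude)),
            is.finite(Im(amplitude)))
  structure(list(lam = as.integer(lam), k = k, theta_k = theta_k,
                 phi_k = phi_k, amplitude = amplitude + 0i),
            class = "plane_wave")
}

.new_dipole_coefficients <- function(values, role, k) {
  stopifnot(length(values) == 6L, role %in% c("incident", "scattered"))
  names(values) <- c("p.m-1", "p.m0", "p.m+1", "m.m-1", "m.m0", "m.m+1")
  structure(list(values = values + 0i, role = role, k = k),
            class = "dipole_coefficients")
}

#' Expand an axial plane wave in dipolar spherical waves
#'
#' Spherical-wave (l = 1) expansion coefficients of a -z-propagating plane
#' wave of pure helicity in the helicity basis. Only the `m = -lam` entry of
#' the co-helical channel is populated, with value
#' `sqrt(3/(4*pi)) * amplitude` (the Wigner selection rule
#' \eqn{d^1_{m\lambda}(\pi) = \delta_{m,-\lambda}}; the monochromatic radial
#' delta weight is absorbed into the single-wavenumber amplitude, see the
#' methods vignette).
#'
#' @param wave a [plane_wave()] with `theta_k = pi`.
#' @return `"dipole_coefficients"` with role `"incident"`: six complex
#'   amplitudes ordered `(lam=+1, m=-1,0,+1), (lam=-1, m=-1,0,+1)`.
#' @export
expand_plane_wave <- function(wave) {
  stopifnot(inherits(wave, "plane_wave"))
  .check_axial(wave)
  values <- rep(0i, 6)
  values[.hel_index(wave$lam, -wave$lam)] <-
    .pw_coef * wigner_small_d(1L, -wave$lam, wave$lam, pi) * wave$amplitude
  .new_dipole_coefficients(values, "incident", wave$k)
}

#' Apply a helicity-basis T-matrix to incident dipole coefficients
#'
#' Matrix-vector product `B' = T^H A'` in the documented index order.
#'
#' @param tmat a helicity-basis `"tmatrix6"` (possibly rotated).
#' @param a `"dipole_coefficients"` with role `"incident"`.
#' @return `"dipole_coefficients"` with role `"scattered"`.
#' @export
apply_tmatrix <- function(tmat, a) {
  stopifnot(inherits(tmat, "tmatrix6"), inherits(a, "dipole_coefficients"))
  if (tmat$basis != "helicity") {
    stop("apply_tmatrix: T-matrix must be in the helicity basis (got '",
         tmat$basis, "')")
  }
  if (a$role != "incident") {
    stop("apply_tmatrix: coefficients must have role 'incident' (got '",
         a$role, "')")
  }
  .new_dipole_coefficients(drop(tmat$entries %*% a$values), "scattered", a$k)
}

#' Forward far-field plane-wave amplitudes of the scattered field
#'
#' Far-field amplitudes of the scattered field evaluated in the forward
#' direction (`theta_s = pi`, along -z), one per outgoing helicity. By the
#' same Wigner selection rule as in [expand_plane_wave()], only the
#' `m = -lam` entry of each helicity channel radiates exactly forward, with
#' one common normalization constant `sqrt(12*pi)` for both channels (the
#' stationary-phase constant of the l = 1 spherical waves with the
#' `exp(ikr)/(k r)` envelope and its common phase dropped; pinned against
#' brute-force vector-spherical-wave summation in the test suite).
#'
#' @param b `"dipole_coefficients"` with role `"scattered"`.
#' @param k_s outgoing wavenumber (defaults to the wavenumber carried by `b`).
#' @return complex length-2 vector `c(plus = E_s(lam=+1), minus = E_s(lam=-1))`.
#' @export
farfield_forward <- function(b, k_s = b$k) {
  stopifnot(inherits(b, "dipole_coefficients"))
  if (b$role != "scattered") {
    stop("farfield_forward: coefficients must have role 'scattered' (got '",
         b$role, "')")
  }
  c(plus = .ff_norm * b$values[[.hel_index(1L, -1L)]],
    minus = .ff_norm * b$values[[.hel_index(-1L, 1L)]])
}

#' Forward field pair for the two incident helicities
#'
#' Bundles, for each incident helicity, the two forward scattered
#' amplitudes and the incoming (non-interacting) forward amplitude that
#' together make up the outgoing field in the forward direction.
#'
#' @param scattered complex 2x2 matrix; rows = incident helicity (+, -),
#'   columns = outgoing helicity (+, -).
#' @param incoming complex length-2 vector of incoming amplitudes per
#'   incident helicity (default unit).
#' @param k wavenumber the amplitudes refer to (rad/m).
#' @return object of class `"forward_field_pair"`.
#' @export
forward_field_pair <- function(scattered, incoming = c(1 + 0i, 1 + 0i), k = NA_real_) {
  scattered <- matrix(scattered + 0i, 2, 2,
                      dimnames = list(incident = c("plus", "minus"),
                                      outgoing = c("plus", "minus")))
  stopifnot(all(is.finite(Re(scattered))), all(is.finite(Im(scattered))),
            length(incoming) == 2L)
  structure(list(scattered = scattered, incoming = incoming + 0i, k = k),
            class = "forward_field_pair")
}

#' Forward transmissions for the two incident helicities
#'
#' \deqn{T^+ = |E^+_{s,+} + E_{in,+}|^2 + |E^+_{s,-}|^2, \qquad
#'       T^- = |E^-_{s,-} + E_{in,-}|^2 + |E^-_{s,+}|^2.}
#' The incoming amplitude contributes only to the co-helical channel: it
#' does not interact with the molecule but still reaches the forward
#' detector.
#'
#' @param f a [forward_field_pair()].
#' @return numeric `c(T_plus =, T_minus =)`, both non-negative.
#' @export
transmissions <- function(f) {
  stopifnot(inherits(f, "forward_field_pair"))
  sc <- f$scattered
  c(T_plus  = Mod(sc[1, 1] + f$incoming[1])^2 + Mod(sc[1, 2])^2,
    T_minus = Mod(sc[2, 1])^2 + Mod(sc[2, 2] + f$incoming[2])^2)
}

#' Transmission circular dichroism
#'
#' \eqn{TCD = (T^- - T^+)/(T^- + T^+)}, the normalized difference of the
#' forward transmissions for incident waves of negative and positive
#' helicity. Bounded in `[-1, 1]` and antisymmetric under swapping the
#' arguments.
#'
#' @param T_plus,T_minus non-negative transmissions.
#' @return numeric scalar in `[-1, 1]`.
#' @export
tcd <- function(T_plus, T_minus) {
  stopifnot(.is_number(T_plus), .is_number(T_minus),
            T_plus >= 0, T_minus >= 0)
  if (T_plus + T_minus <= 0) {
    stop("tcd: undefined ratio, both transmissions are zero")
  }
  (T_minus - T_plus) / (T_minus + T_plus)
}

## Per-orientation forward pipeline: rotated T-matrix -> scattered dipole
## coefficients for both incident helicities -> forward amplitudes.
.forward_pair_for_tmatrix <- function(tmat, amplitude = 1 + 0i) {
  ap <- expand_plane_wave(plane_wave(1L, tmat$k, amplitude = amplitude))
  am <- expand_plane_wave(plane_wave(-1L, tmat$k, amplitude = amplitude))
  ep <- farfield_forward(apply_tmatrix(tmat, ap))
  em <- farfield_forward(apply_tmatrix(tmat, am))
  forward_field_pair(rbind(ep, em), incoming = c(amplitude, amplitude),
                     k = tmat$k)
}

#' Rotationally averaged absorption and ACD spectra
#'
#' Reconstructs, for every grid energy, the orientation-averaged extinction,
#' scattering and absorption cross sections per incident helicity from the
#' helicity-basis T-matrix via the standard trace formulas
#' \deqn{\sigma_{ext}^\lambda = -\frac{2\pi}{k^2}\,\mathrm{Re}\,
#'   \mathrm{tr}\, T^H_{\lambda\lambda}/3, \qquad
#'   \sigma_{sca}^\lambda = \frac{2\pi}{k^2}\sum_{rows}
#'   |T^H_{\cdot,\lambda}|^2/3,}
#' with absorption = extinction - scattering and the absorption circular
#' dichroism ACD = absorption(+) - absorption(-).
#'
#' @param stack a helicity-basis `"tmatrix_stack"`.
#' @return a `data.frame` of class `"spectrum_set"` with columns
#'   `energy_eV`, `wavelength_nm`, `abs_plus`, `abs_minus`, `acd`,
#'   `ext_plus`, `ext_minus`, `sca_plus`, `sca_minus` (cross sections, m^2).
#' @export
absorption_acd_spectra <- function(stack) {
  stopifnot(inherits(stack, "tmatrix_stack"))
  if (stack$basis != "helicity") {
    stop("absorption_acd_spectra: stack must be in the helicity basis ",
         "(got '", stack$basis, "')")
  }
  blk <- list(`1` = 1:3, `-1` = 4:6)
  rows <- lapply(seq_along(stack$tms), function(i) {
    tm <- stack$tms[[i]]
    pref <- 2 * pi / tm$k^2 / 3
    out <- lapply(blk, function(cols) {
      ext <- -pref * sum(Re(diag(tm$entries[cols, cols, drop = FALSE])))
      sca <- pref * sum(Mod(tm$entries[, cols])^2)
      c(ext = ext, sca = sca, abs = ext - sca)
    })
    data.frame(energy_eV = tm$energy_eV,
               wavelength_nm = .energy_to_wavelength_nm(tm$energy_eV),
               abs_plus = out[["1"]][["abs"]], abs_minus = out[["-1"]][["abs"]],
               acd = out[["1"]][["abs"]] - out[["-1"]][["abs"]],
               ext_plus = out[["1"]][["ext"]], ext_minus = out[["-1"]][["ext"]],
               sca_plus = out[["1"]][["sca"]], sca_minus = out[["-1"]][["sca"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spectrum_set", "data.frame")
  out
}
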