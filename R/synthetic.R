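## Synthetic chiral/achiral polarizability sets: sums of damped-Lorentzian
## oscillators with controllable electric-magnetic (chiral) coupling.
## Stands in for the quantum-chemistry stage so the full pipeline can run
## and be tested without external data.
##
## Line shape: Lambda(E) = gamma / (E0 - E - i*gamma), a single-pole
## resonance, dimensionless with |Lambda(E0)| = 1. Its imaginary part is the
## Lorentzian gamma^2/((E0-E)^2 + gamma^2): strictly positive (absorptive in
## the exp(-i w t) convention) with half-width at half-maximum exactly
## `gamma_hwhm`.
##
## Tensor structure per oscillator (reduced SI units, C m^2/V):
##   a_ee += alpha0 * p p^T * Lambda
##   a_mm += alpha0 * m m^T * Lambda
##   a_em += i * kappa * alpha0 * p m^T * Lambda
##   a_me += -i * kappa * alpha0 * m p^T * Lambda  ( = -t(a_em), reciprocity )
## With |kappa| <= 1 the 6x6 bianisotropic imaginary part is positive
## semidefinite, so the induced T-matrices are passive for weak moments.

#' Synthetic molecular oscillator
#'
#' One damped electronic transition with electric and magnetic transition
#' moments and a chirality coupling.
#'
#' @param resonance_eV transition energy (eV), > 0.
#' @param gamma_hwhm damping, half-width at half-maximum of the absorptive
#'   line shape (eV), > 0. Typical presets use 0.15 eV (broad UV bands) or
#'   0.03 eV (narrow visible bands).
#' @param electric real length-3 electric transition moment direction/
#'   magnitude (dimensionless; overall scale enters via `alpha0` in
#'   [generate_polarizabilities()]).
#' @param magnetic real length-3 magnetic transition moment (same reduced
#'   scale; magnitudes well below the electric ones emulate the weak
#'   magnetic response of molecules).
#' @param kappa chirality coupling in `[-1, 1]`; `0` gives an achiral
#'   oscillator, sign selects the enantiomer.
#' @return object of class `"oscillator"`.
#' @export
oscillator <- function(resonance_eV, gamma_hwhm, electric = c(1, 0, 0),
                       magnetic = c(0, 0, 0), kappa = 0) {
  stopifnot(.is_number(resonance_eV), resonance_eV > 0,
            .is_number(gamma_hwhm), gamma_hwhm > 0,
            is.numeric(electric), length(electric) == 3, all(is.finite(electric)),
            is.numeric(magnetic), length(magnetic) == 3, all(is.finite(magnetic)),
            .is_number(kappa))
  if (abs(kappa) > 1) {
    stop("oscillator: |kappa| <= 1 required for a passive oscillator")
  }
  structure(list(resonance_eV = resonance_eV, gamma_hwhm = gamma_hwhm,
                 electric = electric, magnetic = magnetic, kappa = kappa),
            class = "oscillator")
}

#' Damped-Lorentzian line shape
#'
#' `gamma / (E0 - E - i*gamma)`: dimensionless single-pole resonance whose
#' imaginary part is positive everywhere and peaks at `E0` with HWHM `gamma`.
#'
#' @param energy_eV evaluation energies (eV).
#' @param resonance_eV,gamma_hwhm resonance position and HWHM damping (eV).
#' @return complex vector.
#' @export
lorentzian_lineshape <- function(energy_eV, resonance_eV, gamma_hwhm) {
  gamma_hwhm / (resonance_eV - energy_eV - 1i * gamma_hwhm)
}

#' Generate a synthetic bianisotropic polarizability set
#'
#' Sums damped-Lorentzian oscillator contributions into the four reduced-SI
#' polarizability tensors (see the module notes above). Reciprocity
#' (`a_me = -t(a_em)`, symmetric `a_ee`, `a_mm`) holds exactly by
#' construction, and [mirror_enantiomer()] of the output equals the output
#' for `kappa -> -kappa`.
#'
#' @param oscillators list of [oscillator()] objects (non-empty).
#' @param energies_eV strictly increasing photon-energy grid (non-empty).
#' @param alpha0 overall electric polarizability scale (C m^2/V). The
#'   default, 4e-39 (about 240 atomic units), is typical of a small
#'   biomolecule and keeps the resulting T-matrix entries around 1e-7, deep
#'   in the weak-scattering (passive) regime.
#' @return a [polarizability_set()].
#' @export
generate_polarizabilities <- function(oscillators, energies_eV,
                                      alpha0 = 4e-39) {
  if (!is.list(oscillators) || length(oscillators) == 0) {
    stop("generate_polarizabilities: need a non-empty list of oscillators")
  }
  if (!is.numeric(energies_eV) || length(energies_eV) == 0) {
    stop("generate_polarizabilities: need a non-empty energy grid")
  }
  stopifnot(all(vapply(oscillators, inherits, logical(1), "oscillator")),
            .is_number(alpha0), alpha0 > 0)
  n <- length(energies_eV)
  ee <- array(0i, c(3, 3, n)); mm <- array(0i, c(3, 3, n))
  em <- array(0i, c(3, 3, n)); me <- array(0i, c(3, 3, n))
  for (osc in oscillators) {
    lam <- lorentzian_lineshape(energies_eV, osc$resonance_eV, osc$gamma_hwhm)
    p <- osc$electric; m <- osc$magnetic; kap <- osc$kappa
    pp <- alpha0 * outer(p, p)
    mmx <- alpha0 * outer(m, m)
    pm <- 1i * kap * alpha0 * outer(p, m)
    mp <- -1i * kap * alpha0 * outer(m, p)
    for (i in seq_len(n)) {
      ee[, , i] <- ee[, , i] + pp * lam[i]
      mm[, , i] <- mm[, , i] + mmx * lam[i]
      em[, , i] <- em[, , i] + pm * lam[i]
      me[, , i] <- me[, , i] + mp * lam[i]
    }
  }
  polarizability_set(energies_eV, ee, em, me, mm, units = "si_reduced")
}

#' Synthetic presets
#'
#' Deterministic oscillator lists and energy grids emulating the two damping
#' regimes of molecular response calculations: broad UV bands
#' (`gamma = 0.15` eV, DNA-like) and narrow visible/near-UV bands
#' (`gamma = 0.03` eV, chlorophyll-like, anchored near 3.1 eV / 400 nm).
#'
#' \describe{
#'   \item{`"achiral-iso"`}{three degenerate orthogonal electric oscillators
#'     at 3.1 eV, `kappa = 0`: an isotropic achiral absorber (exact TCD
#'     null).}
#'   \item{`"chiral-single"`}{one chiral oscillator at 3.1 eV,
#'     `gamma = 0.15` eV: the minimal single-band circular-dichroism model.}
#'   \item{`"chiral-dna-like"`}{two UV oscillators (4.6/4.95 eV) with
#'     opposite chirality couplings: an exciton-like bisignate couplet,
#'     `gamma = 0.15` eV.}
#'   \item{`"chiral-chl-like"`}{two narrow bands near 3 eV with
#'     `gamma = 0.03` eV and mixed couplings.}
#' }
#'
#' @param name preset name.
#' @return list with elements `oscillators` (list of [oscillator()]) and
#'   `energies_eV` (numeric grid).
#' @export
synthetic_preset <- function(name = c("achiral-iso", "chiral-single",
                                      "chiral-dna-like", "chiral-chl-like")) {
  name <- match.arg(name)
  switch(name,
    "achiral-iso" = list(
      oscillators = list(
        oscillator(3.1, 0.15, electric = c(1, 0, 0)),
        oscillator(3.1, 0.15, electric = c(0, 1, 0)),
        oscillator(3.1, 0.15, electric = c(0, 0, 1))),
      energies_eV = seq(2.2, 4.0, by = 0.02)),
    "chiral-single" = list(
      oscillators = list(
        oscillator(3.1, 0.15, electric = c(1, 0, 0),
                   magnetic = c(0.1, 0, 0), kappa = 0.6)),
      energies_eV = seq(2.2, 4.0, by = 0.02)),
    "chiral-dna-like" = list(
      oscillators = list(
        oscillator(4.60, 0.15, electric = c(1, 0.2, 0),
                   magnetic = c(0.08, 0.02, 0), kappa = 0.5),
        oscillator(4.95, 0.15, electric = c(0.2, 1, 0.1),
                   magnetic = c(0.02, 0.09, 0.01), kappa = -0.5)),
      energies_eV = seq(3.6, 6.0, by = 0.02)),
    "chiral-chl-like" = list(
      oscillators = list(
        oscillator(3.10, 0.03, electric = c(1, 0.1, 0),
                   magnetic = c(0.07, 0.01, 0), kappa = 0.7),
        oscillator(2.95, 0.03, electric = c(0.3, 0.8, 0.2),
                   magnetic = c(0.02, 0.06, 0.02), kappa = -0.4)),
      energies_eV = seq(2.7, 3.4, by = 0.005))
  )
}

#' Polarizability set for a named preset
#'
#' Convenience wrapper: [generate_polarizabilities()] applied to
#' [synthetic_preset()].
#'
#' @inheritParams synthetic_preset
#' @param alpha0 passed to [generate_polarizabilities()].
#' @return a [polarizability_set()].
#' @export
preset_polarizabilities <- function(name, alpha0 = 4e-39) {
  p <- synthetic_preset(name)
  generate_polarizabilities(p$oscillators, p$energies_eV, alpha0 = alpha0)
}
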