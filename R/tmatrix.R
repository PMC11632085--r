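## Dipolar 6x6 T-matrices from bianisotropic polarizability tensors:
## construction, parity <-> helicity conversion, rotation, enantiomer
## mirroring, validation.
##
## Internal unit convention ("reduced SI"): the four tensors are stored as
##   r_ee = a_ee,  r_em = a_em / Z0,  r_me = a_me * 1/c0? no -- a_me / c0,
##   r_mm = a_mm / (c0 Z0),
## all in C m^2/V, where a_xx are the raw SI tensors of the constitutive
## relations p = a_ee E + a_em H, m = a_me E + a_mm H. In this reduced form
## Onsager reciprocity reads literally r_me = -t(r_em) (because mu0 c0 = Z0),
## and the T-matrix prefactors involve only the ratio of host to vacuum
## impedance/speed.

#' Bianisotropic polarizability set
#'
#' Container for the four complex 3x3 dynamic polarizability tensors on a
#' strictly increasing photon-energy grid. Tensors are stored internally in
#' reduced SI units (all four scaled to C m^2/V, see Details), the natural
#' form for T-matrix assembly.
#'
#' @details The constructor accepts tensors in three unit systems:
#' `"au"` (atomic units, the native output of quantum-chemistry response
#' calculations), `"si"` (raw SI of the constitutive relations
#' `p = a_ee E + a_em H`, `m = a_me E + a_mm H`), or `"si_reduced"` (already
#' reduced; used internally and by the synthetic generator). In reduced form
#' the reciprocity conditions are `a_ee = t(a_ee)`, `a_mm = t(a_mm)`,
#' `a_me = -t(a_em)`.
#'
#' @param energies_eV strictly increasing numeric vector of photon energies.
#' @param alpha_ee,alpha_em,alpha_me,alpha_mm complex arrays of dim
#'   `c(3, 3, length(energies_eV))` (a 3x3 matrix is accepted when the grid
#'   has length one).
#' @param units one of `"au"`, `"si"`, `"si_reduced"`.
#' @return object of class `"polarizability_set"`.
#' @seealso [generate_polarizabilities()], [read_polarizabilities()],
#'   [check_reciprocity()]
#' @export
polarizability_set <- function(energies_eV, alpha_ee, alpha_em, alpha_me,
                               alpha_mm, units = c("si_reduced", "au", "si")) {
  units <- match.arg(units)
  stopifnot(is.numeric(energies_eV), length(energies_eV) >= 1,
            all(is.finite(energies_eV)), all(energies_eV > 0))
  if (length(energies_eV) > 1 && any(diff(energies_eV) <= 0)) {
    stop("polarizability_set: energy grid must be strictly increasing")
  }
  n <- length(energies_eV)
  fix <- function(a, nm) {
    if (is.matrix(a)) a <- array(a, c(3, 3, 1))
    if (!is.array(a) || !all(dim(a) == c(3, 3, n))) {
      stop("polarizability_set: ", nm, " must be a 3x3x", n, " array")
    }
    if (!all(is.finite(Re(a))) || !all(is.finite(Im(a)))) {
      stop("polarizability_set: non-finite entries in ", nm)
    }
    a * (1 + 0i)
  }
  alpha_ee <- fix(alpha_ee, "alpha_ee")
  alpha_em <- fix(alpha_em, "alpha_em")
  alpha_me <- fix(alpha_me, "alpha_me")
  alpha_mm <- fix(alpha_mm, "alpha_mm")
  cv <- switch(units,
    si_reduced = c(ee = 1, em = 1, me = 1, mm = 1),
    si = c(ee = 1, em = 1 / .const$Z0, me = 1 / .const$c0,
           mm = 1 / (.const$c0 * .const$Z0)),
    au = c(ee = .au_to_si$ee,
           em = .au_to_si$em / .const$Z0,
           me = .au_to_si$me / .const$c0,
           mm = .au_to_si$mm / (.const$c0 * .const$Z0))
  )
  structure(
    list(energies_eV = energies_eV,
         alpha_ee = alpha_ee * cv[["ee"]],
         alpha_em = alpha_em * cv[["em"]],
         alpha_me = alpha_me * cv[["me"]],
         alpha_mm = alpha_mm * cv[["mm"]],
         units = "si_reduced"),
    class = "polarizability_set")
}

#' @export
print.polarizability_set <- function(x, ...) {
  cat("<polarizability_set> ", length(x$energies_eV), " energies, ",
      format(min(x$energies_eV)), "-", format(max(x$energies_eV)),
      " eV (reduced SI)\n", sep = "")
  invisible(x)
}

#' Check Onsager reciprocity of a polarizability set
#'
#' Verifies, on the internal reduced-SI tensors, that `a_ee` and `a_mm` are
#' symmetric and `a_me = -t(a_em)` at every grid point.
#'
#' @param pol a [polarizability_set()].
#' @param tol relative tolerance.
#' @return `TRUE` invisibly; throws if violated.
#' @export
check_reciprocity <- function(pol, tol = 1e-10) {
  stopifnot(inherits(pol, "polarizability_set"))
  scl <- max(Mod(pol$alpha_ee), Mod(pol$alpha_em),
             Mod(pol$alpha_me), Mod(pol$alpha_mm), .Machine$double.xmin)
  for (i in seq_along(pol$energies_eV)) {
    dev <- max(Mod(pol$alpha_ee[, , i] - t(pol$alpha_ee[, , i])),
               Mod(pol$alpha_mm[, , i] - t(pol$alpha_mm[, , i])),
               Mod(pol$alpha_me[, , i] + t(pol$alpha_em[, , i])))
    if (dev > tol * scl) {
      stop("check_reciprocity: violation at grid point ", i,
           " (relative deviation ", format(dev / scl), ")")
    }
  }
  invisible(TRUE)
}

#' Host-medium parameters
#'
#' Relative permittivity and permeability of the embedding medium, with the
#' derived wave speed `c_h = c0/sqrt(eps_h mu_h)` and impedance
#' `Z_h = Z0 sqrt(mu_h/eps_h)`. The default (vacuum values) reproduces the
#' convention used for molecules whose solvation is already contained in the
#' quantum-chemistry tensors, i.e. `c_h = c0`.
#'
#' @param eps_h,mu_h positive relative permittivity / permeability.
#' @return object of class `"medium_params"`.
#' @export
medium_params <- function(eps_h = 1, mu_h = 1) {
  stopifnot(.is_number(eps_h), eps_h > 0, .is_number(mu_h), mu_h > 0)
  structure(list(eps_h = eps_h, mu_h = mu_h,
                 c_h = .const$c0 / sqrt(eps_h * mu_h),
                 Z_h = .const$Z0 * sqrt(mu_h / eps_h)),
            class = "medium_params")
}

.parity_order <- "N(-1),N(0),N(+1),M(-1),M(0),M(+1)"
.helicity_order <- "+( -1),+(0),+(+1),-(-1),-(0),-(+1)"

.new_tmatrix6 <- function(entries, k, energy_eV, basis, medium) {
  structure(list(entries = entries, k = k, energy_eV = energy_eV,
                 basis = basis,
                 index_order = if (basis == "parity") .parity_order
                               else .helicity_order,
                 medium = medium),
            class = "tmatrix6")
}

#' @export
print.tmatrix6 <- function(x, ...) {
  cat("<tmatrix6> basis=", x$basis, "  E=", format(x$energy_eV),
      " eV  k=", format(x$k), " rad/m  max|T|=",
      format(max(Mod(x$entries))), "\n", sep = "")
  invisible(x)
}

#' Build a dipolar T-matrix from polarizability tensors
#'
#' Assembles the 6x6 parity-basis T-matrix at one grid point,
#' \deqn{T = \frac{i c_h Z_h k_h^3}{6\pi}
#'   \begin{pmatrix} C\alpha_{ee}C^{-1} & C(-i\alpha_{em}/Z_h)C^{-1} \\
#'   C(i\alpha_{me}/c_h)C^{-1} & C(\alpha_{mm}/(c_h Z_h))C^{-1}
#'   \end{pmatrix},}
#' with `C` from [cartesian_to_spherical_matrix()] and
#' `k_h = E/(hbar c_h)`. Rows/columns are ordered
#' `(N,-1),(N,0),(N,+1),(M,-1),(M,0),(M,+1)` where N/M denote electric/
#' magnetic dipole channels.
#'
#' @param pol a [polarizability_set()].
#' @param medium a [medium_params()] (default: `c_h = c0`).
#' @param grid_index integer index into the energy grid.
#' @return a `"tmatrix6"` in the parity basis.
#' @export
build_tmatrix <- function(pol, medium = medium_params(), grid_index) {
  stopifnot(inherits(pol, "polarizability_set"), inherits(medium, "medium_params"),
            .is_number(grid_index), grid_index == round(grid_index),
            grid_index >= 1, grid_index <= length(pol$energies_eV))
  E <- pol$energies_eV[grid_index]
  k <- .energy_to_k(E, medium$c_h)
  K <- medium$c_h * medium$Z_h * k^3 / (6 * pi)
  C <- cartesian_to_spherical_matrix()
  Ct <- Conj(t(C))
  S <- function(a) C %*% a %*% Ct
  ## reduced tensors carry the vacuum scalings; rescale to the host medium
  rz <- .const$Z0 / medium$Z_h
  rc <- .const$c0 / medium$c_h
  ee <- pol$alpha_ee[, , grid_index]
  em <- pol$alpha_em[, , grid_index] * rz
  me <- pol$alpha_me[, , grid_index] * rc
  mm <- pol$alpha_mm[, , grid_index] * rz * rc
  entries <- (1i * K) * rbind(cbind(S(ee), S(-1i * em)),
                              cbind(S(1i * me), S(mm)))
  .new_tmatrix6(entries, k, E, "parity", medium)
}

#' Build the full T-matrix stack over the energy grid
#'
#' @inheritParams build_tmatrix
#' @return object of class `"tmatrix_stack"`: T-matrices (shared basis) on
#'   the polarizability grid.
#' @export
build_tmatrix_stack <- function(pol, medium = medium_params()) {
  tms <- lapply(seq_along(pol$energies_eV), function(i)
    build_tmatrix(pol, medium, i))
  structure(list(energies_eV = pol$energies_eV,
                 k = vapply(tms, function(t) t$k, numeric(1)),
                 tms = tms, basis = "parity", medium = medium),
            class = "tmatrix_stack")
}

#' @export
print.tmatrix_stack <- function(x, ...) {
  cat("<tmatrix_stack> ", length(x$tms), " energies, basis=", x$basis, ", ",
      format(min(x$energies_eV)), "-", format(max(x$energies_eV)), " eV\n",
      sep = "")
  invisible(x)
}

## unitary parity -> helicity map: lam = +1 channel is (N + M)/sqrt(2)
.U_parity_to_helicity <- function() {
  I3 <- diag(3)
  rbind(cbind(I3, I3), cbind(I3, -I3)) / sqrt(2)
}

#' Convert a T-matrix between parity and helicity bases
#'
#' `parity_to_helicity()` conjugates by the unitary mixing the electric (N)
#' and magnetic (M) dipole channels into helicity channels
#' \eqn{(N \pm M)/\sqrt2} (the `+` combination is helicity +1);
#' `helicity_to_parity()` is its exact inverse.
#'
#' @param x a `"tmatrix6"` or `"tmatrix_stack"`.
#' @return the same class in the other basis.
#' @export
parity_to_helicity <- function(x) UseMethod("parity_to_helicity")

#' @export
parity_to_helicity.tmatrix6 <- function(x) {
  if (x$basis != "parity") stop("parity_to_helicity: T-matrix is in basis '",
                                x$basis, "', expected 'parity'")
  U <- .U_parity_to_helicity()
  .new_tmatrix6(U %*% x$entries %*% t(U), x$k, x$energy_eV, "helicity",
                x$medium)
}

#' @export
parity_to_helicity.tmatrix_stack <- function(x) {
  if (x$basis != "parity") stop("parity_to_helicity: stack is in basis '",
                                x$basis, "', expected 'parity'")
  x$tms <- lapply(x$tms, parity_to_helicity)
  x$basis <- "helicity"
  x
}

#' @rdname parity_to_helicity
#' @export
helicity_to_parity <- function(x) UseMethod("helicity_to_parity")

#' @export
helicity_to_parity.tmatrix6 <- function(x) {
  if (x$basis != "helicity") stop("helicity_to_parity: T-matrix is in basis '",
                                  x$basis, "', expected 'helicity'")
  U <- .U_parity_to_helicity()  # involutory up to transpose; U is symmetric
  .new_tmatrix6(t(U) %*% x$entries %*% U, x$k, x$energy_eV, "parity", x$medium)
}

#' @export
helicity_to_parity.tmatrix_stack <- function(x) {
  if (x$basis != "helicity") stop("helicity_to_parity: stack is in basis '",
                                  x$basis, "', expected 'helicity'")
  x$tms <- lapply(x$tms, helicity_to_parity)
  x$basis <- "parity"
  x
}

#' Rotate a helicity-basis T-matrix
#'
#' Applies the active rotation `R = Ry(theta) Rz(Phi)` (zyz Euler angles
#' `(0, theta, Phi)`) to the scatterer: \eqn{T_R = R\,T\,R^{-1}} with `R`
#' block-diagonal in the two helicity channels, each block the l = 1
#' Wigner-D matrix `wigner_D1_matrix(0, theta, Phi)`. The initial (leftmost)
#' z-rotation of the full Euler triple is omitted: it rotates the molecule
#' about the axis of the circularly polarized beam and therefore only
#' contributes a global phase to the forward amplitudes. With this
#' parameterization the two angles `(theta, Phi)` sampled uniformly on the
#' sphere reproduce the full rotational average of axial observables.
#' Equivalent to rotating the underlying Cartesian tensors,
#' `alpha -> R alpha t(R)`.
#'
#' @param tmat a helicity-basis `"tmatrix6"`.
#' @param theta,Phi rotation angles (radians): polar tilt about y after an
#'   azimuthal turn about z.
#' @return rotated `"tmatrix6"` (helicity basis).
#' @export
rotate_tmatrix <- function(tmat, theta, Phi) {
  stopifnot(inherits(tmat, "tmatrix6"))
  if (tmat$basis != "helicity") {
    stop("rotate_tmatrix: T-matrix must be in the helicity basis (got '",
         tmat$basis, "')")
  }
  R6 <- .rotation6(theta, Phi)
  tmat$entries <- R6 %*% tmat$entries %*% Conj(t(R6))
  tmat
}

.rotation6 <- function(theta, Phi) {
  D <- wigner_D1_matrix(0, theta, Phi)
  Z <- matrix(0i, 3, 3)
  rbind(cbind(D, Z), cbind(Z, D))
}

#' Mirror a polarizability set into its enantiomer
#'
#' Negates the magnetoelectric coupling tensors (`alpha_em`, `alpha_me`)
#' while leaving `alpha_ee` and `alpha_mm` unchanged -- the dipolar-order
#' signature of a mirror-image molecule. An involution; the fixed points are
#' exactly the achiral (uncoupled) sets, and all circular-dichroism
#' observables change sign.
#'
#' @param pol a [polarizability_set()].
#' @return the mirrored set.
#' @export
mirror_enantiomer <- function(pol) {
  stopifnot(inherits(pol, "polarizability_set"))
  pol$alpha_em <- -pol$alpha_em
  pol$alpha_me <- -pol$alpha_me
  pol
}

#' Passivity defect of a T-matrix
#'
#' Smallest eigenvalue of the Hermitian form \eqn{-(T+T^\dagger)/2 -
#' T^\dagger T}. A passive (non-amplifying) scatterer has this matrix
#' positive semidefinite, so the returned value should be `>= -tol` for a
#' physically admissible T-matrix.
#'
#' @param tmat a `"tmatrix6"` (either basis; the form is basis-invariant under
#'   the unitary parity/helicity conversion).
#' @return smallest eigenvalue (numeric scalar).
#' @export
passivity_defect <- function(tmat) {
  stopifnot(inherits(tmat, "tmatrix6"))
  Tm <- tmat$entries
  H <- -(Tm + Conj(t(Tm))) / 2 - Conj(t(Tm)) %*% Tm
  min(Re(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
}
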