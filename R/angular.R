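## Angular-momentum toolbox: Wigner rotation functions, helical polarization
## vectors, and the Cartesian <-> spherical basis matrix. Pure functions.

#' Wigner small-d function
#'
#' Evaluates the real rotation matrix element \eqn{d^l_{m\lambda}(\theta)} in
#' the Varshalovich sign convention (zyz, active rotations) via the standard
#' factorial series. For `l = 1` this reduces to the closed forms
#' \eqn{(1\pm\cos\theta)/2}, \eqn{\mp\sin\theta/\sqrt 2} and \eqn{\cos\theta}.
#'
#' @param l non-negative integer order.
#' @param m,lam integer projections, `|m| <= l`, `|lam| <= l`.
#' @param theta rotation angle about y, radians. May be a vector.
#' @return numeric vector, `d^l_{m lam}(theta)`.
#' @examples
#' wigner_small_d(1, 0, 0, pi / 3)  # cos(pi/3)
#' @export
wigner_small_d <- function(l, m, lam, theta) {
  stopifnot(.is_number(l), l >= 0, l == round(l),
            .is_number(m), m == round(m), .is_number(lam), lam == round(lam))
  if (abs(m) > l || abs(lam) > l) {
    stop("wigner_small_d: need |m| <= l and |lam| <= l (got l=", l,
         ", m=", m, ", lam=", lam, ")")
  }
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  ## d^l_{m lam} = sum_s (-1)^(m - lam + s) * sqrt((l+m)!(l-m)!(l+lam)!(l-lam)!)
  ##   / ((l+lam-s)! s! (m-lam+s)! (l-m-s)!)
  ##   * cos(t/2)^(2l-2s+lam-m) * sin(t/2)^(m-lam+2s)
  s_min <- max(0L, lam - m)
  s_max <- min(l + lam, l - m)
  ct <- cos(theta / 2)
  st <- sin(theta / 2)
  pref <- exp(0.5 * (lfactorial(l + m) + lfactorial(l - m) +
                       lfactorial(l + lam) + lfactorial(l - lam)))
  out <- numeric(length(theta))
  for (s in s_min:s_max) {
    term <- (-1)^(m - lam + s) /
      exp(lfactorial(l + lam - s) + lfactorial(s) +
            lfactorial(m - lam + s) + lfactorial(l - m - s))
    out <- out + term * ct^(2 * l - 2 * s + lam - m) * st^(m - lam + 2 * s)
  }
  pref * out
}

#' Wigner D-matrix element
#'
#' \eqn{D^l_{m\lambda}(\phi,\theta,\psi) =
#' e^{-im\phi}\, d^l_{m\lambda}(\theta)\, e^{-i\lambda\psi}} for active zyz
#' Euler rotations. At `l = 1` and in the spherical component order
#' `m = (-1, 0, +1)` used throughout the package, the full 3x3 matrix equals
#' `C %*% Rz(phi) %*% Ry(theta) %*% Rz(psi) %*% Conj(t(C))` with `C` from
#' [cartesian_to_spherical_matrix()].
#'
#' @inheritParams wigner_small_d
#' @param phi,theta,psi Euler angles (z, y, z), radians.
#' @return complex scalar (or vector along `theta`).
#' @export
wigner_D <- function(l, m, lam, phi, theta, psi) {
  stopifnot(.is_number(phi), .is_number(psi))
  exp(-1i * m * phi) * wigner_small_d(l, m, lam, theta) * exp(-1i * lam * psi)
}

#' Full l = 1 Wigner-D matrix
#'
#' 3x3 complex matrix with rows/columns ordered `m = (-1, 0, +1)`.
#'
#' @inheritParams wigner_D
#' @return complex 3x3 matrix `D[m, m'] = D^1_{m m'}(phi, theta, psi)`.
#' @export
wigner_D1_matrix <- function(phi, theta, psi = 0) {
  ms <- c(-1L, 0L, 1L)
  out <- matrix(0i, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    out[i, j] <- wigner_D(1L, ms[i], ms[j], phi, theta, psi)
  }
  out
}

#' Helical polarization vector
#'
#' Unit polarization vector of a circularly polarized plane wave of helicity
#' `lam` propagating along the direction `(theta_k, phi_k)`:
#' \eqn{\hat e_\lambda = (-\lambda\hat\theta - i\hat\phi)/\sqrt2}. It is
#' orthogonal to the propagation direction and an eigenvector of
#' \eqn{i\hat k \times} with eigenvalue \eqn{\lambda}. At the poles
#' (`theta_k` 0 or pi) the continuous limits
#' \eqn{\hat\theta = (\cos\theta\cos\phi, \cos\theta\sin\phi, -\sin\theta)},
#' \eqn{\hat\phi = (-\sin\phi, \cos\phi, 0)} are used with `phi_k` as given.
#'
#' @param theta_k,phi_k propagation direction, radians.
#' @param lam helicity, +1 or -1.
#' @return complex length-3 vector (Cartesian components).
#' @examples
#' helical_polarization(pi, 0, 1)  # (x - i y)/sqrt(2), the -z-propagating LCP
#' @export
helical_polarization <- function(theta_k, phi_k, lam) {
  stopifnot(.is_number(theta_k), .is_number(phi_k), lam %in% c(1, -1))
  th_hat <- c(cos(theta_k) * cos(phi_k), cos(theta_k) * sin(phi_k), -sin(theta_k))
  ph_hat <- c(-sin(phi_k), cos(phi_k), 0)
  (-lam * th_hat - 1i * ph_hat) / sqrt(2)
}

#' Cartesian to spherical basis matrix
#'
#' The constant unitary matrix `C` mapping Cartesian vector components
#' `(x, y, z)` to spherical components ordered `m = (-1, 0, +1)`. Rows are the
#' conjugate-transposed spherical basis vectors
#' \eqn{e_{-1} = (\hat x - i\hat y)/\sqrt2}, \eqn{e_0 = \hat z},
#' \eqn{e_{+1} = -(\hat x + i\hat y)/\sqrt2} (Condon-Shortley phases), so that
#' `C %*% a` gives the spherical components of a Cartesian vector `a` and
#' `C %*% A %*% Conj(t(C))` transforms a rank-2 tensor.
#'
#' @return complex 3x3 unitary matrix.
#' @export
cartesian_to_spherical_matrix <- function() {
  rbind(c(1, 1i, 0) / sqrt(2),
        c(0, 0, 1),
        c(-1, 1i, 0) / sqrt(2))
}
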