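# Independent oracles used across the suite. These deliberately avoid the
# package's Wigner-function shortcut paths: spherical harmonics and their
# derivatives are written out explicitly, radial functions use closed-form
# spherical Hankel/Bessel expressions, and the curl is taken numerically.

# ---- l = 1 vector spherical wavefunctions (Condon-Shortley phases) --------

.or_N1 <- sqrt(3 / (8 * pi))

.or_Y1 <- function(m, th, ph) {
  if (m == 0) sqrt(3 / (4 * pi)) * cos(th)
  else if (m == 1) -.or_N1 * sin(th) * exp(1i * ph)
  else .or_N1 * sin(th) * exp(-1i * ph)
}
.or_dY1_dth <- function(m, th, ph) {
  if (m == 0) -sqrt(3 / (4 * pi)) * sin(th)
  else if (m == 1) -.or_N1 * cos(th) * exp(1i * ph)
  else .or_N1 * cos(th) * exp(-1i * ph)
}
# (1/sin th) dY/dph, analytic limit
.or_Y1_phi <- function(m, th, ph) {
  if (m == 0) 0 + 0i
  else if (m == 1) -1i * .or_N1 * exp(1i * ph)
  else -1i * .or_N1 * exp(-1i * ph)
}

.or_units <- function(th, ph) {
  list(r  = c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
       th = c(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th)),
       ph = c(-sin(ph), cos(ph), 0))
}

# X_{1m} = L Y_{1m} / sqrt(2), L = -i (phi_hat d/dth - th_hat (1/sin) d/dph)
.or_X1 <- function(m, th, ph) {
  u <- .or_units(th, ph)
  (-1i) * (u$ph * .or_dY1_dth(m, th, ph) - u$th * .or_Y1_phi(m, th, ph)) /
    sqrt(2)
}

.or_h1 <- function(x) -(1 + 1i / x) * exp(1i * x) / x

# outgoing magnetic multipole M_{1m}(r) at k = 1
.or_M1 <- function(m, r3) {
  r <- sqrt(sum(r3^2))
  th <- acos(r3[3] / r)
  ph <- atan2(r3[2], r3[1])
  .or_h1(r) * .or_X1(m, th, ph)
}

.or_num_curl <- function(f, r3, h = 1e-3) {
  d <- diag(3)
  J <- sapply(1:3, function(j) (f(r3 + h * d[j, ]) - f(r3 - h * d[j, ])) /
                (2 * h))
  c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
}

.or_e_hel <- function(lam, th, ph) {
  u <- .or_units(th, ph)
  (-lam * u$th - 1i * u$ph) / sqrt(2)
}

# Brute-force forward far field of a package coefficient vector (order
# (+,-1),(+,0),(+,+1),(-,-1),(-,0),(-,+1)). The package's spherical waves
# are the helicity combinations (N + lam M)/sqrt(2) scaled by the uniform
# plane-wave-matching constant -4*pi*i; the returned amplitudes divide out
# the exp(ikr)/(kr) envelope and the common -i phase, matching the
# farfield_forward() normalization.
oracle_farfield_forward <- function(bvals, kr = 1e6) {
  r3 <- c(0, 0, -kr)
  E <- c(0i, 0i, 0i)
  i <- 0L
  for (lam in c(1, -1)) for (m in c(-1, 0, 1)) {
    i <- i + 1L
    if (bvals[i] == 0) next
    Mv <- .or_M1(m, r3)
    Nv <- .or_num_curl(function(x) .or_M1(m, x), r3)
    E <- E + bvals[i] * (-4i * pi) * (Nv + lam * Mv) / sqrt(2)
  }
  env <- exp(1i * kr) / kr
  c(plus  = sum(Conj(.or_e_hel(1, pi, 0)) * E) / env / (-1i),
    minus = sum(Conj(.or_e_hel(-1, pi, 0)) * E) / env / (-1i))
}

# ---- Cartesian zyz rotation matrices --------------------------------------

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                           c(0, 0, 1))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                           c(-sin(a), 0, cos(a)))
rot_zyz <- function(phi, theta, psi) rot_z(phi) %*% rot_y(theta) %*% rot_z(psi)

# ---- fixtures -------------------------------------------------------------

# random reciprocal chiral polarizability set (reduced SI), weak-scatterer
# scale comparable to the synthetic presets
random_reciprocal_pol <- function(seed, n_energy = 5, scale = 4e-39,
                                  chiral = TRUE) {
  set.seed(seed)
  energies <- seq(2.5, 3.5, length.out = n_energy)
  rmat <- function() matrix(stats::rnorm(9), 3, 3) +
    1i * matrix(stats::rnorm(9), 3, 3)
  sym <- function(a) (a + t(a)) / 2
  ee <- array(0i, c(3, 3, n_energy)); mm <- array(0i, c(3, 3, n_energy))
  em <- array(0i, c(3, 3, n_energy)); me <- array(0i, c(3, 3, n_energy))
  for (i in seq_len(n_energy)) {
    ee[, , i] <- sym(rmat()) * scale
    mm[, , i] <- sym(rmat()) * scale * 1e-2
    if (chiral) {
      em[, , i] <- rmat() * scale * 1e-1
      me[, , i] <- -t(em[, , i])
    }
  }
  polarizability_set(energies, ee, em, me, mm, units = "si_reduced")
}

# pre-rotate every T-matrix of a helicity stack by a fixed global rotation
rotate_stack <- function(stack, phi, theta, psi = 0) {
  D <- wigner_D1_matrix(phi, theta, psi)
  Z <- matrix(0i, 3, 3)
  R6 <- rbind(cbind(D, Z), cbind(Z, D))
  stack$tms <- lapply(stack$tms, function(tm) {
    tm$entries <- R6 %*% tm$entries %*% Conj(t(R6))
    tm
  })
  stack
}

# single-energy polarizability set from scalar (or matrix) blocks
pol_single <- function(ee = 0, em = 0, me = NULL, mm = 0, energy = 3.1) {
  as_arr <- function(x) {
    if (is.matrix(x)) array(x, c(3, 3, 1)) else array(x * diag(3), c(3, 3, 1))
  }
  me <- if (is.null(me)) {
    m <- as_arr(em); m[, , 1] <- -t(m[, , 1]); m
  } else as_arr(me)
  polarizability_set(energy, as_arr(ee), as_arr(em), me, as_arr(mm),
                     units = "si_reduced")
}

# forward field pair of an unrotated helicity T-matrix with unit incidence
.pair_from_tmat <- function(tm) {
  ap <- expand_plane_wave(plane_wave(1, tm$k))
  am <- expand_plane_wave(plane_wave(-1, tm$k))
  ep <- farfield_forward(apply_tmatrix(tm, ap))
  em <- farfield_forward(apply_tmatrix(tm, am))
  forward_field_pair(rbind(ep, em), k = tm$k)
}

# single-orientation TCD for a helicity tmatrix6 (no averaging)
single_orientation_tcd <- function(tm, theta = 0, Phi = 0) {
  tr <- rotate_tmatrix(tm, theta, Phi)
  ap <- expand_plane_wave(plane_wave(1, tr$k))
  am <- expand_plane_wave(plane_wave(-1, tr$k))
  ep <- farfield_forward(apply_tmatrix(tr, ap))
  em <- farfield_forward(apply_tmatrix(tr, am))
  tt <- transmissions(forward_field_pair(rbind(ep, em), k = tr$k))
  tcd(tt[["T_plus"]], tt[["T_minus"]])
}
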