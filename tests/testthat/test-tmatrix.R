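# T-matrix construction, basis conversion, rotation, mirroring, passivity.

K_pref <- function(energy_eV) {
  k <- energy_eV * 1.602176634e-19 / (1.054571817e-34 * 299792458)
  299792458 * 376.730313668 * k^3 / (6 * pi)
}

test_that("build_tmatrix reproduces the scalar-block closed forms", {
  E <- 3.1; K <- K_pref(E)
  # all-zero tensors -> zero matrix
  t0 <- build_tmatrix(pol_single(), grid_index = 1)
  expect_true(all(t0$entries == 0))
  # isotropic electric: T_NN = i K a I, other blocks zero
  a <- (2 - 0.5i) * 1e-39
  te <- build_tmatrix(pol_single(ee = a), grid_index = 1)
  expect_lt(max(Mod(te$entries[1:3, 1:3] - 1i * K * a * diag(3))),
            1e-12 * K * Mod(a))
  expect_equal(max(Mod(te$entries[4:6, ])), 0)
  expect_equal(max(Mod(te$entries[1:3, 4:6])), 0)
  # isotropic magnetoelectric: T_NM = K g I (the -i cancels the global i)
  g <- (1 + 1i) * 1e-40
  tg <- build_tmatrix(pol_single(em = g), grid_index = 1)
  expect_lt(max(Mod(tg$entries[1:3, 4:6] - K * g * diag(3))),
            1e-12 * K * Mod(g))
  expect_equal(max(Mod(tg$entries[1:3, 1:3])), 0)
  expect_equal(max(Mod(tg$entries[4:6, 4:6])), 0)
})

test_that("build_tmatrix is linear in each tensor block (superposition)", {
  pol1 <- random_reciprocal_pol(21, n_energy = 3)
  pol2 <- random_reciprocal_pol(22, n_energy = 3)
  pol2$energies_eV <- pol1$energies_eV
  sum_pol <- pol1
  for (f in c("alpha_ee", "alpha_em", "alpha_me", "alpha_mm")) {
    sum_pol[[f]] <- pol1[[f]] + pol2[[f]]
  }
  for (i in 1:3) {
    t1 <- build_tmatrix(pol1, grid_index = i)
    t2 <- build_tmatrix(pol2, grid_index = i)
    ts <- build_tmatrix(sum_pol, grid_index = i)
    scl <- max(Mod(ts$entries))
    expect_lt(max(Mod(ts$entries - t1$entries - t2$entries)), 1e-12 * scl)
  }
})

test_that("reciprocal polarizabilities give a reciprocal T-matrix", {
  # For alpha_ee = t(alpha_ee), alpha_mm = t(alpha_mm), alpha_me = -t(alpha_em)
  # the parity-basis blocks satisfy X_{m m'} = (-1)^{m+m'} sigma X'_{-m',-m}
  # with sigma = +1 within NN/MM and the NM <-> MN exchange.
  pol <- random_reciprocal_pol(31, n_energy = 2)
  check_reciprocity(pol)
  tm <- build_tmatrix(pol, grid_index = 1)
  Tm <- tm$entries
  ms <- c(-1, 0, 1)
  idx <- function(p, m) (p - 1) * 3 + match(m, ms)  # p = 1 (N), 2 (M)
  worst <- 0
  for (p1 in 1:2) for (p2 in 1:2) for (m1 in ms) for (m2 in ms) {
    lhs <- Tm[idx(p1, m1), idx(p2, m2)]
    rhs <- (-1)^(m1 + m2) * Tm[idx(p2, -m2), idx(p1, -m1)]
    worst <- max(worst, Mod(lhs - rhs))
  }
  expect_lt(worst, 1e-12 * max(Mod(Tm)))
})

test_that("parity <-> helicity conversion is unitary, involutive and maps the
           achiral-diagonal case to a scalar matrix", {
  pol <- random_reciprocal_pol(41, n_energy = 2)
  tp <- build_tmatrix(pol, grid_index = 2)
  th <- parity_to_helicity(tp)
  expect_identical(th$basis, "helicity")
  back <- helicity_to_parity(th)
  expect_lt(max(Mod(back$entries - tp$entries)), 1e-14 * max(Mod(tp$entries)))
  # zero matrix stays zero
  t0 <- build_tmatrix(pol_single(), grid_index = 1)
  expect_true(all(parity_to_helicity(t0)$entries == 0))
  # T_NN = T_MM = t I, off-diagonal zero -> t I6 in helicity basis
  tnn <- 3e-8 + 1e-9i
  tp2 <- t0
  tp2$entries[1:3, 1:3] <- tnn * diag(3)
  tp2$entries[4:6, 4:6] <- tnn * diag(3)
  th2 <- parity_to_helicity(tp2)
  expect_lt(max(Mod(th2$entries - tnn * diag(6))), 1e-15)
  # singular values preserved by the unitary conversion
  expect_equal(svd(th$entries)$d, svd(tp$entries)$d, tolerance = 1e-10)
  # wrong-basis usage errors
  expect_error(parity_to_helicity(th), "basis")
  expect_error(helicity_to_parity(tp), "basis")
})

test_that("rotation: identity at zero angles, scalars invariant, singular
           values preserved, and consistent with Cartesian tensor rotation", {
  pol <- random_reciprocal_pol(51, n_energy = 2)
  th <- parity_to_helicity(build_tmatrix(pol, grid_index = 1))
  expect_lt(max(Mod(rotate_tmatrix(th, 0, 0)$entries - th$entries)),
            1e-14 * max(Mod(th$entries)))
  iso <- th; iso$entries <- (2e-8 + 3e-9i) * diag(6)
  rot_iso <- rotate_tmatrix(iso, 1.1, 2.3)
  expect_lt(max(Mod(rot_iso$entries - iso$entries)), 1e-14 * 2e-8)
  set.seed(7)
  for (i in 1:10) {
    ang <- c(stats::runif(1, 0, pi), stats::runif(1, 0, 2 * pi))
    tr <- rotate_tmatrix(th, ang[1], ang[2])
    expect_equal(svd(tr$entries)$d, svd(th$entries)$d,
                 tolerance = 1e-12)
  }
  # rotating the T-matrix == building from Cartesian-rotated tensors
  ang <- c(0.9, 2.0)
  R <- rot_y(ang[1]) %*% rot_z(ang[2])
  pol_rot <- pol
  for (f in c("alpha_ee", "alpha_em", "alpha_me", "alpha_mm")) {
    for (i in seq_along(pol$energies_eV)) {
      pol_rot[[f]][, , i] <- R %*% pol[[f]][, , i] %*% t(R)
    }
  }
  th_rot <- parity_to_helicity(build_tmatrix(pol_rot, grid_index = 1))
  direct <- rotate_tmatrix(th, ang[1], ang[2])
  expect_lt(max(Mod(th_rot$entries - direct$entries)),
            1e-12 * max(Mod(th$entries)))
  # rotation requires the helicity basis
  expect_error(rotate_tmatrix(build_tmatrix(pol, grid_index = 1), 0.1, 0.2),
               "helicity")
})

test_that("mirror_enantiomer is an involution with achiral fixed points", {
  pol <- random_reciprocal_pol(61, n_energy = 2)
  m1 <- mirror_enantiomer(pol)
  expect_equal(m1$alpha_em, -pol$alpha_em)
  expect_equal(m1$alpha_me, -pol$alpha_me)
  expect_equal(m1$alpha_ee, pol$alpha_ee)
  expect_equal(mirror_enantiomer(m1), pol)
  ach <- random_reciprocal_pol(62, n_energy = 2, chiral = FALSE)
  expect_equal(mirror_enantiomer(ach), ach)
})

test_that("every shipped preset yields passive T-matrices", {
  for (nm in c("achiral-iso", "chiral-single", "chiral-dna-like",
               "chiral-chl-like")) {
    stack <- build_tmatrix_stack(preset_polarizabilities(nm))
    defects <- vapply(stack$tms, passivity_defect, numeric(1))
    expect_gt(min(defects), -1e-12)
  }
})

test_that("polarizability_set validates its inputs", {
  arr <- array(0i, c(3, 3, 2))
  expect_error(polarizability_set(c(2, 1), arr, arr, arr, arr),
               "strictly increasing")
  bad <- arr; bad[1, 1, 1] <- NaN
  expect_error(polarizability_set(c(1, 2), bad, arr, arr, arr), "non-finite")
  expect_error(polarizability_set(c(1, 2), arr[, , 1], arr, arr, arr),
               "3x3x2")
  expect_error(medium_params(eps_h = -1))
})

test_that("atomic-unit import applies the documented CODATA conversion", {
  # alpha_ee = 1 a.u. = e^2 a0^2 / Eh in SI
  au_ee <- 1.602176634e-19^2 * 5.29177210903e-11^2 / 4.3597447222071e-18
  one <- array(diag(3), c(3, 3, 1))
  zero <- array(0i, c(3, 3, 1))
  pol <- polarizability_set(3.0, one, zero, zero, zero, units = "au")
  expect_equal(Re(pol$alpha_ee[1, 1, 1]), au_ee, tolerance = 1e-12)
  # reciprocity is unit-system consistent: an a.u.-reciprocal set stays
  # reciprocal after conversion to the internal reduced-SI form
  em_au <- matrix(stats::rnorm(9), 3, 3) + 1i * matrix(stats::rnorm(9), 3, 3)
  pol2 <- polarizability_set(3.0, one, array(em_au, c(3, 3, 1)),
                             array(-t(em_au), c(3, 3, 1)), zero, units = "au")
  expect_silent(check_reciprocity(pol2))
})
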