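# Plane-wave expansion, T-matrix application, far fields, transmissions,
# TCD arithmetic, absorption/ACD spectra.

test_that("expand_plane_wave populates only the co-helical m = -lam entry
           with sqrt(3/4pi) times the amplitude", {
  k <- 2 * pi / 350e-9
  a_p <- expand_plane_wave(plane_wave(1, k))
  expect_equal(unname(a_p$values[1]), sqrt(3 / (4 * pi)) + 0i,
               tolerance = 1e-15)
  expect_identical(unname(a_p$values[-1]), rep(0i, 5))
  a_m <- expand_plane_wave(plane_wave(-1, k))
  expect_equal(unname(a_m$values[6]), sqrt(3 / (4 * pi)) + 0i,
               tolerance = 1e-15)
  expect_identical(unname(a_m$values[-6]), rep(0i, 5))
  # linearity in the amplitude, zero in -> zero out
  amp <- 0.3 - 1.2i
  a_s <- expand_plane_wave(plane_wave(1, k, amplitude = amp))
  expect_equal(a_s$values, a_p$values * amp, tolerance = 1e-15)
  a_0 <- expand_plane_wave(plane_wave(1, k, amplitude = 0))
  expect_identical(unname(a_0$values), rep(0i, 6))
  expect_error(expand_plane_wave(plane_wave(1, k, theta_k = 0.5)),
               "unsupported geometry")
})

test_that("apply_tmatrix is a plain 6x6 product with role bookkeeping", {
  pol <- random_reciprocal_pol(71, n_energy = 1)
  th <- parity_to_helicity(build_tmatrix(pol, grid_index = 1))
  a <- expand_plane_wave(plane_wave(1, th$k))
  b <- apply_tmatrix(th, a)
  expect_identical(b$role, "scattered")
  # brute-force index-by-index summation oracle
  set.seed(72)
  av <- a$values
  av[] <- stats::rnorm(6) + 1i * stats::rnorm(6)
  a2 <- a; a2$values <- av
  b2 <- apply_tmatrix(th, a2)
  brute <- vapply(1:6, function(i) sum(th$entries[i, ] * av), complex(1))
  expect_lt(max(Mod(b2$values - brute)), 1e-15 * max(Mod(brute)))
  # scalar T preserves helicity channels
  iso <- th; iso$entries <- (4e-8 + 1e-8i) * diag(6)
  b3 <- apply_tmatrix(iso, a)
  expect_equal(b3$values, a$values * (4e-8 + 1e-8i), tolerance = 1e-15)
  # usage errors
  expect_error(apply_tmatrix(build_tmatrix(pol, grid_index = 1), a), "basis")
  expect_error(apply_tmatrix(th, b), "incident")
})

test_that("farfield_forward matches brute-force vector-spherical-wave
           summation at k r = 1e6 on random coefficient vectors", {
  set.seed(9)
  worst <- 0
  for (rep in 1:100) {
    bvals <- stats::rnorm(6) + 1i * stats::rnorm(6)
    b <- apply_tmatrix(
      structure(list(entries = diag(6) + 0i, k = 1, basis = "helicity"),
                class = "tmatrix6"),
      structure(list(values = bvals + 0i, role = "incident", k = 1),
                class = "dipole_coefficients"))
    got <- farfield_forward(b)
    want <- oracle_farfield_forward(bvals)
    worst <- max(worst, Mod(got - want) / Mod(want))
  }
  expect_lt(worst, 1e-4)
})

test_that("farfield_forward obeys the Wigner selection rule and chains with
           a scalar T-matrix", {
  k <- 2 * pi / 400e-9
  tval <- 2e-8 - 5e-9i
  iso <- structure(list(entries = tval * diag(6), k = k, basis = "helicity"),
                   class = "tmatrix6")
  b <- apply_tmatrix(iso, expand_plane_wave(plane_wave(1, k)))
  es <- farfield_forward(b)
  expect_equal(unname(es["plus"]), sqrt(12 * pi) * sqrt(3 / (4 * pi)) * tval,
               tolerance = 1e-14)
  expect_identical(unname(es["minus"]), 0i)
  # zero coefficients give zero amplitudes
  b0 <- b; b0$values[] <- 0i
  expect_identical(unname(farfield_forward(b0)), c(0i, 0i))
})

test_that("transmissions implement the co-helical incoming placement", {
  # empty scatterer: T+ = T- = 1
  f0 <- forward_field_pair(matrix(0i, 2, 2))
  expect_equal(unname(transmissions(f0)), c(1, 1))
  # degenerate arithmetic check of the modulus-square sum
  f1 <- forward_field_pair(rbind(c(1 + 0i, 0), c(0, 0)),
                           incoming = c(1 + 0i, 0))
  tt <- transmissions(f1)
  expect_equal(unname(tt[["T_plus"]]), 4)
  expect_equal(unname(tt[["T_minus"]]), 0)
  # random pair against expanded real/imaginary arithmetic
  set.seed(13)
  for (i in 1:25) {
    sc <- matrix(stats::rnorm(4) + 1i * stats::rnorm(4), 2, 2)
    ei <- stats::rnorm(2) + 1i * stats::rnorm(2)
    tt <- transmissions(forward_field_pair(sc, incoming = ei))
    mod2 <- function(z) Re(z)^2 + Im(z)^2
    expect_equal(unname(tt[["T_plus"]]),
                 mod2(sc[1, 1] + ei[1]) + mod2(sc[1, 2]), tolerance = 1e-13)
    expect_equal(unname(tt[["T_minus"]]),
                 mod2(sc[2, 2] + ei[2]) + mod2(sc[2, 1]), tolerance = 1e-13)
  }
})

test_that("tcd arithmetic: symmetry, bounds, antisymmetry, degenerate error", {
  expect_identical(tcd(1.3, 1.3), 0)
  expect_equal(tcd(1, 2), 1 / 3, tolerance = 1e-15)
  expect_identical(tcd(0, 0.5), 1)
  expect_identical(tcd(0.5, 0), -1)
  set.seed(4)
  for (i in 1:50) {
    tp <- stats::runif(1, 0, 2); tm <- stats::runif(1, 0, 2)
    v <- tcd(tp, tm)
    expect_true(v >= -1 && v <= 1)
    expect_equal(tcd(tm, tp), -v, tolerance = 1e-15)
  }
  expect_error(tcd(0, 0), "undefined ratio")
})

test_that("a lossy scatterer dims the forward transmission below the empty
           value (extinction phase consistency)", {
  # isotropic absorptive electric dipole: alpha'' > 0 -> destructive forward
  # interference, T < 1 for both helicities; lossless -> change only at
  # second order in |T|
  lossy <- pol_single(ee = (1 + 4i) * 1e-39)
  th <- parity_to_helicity(build_tmatrix(lossy, grid_index = 1))
  tt <- transmissions(.pair_from_tmat(th))
  expect_lt(tt[["T_plus"]], 1)
  expect_lt(tt[["T_minus"]], 1)
  expect_equal(unname(tt[["T_plus"]]), unname(tt[["T_minus"]]),
               tolerance = 1e-15)
  lossless <- pol_single(ee = 1e-39)
  th2 <- parity_to_helicity(build_tmatrix(lossless, grid_index = 1))
  tt2 <- transmissions(.pair_from_tmat(th2))
  expect_lt(abs(tt2[["T_plus"]] - 1), 1e-13)
})

test_that("per-orientation TCD vanishes for achiral reciprocal scatterers", {
  # isotropic achiral: exactly zero for any orientation
  iso <- preset_polarizabilities("achiral-iso")
  th <- parity_to_helicity(build_tmatrix(iso, grid_index = 20))
  set.seed(17)
  for (i in 1:5) {
    v <- single_orientation_tcd(th, stats::runif(1, 0, pi),
                                stats::runif(1, 0, 2 * pi))
    expect_identical(v, 0)
  }
  # anisotropic achiral reciprocal, weak-scattering regime: zero to 1e-12
  # (residual is second order in the scattering strength)
  ach <- random_reciprocal_pol(81, n_energy = 1, chiral = FALSE)
  th2 <- parity_to_helicity(build_tmatrix(ach, grid_index = 1))
  for (i in 1:5) {
    v <- single_orientation_tcd(th2, stats::runif(1, 0, pi),
                                stats::runif(1, 0, 2 * pi))
    expect_lt(abs(v), 1e-12)
  }
})

test_that("absorption/ACD spectra: zero T, achiral symmetry, positivity and
           enantiomer sign flip", {
  # zero T-matrix -> all cross sections zero
  z <- pol_single()
  zs <- parity_to_helicity(build_tmatrix_stack(
    polarizability_set(c(3, 3.2), array(0i, c(3, 3, 2)), array(0i, c(3, 3, 2)),
                       array(0i, c(3, 3, 2)), array(0i, c(3, 3, 2)))))
  sp0 <- absorption_acd_spectra(zs)
  expect_true(all(sp0$abs_plus == 0 & sp0$abs_minus == 0 & sp0$acd == 0))
  # isotropic lossy electric dipole: ACD = 0, absorption > 0
  iso <- parity_to_helicity(build_tmatrix_stack(
    preset_polarizabilities("achiral-iso")))
  spi <- absorption_acd_spectra(iso)
  expect_lt(max(abs(spi$acd)), 1e-25 * max(spi$abs_plus))
  expect_true(all(spi$abs_plus > 0))
  # chiral preset: nonzero ACD, sign flips under mirroring, absorption >= 0
  pol <- preset_polarizabilities("chiral-single")
  sp <- absorption_acd_spectra(parity_to_helicity(build_tmatrix_stack(pol)))
  spm <- absorption_acd_spectra(parity_to_helicity(build_tmatrix_stack(
    mirror_enantiomer(pol))))
  expect_gt(max(abs(sp$acd)), 0)
  expect_equal(spm$acd, -sp$acd, tolerance = 1e-14)
  expect_true(all(sp$abs_plus >= 0 & sp$abs_minus >= 0))
  expect_error(absorption_acd_spectra(build_tmatrix_stack(pol)), "helicity")
})
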