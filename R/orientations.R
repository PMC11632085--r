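## Uniformly dispersed molecular orientations via Thomson-style repulsion
## minimized by projected gradient descent, and the rotational average of
## the TCD over those orientations.

#' Sample uniformly dispersed orientations on the sphere
#'
#' Draws `n` unit directions from a seeded random start and minimizes the
#' inverse-chord-distance repulsion energy
#' \eqn{E = \sum_{i<j} 1/\|x_i - x_j\|} (the Thomson problem) by projected
#' gradient descent with a backtracking step search. The converged points
#' are returned as orientation angles `(theta, Phi)` of the rotated
#' molecular z-axis, `theta` in `[0, pi)`, `Phi` in `[0, 2*pi)`. Fully
#' deterministic for fixed `(n, seed)`.
#'
#' @param n number of orientations (default 50).
#' @param seed integer RNG seed for the starting configuration.
#' @param max_iter maximum gradient-descent iterations.
#' @param tol convergence threshold on the tangential gradient norm
#'   (relative to `n^2`, the natural energy scale).
#' @return object of class `"orientation_set"`: a `data.frame` with columns
#'   `theta`, `Phi` and attributes `n`, `seed`, `energy` (final repulsion
#'   energy), `converged`, `points` (the n x 3 unit vectors).
#' @export
sample_orientations <- function(n = 50, seed = 1, max_iter = 2000, tol = 1e-10) {
  stopifnot(.is_number(n), n == round(n))
  if (n < 1) stop("sample_orientations: n must be >= 1")
  stopifnot(.is_number(seed), .is_number(max_iter), .is_number(tol))
  x <- .with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  x <- x / sqrt(rowSums(x^2))
  energy <- 0
  converged <- TRUE
  if (n > 1) {
    obj <- .thomson_energy_grad(x)
    energy <- obj$energy
    step <- 0.1 / n
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      g <- obj$grad
      ## project onto the tangent space of each point
      g <- g - x * rowSums(g * x)
      gn <- sqrt(sum(g^2))
      if (gn < tol * n^2) { converged <- TRUE; break }
      repeat {
        xn <- x - step * g
        xn <- xn / sqrt(rowSums(xn^2))
        cand <- .thomson_energy_grad(xn)
        if (cand$energy < obj$energy || step < 1e-14) break
        step <- step / 2
      }
      if (cand$energy >= obj$energy) { converged <- TRUE; break }  # stalled
      x <- xn; obj <- cand; energy <- cand$energy
      step <- step * 1.5
    }
  }
  theta <- acos(pmin(1, pmax(-1, x[, 3])))
  Phi <- atan2(x[, 2], x[, 1]) %% (2 * pi)
  out <- data.frame(theta = theta, Phi = Phi)
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "energy") <- energy
  attr(out, "converged") <- converged
  attr(out, "points") <- x
  class(out) <- c("orientation_set", "data.frame")
  out
}

.thomson_energy_grad <- function(x) {
  n <- nrow(x)
  energy <- 0
  grad <- matrix(0, n, 3)
  d2 <- as.matrix(stats::dist(x))
  diag(d2) <- Inf
  energy <- sum(1 / d2[upper.tri(d2)])
  inv3 <- 1 / d2^3
  for (j in 1:3) {
    diffs <- outer(x[, j], x[, j], "-")
    grad[, j] <- -rowSums(diffs * inv3)
  }
  list(energy = energy, grad = grad)
}

## run expr with a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Minimum pairwise angle of an orientation set
#'
#' @param orientations an `"orientation_set"`.
#' @return smallest angle (radians) between any two sampled directions.
#' @export
min_pairwise_angle <- function(orientations) {
  x <- attr(orientations, "points")
  stopifnot(is.matrix(x), nrow(x) >= 2)
  g <- x %*% t(x)
  diag(g) <- -Inf
  acos(pmin(1, pmax(-1, max(g[upper.tri(g)]))))
}

## locate molecule-frame wavenumbers on the stack grid.
## Returns index (exact match), or interpolated 6x6 entries.
.stack_lookup <- function(stack, k_prime, interpolate, rel_tol = 1e-9) {
  ks <- stack$k
  i <- which.min(abs(ks - k_prime))
  if (abs(ks[i] - k_prime) <= rel_tol * k_prime) {
    return(stack$tms[[i]])
  }
  if (!interpolate) {
    stop("T-matrix grid has no point at k' = ", format(k_prime),
         " rad/m (nearest: ", format(ks[i]), "); enable interpolate = TRUE ",
         "or request wavelengths mapped from the grid")
  }
  if (k_prime < min(ks) || k_prime > max(ks)) {
    stop("k' = ", format(k_prime), " rad/m outside the stack grid")
  }
  hi <- which(ks >= k_prime)[1]
  lo <- hi - 1L
  w <- (k_prime - ks[lo]) / (ks[hi] - ks[lo])
  tm <- stack$tms[[lo]]
  tm$entries <- (1 - w) * stack$tms[[lo]]$entries + w * stack$tms[[hi]]$entries
  tm$k <- k_prime
  tm$energy_eV <- .k_to_energy(k_prime, stack$medium$c_h)
  tm
}

#' Rotationally averaged TCD at one boost speed
#'
#' For each lab-frame wavelength: boost the incident -z plane wave into the
#' molecule frame (redshift `exp(-xi)`), evaluate the helicity T-matrix at
#' the boosted wavenumber, and for every sampled orientation apply the
#' rotated T-matrix, form the forward far-field amplitudes, inverse-boost
#' them to the lab frame, and compute the transmissions and the TCD; the
#' reported TCD is the arithmetic mean of the per-orientation TCD values
#' (equal weights). Orientation spacing is uniform in the molecule frame.
#'
#' Lab wavelengths whose boosted counterparts fall outside the stack's
#' spectral window are excluded and reported in the `"excluded"` attribute;
#' if none remain, an error lists the admissible lab-frame window
#' `[L_min, L_max] * exp(-xi)`.
#'
#' @param stack a helicity-basis `"tmatrix_stack"`.
#' @param orientations an `"orientation_set"` (or data.frame with `theta`,
#'   `Phi` columns).
#' @param boost a [boost_z()].
#' @param lab_wavelengths_nm lab-frame wavelengths (nm).
#' @param interpolate interpolate T-matrices linearly in k between grid
#'   points (default `FALSE`: only wavelengths mapping onto the grid are
#'   evaluated).
#' @return a `data.frame` of class `"tcd_grid"` with columns `beta`,
#'   `wavelength_nm_lab`, `tcd`, `t_plus`, `t_minus` (orientation-mean
#'   transmissions) and attributes `orientation_count`, `seed`, `excluded`.
#' @export
rotational_average_tcd <- function(stack, orientations, boost,
                                   lab_wavelengths_nm, interpolate = FALSE) {
  stopifnot(inherits(stack, "tmatrix_stack"), inherits(boost, "boost_z"),
            is.numeric(lab_wavelengths_nm), length(lab_wavelengths_nm) >= 1,
            all(is.finite(lab_wavelengths_nm)), all(lab_wavelengths_nm > 0))
  if (stack$basis != "helicity") {
    stop("rotational_average_tcd: stack must be in the helicity basis")
  }
  fac <- doppler_factor(boost, "forward")
  k_lab <- 2 * pi / (lab_wavelengths_nm * 1e-9)
  k_prime <- k_lab * fac
  span <- range(stack$k)
  tol <- 1e-9
  ok <- k_prime >= span[1] * (1 - tol) & k_prime <= span[2] * (1 + tol)
  excluded <- lab_wavelengths_nm[!ok]
  if (!any(ok)) {
    win <- sort(2 * pi / (span * 1e-9) / fac) * c(1, 1)
    stop("rotational_average_tcd: no admissible lab wavelengths for beta = ",
         format(boost$beta), "; admissible lab-frame window is [",
         format(min(win) * 1e9), ", ", format(max(win) * 1e9), "] nm")
  }
  R6s <- lapply(seq_len(nrow(orientations)), function(i)
    .rotation6(orientations$theta[i], orientations$Phi[i]))
  n_or <- length(R6s)
  idx_p <- .hel_index(1L, -1L); idx_m <- .hel_index(-1L, 1L)
  a_p <- rep(0i, 6); a_p[idx_p] <- .pw_coef
  a_m <- rep(0i, 6); a_m[idx_m] <- .pw_coef
  res <- lapply(which(ok), function(j) {
    tm <- .stack_lookup(stack, k_prime[j], interpolate)
    tcds <- numeric(n_or); tps <- numeric(n_or); tms_ <- numeric(n_or)
    for (i in seq_len(n_or)) {
      R6 <- R6s[[i]]
      TR <- R6 %*% tm$entries %*% Conj(t(R6))
      bp <- TR %*% a_p
      bm <- TR %*% a_m
      pair <- forward_field_pair(
        rbind(c(.ff_norm * bp[idx_p], .ff_norm * bp[idx_m]),
              c(.ff_norm * bm[idx_p], .ff_norm * bm[idx_m])),
        k = tm$k)
      pair <- inverse_boost_scattered(pair, tm$k, boost)$amplitudes
      tt <- transmissions(pair)
      tps[i] <- tt[["T_plus"]]; tms_[i] <- tt[["T_minus"]]
      tcds[i] <- tcd(tt[["T_plus"]], tt[["T_minus"]])
    }
    c(tcd = mean(tcds), t_plus = mean(tps), t_minus = mean(tms_))
  })
  res <- do.call(rbind, res)
  out <- data.frame(beta = boost$beta,
                    wavelength_nm_lab = lab_wavelengths_nm[ok],
                    tcd = res[, "tcd"],
                    t_plus = res[, "t_plus"],
                    t_minus = res[, "t_minus"])
  attr(out, "orientation_count") <- n_or
  attr(out, "seed") <- attr(orientations, "seed")
  attr(out, "excluded") <- excluded
  class(out) <- c("tcd_grid", "data.frame")
  out
}

#' Lab wavelengths mapped from the molecule-frame grid
#'
#' The lab-frame wavelengths that Doppler-map exactly onto the stack's
#' energy grid at speed `beta`: `L_lab = L_grid * exp(-xi)` (features shift
#' to shorter wavelengths as the molecule approaches the observer).
#'
#' @param stack a `"tmatrix_stack"`.
#' @param boost a [boost_z()].
#' @return numeric vector of lab wavelengths (nm), decreasing in energy.
#' @export
grid_lab_wavelengths <- function(stack, boost) {
  stopifnot(inherits(stack, "tmatrix_stack"), inherits(boost, "boost_z"))
  2 * pi / (stack$k * doppler_factor(boost, "inverse")) * 1e9
}

#' TCD sweep over boost speeds
#'
#' Runs [rotational_average_tcd()] for each requested speed. When
#' `lab_wavelengths_nm` is `NULL` (the default), each speed uses the lab
#' wavelengths that map exactly onto the molecule-frame grid
#' ([grid_lab_wavelengths()]), so the admissible window shrinks towards
#' shorter wavelengths as `beta` grows.
#'
#' @param stack helicity-basis `"tmatrix_stack"`.
#' @param betas numeric vector of speeds in `[0, 1)`.
#' @param orientations an `"orientation_set"`.
#' @param lab_wavelengths_nm optional fixed lab wavelength grid (nm).
#' @param interpolate passed to [rotational_average_tcd()].
#' @param verbose emit one progress message per speed.
#' @return `"tcd_grid"` data.frame over all speeds.
#' @export
tcd_beta_sweep <- function(stack, betas, orientations,
                           lab_wavelengths_nm = NULL, interpolate = FALSE,
                           verbose = FALSE) {
  stopifnot(is.numeric(betas), all(betas >= 0 & betas < 1))
  rows <- list()
  for (b in betas) {
    boost <- boost_z(b)
    L <- if (is.null(lab_wavelengths_nm)) grid_lab_wavelengths(stack, boost)
         else lab_wavelengths_nm
    g <- tryCatch(
      rotational_average_tcd(stack, orientations, boost, L, interpolate),
      error = function(e) {
        warning("beta = ", format(b), " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (verbose && !is.null(g)) {
      message(sprintf("beta=%.4g: %d wavelengths, max|TCD|=%.3g",
                      b, nrow(g), max(abs(g$tcd))))
    }
    rows[[length(rows) + 1L]] <- g
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("tcd_beta_sweep: no admissible speeds")
  out <- do.call(rbind, rows)
  attr(out, "orientation_count") <- attr(rows[[1]], "orientation_count")
  attr(out, "seed") <- attr(rows[[1]], "seed")
  class(out) <- c("tcd_grid", "data.frame")
  rownames(out) <- NULL
  out
}
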