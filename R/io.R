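## Plain-text serialization: polarizability CSV dialect, T-matrix JSON
## store, orientation-set CSV, TCD/spectra CSV exports. All numeric output
## uses %.17g so complex values round-trip exactly.

.tensor_tags <- c("ee", "em", "me", "mm")
.comp_tags <- as.vector(t(outer(c("x", "y", "z"), c("x", "y", "z"), paste0)))

.pol_header <- function() {
  cols <- "energy_eV"
  for (tt in .tensor_tags) {
    for (cc in .comp_tags) {
      cols <- c(cols, paste0(tt, "_", cc, "_re"), paste0(tt, "_", cc, "_im"))
    }
  }
  cols  # 1 + 4*9*2 = 73 columns
}

.fmt <- function(x) sprintf("%.17g", x)

#' Read a polarizability table
#'
#' Parses the package's polarizability CSV dialect: comment lines start with
#' `#`, a `# units: au|si` line declares the unit system, the header row
#' names 73 columns (`energy_eV`, then for each tensor ee, em, me, mm the
#' nine Cartesian components in row-major order, each split into `_re` and
#' `_im`). Parse and validation errors name the offending line.
#'
#' @param path file path.
#' @param units override the unit system declared in the file (`"au"` or
#'   `"si"`); by default the `# units:` header is used.
#' @return a [polarizability_set()] (internal reduced-SI units).
#' @export
read_polarizabilities <- function(path, units = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_polarizabilities: empty file '", path, "'")
  is_comment <- grepl("^\\s*#", lines)
  unit_lines <- grep("^\\s*#\\s*units:", lines)
  file_units <- NULL
  if (length(unit_lines)) {
    file_units <- trimws(sub("^\\s*#\\s*units:", "", lines[unit_lines[1]]))
  }
  units <- units %||% file_units
  if (is.null(units)) {
    stop("read_polarizabilities: no '# units:' header in '", path,
         "' and no units= override given")
  }
  if (!units %in% c("au", "si")) {
    stop("read_polarizabilities: unknown unit system '", units,
         "' (expected 'au' or 'si')")
  }
  keep <- which(!is_comment & nzchar(trimws(lines)))
  if (length(keep) < 2) {
    stop("read_polarizabilities: no data rows in '", path, "'")
  }
  header <- strsplit(lines[keep[1]], ",", fixed = TRUE)[[1]]
  expected <- .pol_header()
  if (length(header) != length(expected) || !all(trimws(header) == expected)) {
    stop("read_polarizabilities: malformed header at line ", keep[1],
         " (expected the 73-column dialect starting 'energy_eV,ee_xx_re,...')")
  }
  rows <- keep[-1]
  vals <- matrix(NA_real_, length(rows), length(expected))
  for (r in seq_along(rows)) {
    parts <- strsplit(lines[rows[r]], ",", fixed = TRUE)[[1]]
    if (length(parts) != length(expected)) {
      stop("read_polarizabilities: line ", rows[r], " has ", length(parts),
           " fields, expected ", length(expected))
    }
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) {
      stop("read_polarizabilities: non-numeric value at line ", rows[r],
           ", field ", which(is.na(v))[1])
    }
    vals[r, ] <- v
  }
  energies <- vals[, 1]
  if (anyDuplicated(energies)) {
    dup <- which(duplicated(energies))[1]
    stop("read_polarizabilities: duplicate energy at line ", rows[dup])
  }
  if (length(energies) > 1 && any(diff(energies) <= 0)) {
    bad <- which(diff(energies) <= 0)[1] + 1L
    stop("read_polarizabilities: energy column not strictly increasing at ",
         "line ", rows[bad])
  }
  n <- length(energies)
  tens <- list()
  col <- 2L
  for (tt in .tensor_tags) {
    a <- array(0i, c(3, 3, n))
    for (i in 1:3) for (j in 1:3) {
      a[i, j, ] <- vals[, col] + 1i * vals[, col + 1L]
      col <- col + 2L
    }
    tens[[tt]] <- a
  }
  polarizability_set(energies, tens$ee, tens$em, tens$me, tens$mm,
                     units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a polarizability table
#'
#' Inverse of [read_polarizabilities()]: converts the internal reduced-SI
#' tensors to the requested unit system and writes the 73-column CSV dialect
#' with a `# units:` header.
#'
#' @param pol a [polarizability_set()].
#' @param path output file.
#' @param units `"au"` or `"si"`.
#' @return `path`, invisibly.
#' @export
write_polarizabilities <- function(pol, path, units = c("au", "si")) {
  stopifnot(inherits(pol, "polarizability_set"))
  units <- match.arg(units)
  cv <- if (units == "si") {
    c(ee = 1, em = .const$Z0, me = .const$c0, mm = .const$c0 * .const$Z0)
  } else {
    c(ee = 1 / .au_to_si$ee,
      em = .const$Z0 / .au_to_si$em,
      me = .const$c0 / .au_to_si$me,
      mm = .const$c0 * .const$Z0 / .au_to_si$mm)
  }
  tens <- list(ee = pol$alpha_ee * cv[["ee"]], em = pol$alpha_em * cv[["em"]],
               me = pol$alpha_me * cv[["me"]], mm = pol$alpha_mm * cv[["mm"]])
  n <- length(pol$energies_eV)
  out <- character(n)
  for (r in seq_len(n)) {
    fields <- .fmt(pol$energies_eV[r])
    for (tt in .tensor_tags) {
      a <- tens[[tt]][, , r]
      for (i in 1:3) for (j in 1:3) {
        fields <- c(fields, .fmt(Re(a[i, j])), .fmt(Im(a[i, j])))
      }
    }
    out[r] <- paste(fields, collapse = ",")
  }
  writeLines(c(paste0("# units: ", units),
               paste(.pol_header(), collapse = ","),
               out), path)
  invisible(path)
}

#' Write a T-matrix stack to a JSON store
#'
#' Layout: `{metadata: {basis, index_order, medium, energy_unit}, records:
#' [{energy_eV, k, entries}]}` where `entries` is a 6x6 array of `[re, im]`
#' pairs. Full double precision; a write/read round trip is bit-exact.
#'
#' @param stack a `"tmatrix_stack"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tmatrix <- function(stack, path) {
  stopifnot(inherits(stack, "tmatrix_stack"))
  recs <- lapply(stack$tms, function(tm) {
    ent <- lapply(1:6, function(i) lapply(1:6, function(j)
      c(Re(tm$entries[i, j]), Im(tm$entries[i, j]))))
    list(energy_eV = tm$energy_eV, k = tm$k, entries = ent)
  })
  doc <- list(metadata = list(basis = stack$basis,
                              index_order = stack$tms[[1]]$index_order,
                              medium = list(eps_h = stack$medium$eps_h,
                                            mu_h = stack$medium$mu_h),
                              energy_unit = "eV"),
              records = recs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a T-matrix stack from a JSON store
#'
#' @param path file written by [write_tmatrix()].
#' @return a `"tmatrix_stack"`.
#' @export
read_tmatrix <- function(path) {
  doc <- jsonlite::read_json(path)
  md <- doc$metadata
  if (is.null(md$basis) || !md$basis %in% c("parity", "helicity")) {
    stop("read_tmatrix: missing or invalid basis in '", path, "'")
  }
  medium <- medium_params(md$medium$eps_h, md$medium$mu_h)
  tms <- lapply(doc$records, function(r) {
    ent <- matrix(0i, 6, 6)
    for (i in 1:6) for (j in 1:6) {
      p <- r$entries[[i]][[j]]
      ent[i, j] <- p[[1]] + 1i * p[[2]]
    }
    .new_tmatrix6(ent, r$k, r$energy_eV, md$basis, medium)
  })
  energies <- vapply(tms, function(tm) tm$energy_eV, numeric(1))
  if (length(energies) > 1 && any(diff(energies) <= 0)) {
    stop("read_tmatrix: records not in strictly increasing energy order")
  }
  structure(list(energies_eV = energies,
                 k = vapply(tms, function(tm) tm$k, numeric(1)),
                 tms = tms, basis = md$basis, medium = medium),
            class = "tmatrix_stack")
}

#' Write / read an orientation set as two-column CSV
#'
#' Columns `theta_rad`, `Phi_rad`, with `#` metadata (n, seed, final
#' repulsion energy) for reproducibility.
#'
#' @param orientations an `"orientation_set"`.
#' @param path file path.
#' @return `path` (write) or an `"orientation_set"` (read).
#' @export
write_orientations <- function(orientations, path) {
  stopifnot(inherits(orientations, "orientation_set"))
  hdr <- c(paste0("# n: ", attr(orientations, "n")),
           paste0("# seed: ", attr(orientations, "seed")),
           paste0("# energy: ", .fmt(attr(orientations, "energy"))),
           "theta_rad,Phi_rad")
  body <- paste(.fmt(orientations$theta), .fmt(orientations$Phi), sep = ",")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_orientations
#' @export
read_orientations <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (length(ln)) as.numeric(trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1])))
    else NA_real_
  }
  keep <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(keep) < 2 || trimws(keep[1]) != "theta_rad,Phi_rad") {
    stop("read_orientations: '", path, "' is not an orientation CSV")
  }
  vals <- do.call(rbind, lapply(keep[-1], function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])))
  if (anyNA(vals) || ncol(vals) != 2) {
    stop("read_orientations: malformed data row in '", path, "'")
  }
  out <- data.frame(theta = vals[, 1], Phi = vals[, 2])
  x <- cbind(sin(out$theta) * cos(out$Phi), sin(out$theta) * sin(out$Phi),
             cos(out$theta))
  attr(out, "n") <- nrow(out)
  attr(out, "seed") <- grab("seed")
  attr(out, "energy") <- grab("energy")
  attr(out, "converged") <- NA
  attr(out, "points") <- x
  class(out) <- c("orientation_set", "data.frame")
  out
}

## FNV-1a over a string; short provenance hash for output headers
.config_hash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ";"),
                    character(1)), collapse = "|")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    ## h * 16777619 mod 2^32, split to stay within exact double arithmetic
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a TCD grid as CSV
#'
#' Columns `beta`, `wavelength_nm_lab`, `tcd`; `#` metadata header carries
#' the package version, seed, orientation count, far-field normalization
#' constant and a config hash, so identical configurations reproduce
#' identical bytes.
#'
#' @param grid a `"tcd_grid"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tcd_grid <- function(grid, path) {
  stopifnot(inherits(grid, "tcd_grid"))
  n_or <- attr(grid, "orientation_count")
  seed <- attr(grid, "seed")
  hdr <- c(paste0("# chiroboost_version: ",
                  as.character(utils::packageVersion("chiroboost"))),
           paste0("# seed: ", format(seed)),
           paste0("# orientation_count: ", format(n_or)),
           paste0("# farfield_norm: ", .fmt(.ff_norm)),
           paste0("# config_hash: ",
                  .config_hash(seed, n_or, unique(grid$beta),
                               range(grid$wavelength_nm_lab))),
           "beta,wavelength_nm_lab,tcd")
  body <- paste(.fmt(grid$beta), .fmt(grid$wavelength_nm_lab),
                .fmt(grid$tcd), sep = ",")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write absorption/ACD spectra as CSV
#'
#' Columns `energy_eV`, `abs_plus`, `abs_minus`, `acd` with a `#` metadata
#' header.
#'
#' @param spectra a `"spectrum_set"` from [absorption_acd_spectra()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectrum_set"))
  hdr <- c(paste0("# chiroboost_version: ",
                  as.character(utils::packageVersion("chiroboost"))),
           paste0("# config_hash: ",
                  .config_hash(range(spectra$energy_eV), nrow(spectra))),
           "energy_eV,abs_plus,abs_minus,acd")
  body <- paste(.fmt(spectra$energy_eV), .fmt(spectra$abs_plus),
                .fmt(spectra$abs_minus), .fmt(spectra$acd), sep = ",")
  writeLines(c(hdr, body), path)
  invisible(path)
}
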