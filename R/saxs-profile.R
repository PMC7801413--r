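# 1D SAXS profile container and the ATSAS-style .dat text format.

#' Construct a 1D SAXS profile
#'
#' @param q Momentum transfer grid, 1/A, strictly increasing and positive
#'   (`q = 4 pi sin(theta) / lambda`; real-space spacing `d = 2 pi / q`).
#' @param intensity Scattered intensity, arbitrary units.
#' @param sigma Optional point-wise uncertainty (same units as intensity,
#'   strictly positive). `NULL` for noiseless model curves.
#' @return An object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stopf("`q` and `intensity` must have the same length")
  if (any(!is.finite(q)) || any(q <= 0)) stopf("`q` must be positive and finite")
  if (any(diff(q) <= 0)) stopf("`q` must be strictly increasing")
  if (any(!is.finite(intensity))) stopf("`intensity` must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stopf("`sigma` must match `q` in length")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stopf("`sigma` must be strictly positive where present")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %d points, q in [%.4g, %.4g] 1/A%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) " (noiseless)" else ""))
  invisible(x)
}

#' Default q grid for model scattering curves
#'
#' 301 linearly spaced points on 0.005-0.30 1/A.
#'
#' @return Numeric vector of q values, 1/A.
#' @export
default_q_grid <- function() seq(0.005, 0.30, length.out = 301)

#' Read a 3-column SAXS profile from text
#'
#' Whitespace-separated columns `q I [sigma]`; lines starting with `#` are
#' comments. Two-column files load with absent sigma; a sigma column of all
#' zeros is treated as absent.
#'
#' @param path File path.
#' @return A [saxs_profile()].
#' @export
read_dat <- function(path) {
  lines <- readLines(path)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  rows <- which(keep)
  if (!length(rows)) stopf("no data rows in '%s'", path)
  parts <- strsplit(trimmed[rows], "[ \t]+")
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1 || !(ncol %in% c(2, 3)))
    stopf("'%s': expected a consistent 2- or 3-column layout", path)
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad))
    stopf("'%s': non-numeric value on line %d", path, rows[bad[1]])
  m <- do.call(rbind, vals)
  q <- m[, 1]
  nonasc <- which(diff(q) <= 0)
  if (length(nonasc))
    stopf("'%s': q not strictly ascending at line %d", path, rows[nonasc[1] + 1])
  sigma <- if (ncol == 3 && any(m[, 3] != 0)) m[, 3] else NULL
  saxs_profile(q, m[, 2], sigma)
}

#' Write a SAXS profile as 3-column text
#'
#' @param profile A [saxs_profile()].
#' @param path Output path.
#' @param comment Optional extra header comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_dat <- function(profile, path, comment = NULL) {
  if (!inherits(profile, "saxs_profile")) stopf("`profile` must be a saxs_profile")
  hdr <- c("# chromosaxs SAXS profile (q [1/A], I, sigma); d = 2*pi/q",
           if (!is.null(comment)) paste0("# ", comment))
  cols <- if (is.null(profile$sigma)) {
    sprintf("%.12e %.12e", profile$q, profile$intensity)
  } else {
    sprintf("%.12e %.12e %.12e", profile$q, profile$intensity, profile$sigma)
  }
  writeLines(c(hdr, cols), path)
  invisible(path)
}
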