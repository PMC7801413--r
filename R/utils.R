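# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_number(x) && x >= 0 && x == round(x)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is_number(x) || x < min || x > max)
    stopf("`%s` must be a single finite number in [%g, %g]", name, min, max)
  x
}

# sin(x)/x with the removable singularity handled by series expansion;
# preserves the shape of matrix input
sinc <- function(x) {
  out <- x
  small <- abs(x) < 1e-6
  out[small] <- 1 - x[small]^2 / 6
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is_count(seed)) stopf("`seed` must be a single non-negative integer")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Orientation-averaged form factor of a uniform sphere of radius `a`:
# f(q) = 3 [sin(qa) - qa cos(qa)] / (qa)^3, with f(0) = 1.
sphere_form_factor <- function(q, a) {
  if (a <= 0) return(rep(1, length(q)))
  x <- q * a
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  out[small] <- 1 - x[small]^2 / 10 + x[small]^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

# Volume of the intersection of two spheres (radii a, b; centre separation w).
sphere_overlap_volume <- function(a, b, w) {
  lo <- abs(a - b); hi <- a + b
  v <- numeric(length(w))
  inner <- w <= lo
  v[inner] <- 4 / 3 * pi * min(a, b)^3
  lens <- w > lo & w < hi
  wl <- w[lens]
  v[lens] <- pi * (hi - wl)^2 * (wl^2 + 2 * wl * hi - 3 * (a - b)^2) / (12 * wl)
  v
}

# Radial density of |u - v| for u, v uniform in spheres of radii a and b
# (a == b gives the pair-distance density within a single uniform sphere).
# Support [0, a + b]; integrates to 1.
fw_density <- function(w, a, b) {
  amax <- a + b
  if (amax <= 0) stopf("fw_density() needs at least one positive radius")
  if (min(a, b) <= 1e-12) {
    r <- max(a, b)
    return(ifelse(w >= 0 & w <= r, 3 * w^2 / r^3, 0))
  }
  va <- 4 / 3 * pi * a^3
  vb <- 4 / 3 * pi * b^3
  ifelse(w >= 0 & w <= amax,
         4 * pi * w^2 * sphere_overlap_volume(a, b, w) / (va * vb), 0)
}

# Cubic-lattice points (spacing `spacing`) inside a sphere of radius `radius`
# centred at `centre`; the lattice is symmetric about the centre.
lattice_sphere <- function(radius, spacing, centre = c(0, 0, 0)) {
  n <- floor(radius / spacing)
  s <- seq(-n, n) * spacing
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  sweep(g, 2, centre, `+`)
}

# Cubic-lattice points inside a cylinder (axis = z) of radius and height.
lattice_cylinder <- function(radius, height, spacing) {
  nr <- floor(radius / spacing)
  nz <- floor((height / 2) / spacing)
  sxy <- seq(-nr, nr) * spacing
  sz <- seq(-nz, nz) * spacing
  g <- as.matrix(expand.grid(x = sxy, y = sxy, z = sz))
  g[g[, 1]^2 + g[, 2]^2 <= radius^2, , drop = FALSE]
}
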