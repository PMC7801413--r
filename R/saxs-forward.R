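# Forward SAXS: Debye intensity, model pair-distance distribution, and the
# DNA-unwrapping dip metric at q ~ 0.14 1/A.

# Group the bead pairs of a model by (radius, radius) class so each group
# shares a single product of sphere form factors. Returns pair groups
# (centre distances + pair weights, double-counting unordered pairs) and
# per-class self terms sum(w_i^2).
pair_groups <- function(model) {
  key <- signif(model$radii, 8)
  cls <- split(seq_len(nrow(model$positions)), key)
  radii <- as.numeric(names(cls))
  groups <- list()
  for (i in seq_along(cls)) {
    pi_ <- model$positions[cls[[i]], , drop = FALSE]
    wi <- model$weights[cls[[i]]]
    if (length(cls[[i]]) > 1) {
      d <- as.vector(dist(pi_))
      pw <- 2 * as.vector(as.dist(outer(wi, wi)))
      groups[[length(groups) + 1]] <- list(d = d, pw = pw,
                                           a1 = radii[i], a2 = radii[i])
    }
    if (i < length(cls)) for (j in (i + 1):length(cls)) {
      pj <- model$positions[cls[[j]], , drop = FALSE]
      wj <- model$weights[cls[[j]]]
      d2 <- outer(rowSums(pi_^2), rep(1, nrow(pj))) +
        outer(rep(1, nrow(pi_)), rowSums(pj^2)) - 2 * pi_ %*% t(pj)
      groups[[length(groups) + 1]] <- list(d = sqrt(pmax(as.vector(d2), 0)),
                                           pw = 2 * as.vector(outer(wi, wj)),
                                           a1 = radii[i], a2 = radii[j])
    }
  }
  selfs <- data.frame(radius = radii,
                      sw2 = vapply(cls, function(ii) sum(model$weights[ii]^2),
                                   numeric(1)))
  list(groups = groups, selfs = selfs)
}

# weighted distance histogram: per-bin mass and mass-weighted mean distance
bin_pairs <- function(d, pw, bin_width) {
  bins <- pmax(1L, as.integer(ceiling(d / bin_width)))
  rs <- rowsum(cbind(pw, pw * d), bins)
  list(mass = rs[, 1], dbar = rs[, 2] / rs[, 1],
       bin = as.integer(rownames(rs)))
}

#' Debye scattering intensity of a bead model
#'
#' Orientation-averaged intensity
#' `I(q) = sum_ij w_i w_j f_i(q) f_j(q) sin(q r_ij)/(q r_ij)` with `f` the
#' uniform-sphere form factor of each bead. The `"exact"` method evaluates
#' the full double sum; `"histogram"` bins centre distances (default bin
#' 0.5 A, using the mass-weighted mean distance of each bin) and agrees
#' with the exact sum to well within 0.2% for q <= 0.3 1/A.
#'
#' No hydration layer and no structure factor are included: the curve is a
#' dilute-solution form factor.
#'
#' @param model A [bead_model()].
#' @param q Momentum transfer grid, 1/A.
#' @param method `"exact"` or `"histogram"`.
#' @param bin_width Histogram bin width, A.
#' @return A noiseless [saxs_profile()]; `I(0)` extrapolates to
#'   `(sum w_i)^2`.
#' @export
debye_intensity <- function(model, q = default_q_grid(),
                            method = c("exact", "histogram"),
                            bin_width = 0.5) {
  method <- match.arg(method)
  if (!inherits(model, "bead_model")) stopf("`model` must be a bead_model")
  q <- as.numeric(q)
  if (any(q <= 0)) stopf("`q` must be positive")
  pg <- pair_groups(model)
  intensity <- numeric(length(q))
  for (g in pg$groups) {
    fa <- sphere_form_factor(q, g$a1) * sphere_form_factor(q, g$a2)
    s <- if (method == "exact") {
      vapply(q, function(qi) sum(g$pw * sinc(qi * g$d)), numeric(1))
    } else {
      h <- bin_pairs(g$d, g$pw, bin_width)
      as.vector(crossprod(sinc(outer(h$dbar, q)), h$mass))
    }
    intensity <- intensity + fa * s
  }
  for (k in seq_len(nrow(pg$selfs))) {
    intensity <- intensity +
      sphere_form_factor(q, pg$selfs$radius[k])^2 * pg$selfs$sw2[k]
  }
  saxs_profile(q, intensity)
}

# Spread binned pair mass over r bins using the exact conditional distance
# density of two uniform spheres (radii a1, a2) whose centres are `d` apart:
# r^2 = d^2 + w^2 + 2 d w cos(theta) with w the sphere-pair offset drawn
# from fw_density().
smear_mass <- function(dbar, mass, a1, a2, edges, nw = 32) {
  nb <- length(edges) - 1
  out <- numeric(nb)
  bw <- edges[2] - edges[1]
  amax <- a1 + a2
  if (amax <= 1e-12) {
    k <- pmin(nb, pmax(1L, as.integer(ceiling(dbar / bw))))
    for (i in seq_along(k)) out[k[i]] <- out[k[i]] + mass[i]
    return(out)
  }
  wj <- (seq_len(nw) - 0.5) * amax / nw
  fj <- fw_density(wj, a1, a2)
  fj <- fj / sum(fj)
  for (i in seq_along(dbar)) {
    d <- dbar[i]
    lo <- max(0, d - amax); hi <- d + amax
    k1 <- max(1L, as.integer(floor(lo / bw)) + 1L)
    k2 <- min(nb, as.integer(ceiling(hi / bw)))
    e <- edges[k1:(k2 + 1L)]
    B <- matrix((d - wj)^2, length(e), nw, byrow = TRUE)
    den <- matrix(4 * d * wj, length(e), nw, byrow = TRUE)
    F <- pmin(pmax((e^2 - B) / den, 0), 1)
    out[k1:k2] <- out[k1:k2] + mass[i] * as.vector(diff(F) %*% fj)
  }
  out
}

#' Pair-distance distribution of a bead model
#'
#' Weighted histogram of intra-particle distances, with each bead pair
#' smeared by the exact distance density of two uniform spheres, plus the
#' intra-bead self term of every finite-radius bead. The integral of P(r)
#' equals `(sum w_i)^2` up to the flat self term of zero-radius beads,
#' which contributes no pair distances and is kept only in the
#' normalisation used for Rg.
#'
#' @param model A [bead_model()] with at least two beads.
#' @param bin_width Histogram bin width, A.
#' @return An object of class `pair_distance_distribution` with fields
#'   `r` (bin centres, A), `p` (density, >= 0), `rg` and `dmax`.
#' @export
pair_distance_distribution <- function(model, bin_width = 0.5) {
  if (!inherits(model, "bead_model")) stopf("`model` must be a bead_model")
  if (nrow(model$positions) < 2) stopf("P(r) needs at least two beads")
  check_number(bin_width, "bin_width", min = 1e-6)
  dmax_hard <- dmax_of_model(model)
  nb <- as.integer(ceiling(dmax_hard / bin_width)) + 2L
  edges <- seq(0, by = bin_width, length.out = nb + 1L)
  m <- numeric(nb)
  pg <- pair_groups(model)
  for (g in pg$groups) {
    h <- bin_pairs(g$d, g$pw, bin_width)
    m <- m + smear_mass(h$dbar, h$mass, g$a1, g$a2, edges)
  }
  self_mass0 <- 0
  for (k in seq_len(nrow(pg$selfs))) {
    a <- pg$selfs$radius[k]; sw2 <- pg$selfs$sw2[k]
    if (a <= 1e-12) {
      self_mass0 <- self_mass0 + sw2
    } else {
      mids <- edges[-1] - bin_width / 2
      f <- fw_density(mids, a, a)
      if (sum(f) > 0) m <- m + sw2 * f / sum(f)
    }
  }
  centres <- edges[-1] - bin_width / 2
  total <- sum(m) + self_mass0
  rg <- sqrt(sum(m * centres^2) / (2 * total))
  occupied <- which(m > max(m) * 1e-9)
  dmax <- edges[max(occupied) + 1L]
  structure(list(r = centres, p = m / bin_width, rg = rg, dmax = dmax,
                 bin_width = bin_width, self_mass0 = self_mass0),
            class = "pair_distance_distribution")
}

#' @export
print.pair_distance_distribution <- function(x, ...) {
  cat(sprintf("<pair_distance_distribution> %d bins, Rg = %.2f A, Dmax = %.2f A\n",
              length(x$r), x$rg, x$dmax))
  invisible(x)
}

#' Forward sine transform of a pair-distance distribution
#'
#' `I(q) = int P(r) sin(qr)/(qr) dr` (plus any zero-distance self mass),
#' the inverse of the relation between the Debye intensity and P(r).
#'
#' @param pd A `pair_distance_distribution`.
#' @param q Momentum transfer grid, 1/A.
#' @return A noiseless [saxs_profile()].
#' @export
pofr_intensity <- function(pd, q) {
  if (!inherits(pd, "pair_distance_distribution"))
    stopf("`pd` must be a pair_distance_distribution")
  m <- pd$p * pd$bin_width
  intensity <- as.vector(crossprod(sinc(outer(pd$r, q)), m)) +
    (pd$self_mass0 %||% 0)
  saxs_profile(q, intensity)
}

#' Depth of the DNA-wrapping dip in a scattering profile
#'
#' The depression near q = 0.14 1/A in nucleosome form factors fills in as
#' DNA unwraps from the histone core, so its depth tracks the degree of
#' wrapping. Returns `log10` of the geometric mean of the two flanking
#' local maxima minus `log10` of the local minimum inside the window; 0
#' when the profile is monotonic there (no dip).
#'
#' @param profile A [saxs_profile()] covering the window.
#' @param q_center Window centre, 1/A.
#' @param half_window Half-width of the window, 1/A.
#' @return Dimensionless dip depth (decades), >= 0.
#' @export
dip_metric <- function(profile, q_center = 0.14, half_window = 0.03) {
  if (!inherits(profile, "saxs_profile")) stopf("`profile` must be a saxs_profile")
  lo <- q_center - half_window; hi <- q_center + half_window
  if (min(profile$q) > lo || max(profile$q) < hi)
    stopf("profile does not cover the dip window [%.3f, %.3f] 1/A", lo, hi)
  idx <- which(profile$q >= lo & profile$q <= hi)
  if (length(idx) < 5) stopf("too few points inside the dip window")
  y <- profile$intensity[idx]
  if (any(y <= 0)) stopf("non-positive intensities inside the dip window")
  im <- which.min(y)
  if (im == 1L || im == length(y)) return(0)
  max(0.5 * (log10(max(y[1:im])) + log10(max(y[im:length(y)]))) -
        log10(y[im]), 0)
}
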