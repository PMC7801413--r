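# Inverse SAXS: Guinier analysis, regularised indirect Fourier transform,
# model-to-data fitting and ranking of DNA-unwrapping hypotheses.

#' Guinier fit of the low-q region
#'
#' Weighted linear regression of `ln I` on `q^2` over the largest low-q
#' window satisfying `qmax * Rg <= qmax_rg_limit`, iterated to
#' self-consistency; `Rg = sqrt(-3 * slope)`.
#'
#' @param profile A [saxs_profile()].
#' @param qmax_rg_limit Upper limit on `qmax * Rg` (conventional 1.3).
#' @return An object of class `guinier_result` with fields `rg`, `i0`,
#'   `q_window`, `r_squared` and `n_points`.
#' @export
guinier_fit <- function(profile, qmax_rg_limit = 1.3) {
  if (!inherits(profile, "saxs_profile")) stopf("`profile` must be a saxs_profile")
  check_number(qmax_rg_limit, "qmax_rg_limit", min = 0.1)
  q <- profile$q; I <- profile$intensity

  fit_window <- function(n) {
    qi <- q[1:n]; Ii <- I[1:n]
    if (any(Ii <= 0)) stopf("non-positive intensities in the Guinier window")
    # weights on ln I: delta method gives (I/sigma)^2; without sigma assume
    # constant absolute uncertainty, i.e. weights proportional to I^2
    w <- if (is.null(profile$sigma)) Ii^2 else (Ii / profile$sigma[1:n])^2
    w <- w / max(w)
    fit <- stats::lm(log(Ii) ~ I(qi^2), weights = w)
    slope <- stats::coef(fit)[[2]]
    no_region <- slope >= 0 || -slope * qi[n]^2 < 1e-10
    list(slope = slope, fit = fit, w = w, no_region = no_region)
  }

  n <- min(length(q), 10L)
  rg <- NA_real_
  for (iter in 1:50) {
    res <- fit_window(n)
    if (res$no_region)
      stopf("no Guinier region: ln I is not decreasing in q^2 at low q")
    rg <- sqrt(-3 * res$slope)
    n_new <- max(5L, sum(q * rg <= qmax_rg_limit))
    if (n_new > length(q)) n_new <- length(q)
    if (n_new == n) break
    n <- n_new
  }
  if (n < 5) stopf("fewer than 5 points in the admissible Guinier window")
  res <- fit_window(n)
  if (res$no_region) stopf("no Guinier region after window iteration")
  rg <- sqrt(-3 * res$slope)
  y <- log(I[1:n])
  resid <- stats::residuals(res$fit)
  tss <- sum(res$w * (y - sum(res$w * y) / sum(res$w))^2)
  structure(list(rg = rg,
                 i0 = exp(stats::coef(res$fit)[[1]]),
                 q_window = c(q[1], q[n]),
                 r_squared = if (tss > 0) 1 - sum(res$w * resid^2) / tss else 1,
                 n_points = n),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("<guinier_result> Rg = %.2f A, I(0) = %.4g, window [%.4g, %.4g] (%d pts), R2 = %.4f\n",
              x$rg, x$i0, x$q_window[1], x$q_window[2], x$n_points, x$r_squared))
  invisible(x)
}

# second-difference (curvature) penalty matrix for n unknowns
second_diff_matrix <- function(n) {
  if (n < 3) stopf("need at least 3 grid points")
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

#' Regularised indirect Fourier transform for P(r)
#'
#' Recovers a non-negative pair-distance distribution on `[0, dmax]` from a
#' scattering profile by non-negative least squares under the sine-kernel
#' forward map `I(q) = sum_j P(r_j) sinc(q r_j) dr`, with a
#' second-difference smoothness penalty and both endpoints pinned to zero.
#' The regularisation weight is dimensionless (relative to the scale of
#' the normal equations); when `alpha = NULL` it is chosen by an L-curve
#' corner search over a log grid 1e-4..1e2.
#'
#' @param profile A [saxs_profile()] (uncertainties used as weights when
#'   present, unit weights otherwise).
#' @param dmax Assumed maximum particle dimension, A.
#' @param n_points Number of r-grid points on `[0, dmax]`.
#' @param alpha Regularisation weight, or `NULL` for automatic selection.
#' @return A `pair_distance_distribution` with extra fields
#'   `chi2_reduced`, `alpha` and `resolution_warning` (TRUE when `dmax`
#'   exceeds the scale `2*pi/qmin` resolvable from the data).
#' @export
ift_pofr <- function(profile, dmax, n_points = 101, alpha = NULL) {
  if (!inherits(profile, "saxs_profile")) stopf("`profile` must be a saxs_profile")
  check_number(dmax, "dmax", min = 1e-6)
  if (!is_count(n_points) || n_points < 10) stopf("`n_points` must be >= 10")
  resolution_warning <- dmax > 2 * pi / min(profile$q)
  if (resolution_warning)
    warnf("dmax = %.1f A exceeds the 2*pi/qmin = %.1f A scale resolvable from the data",
          dmax, 2 * pi / min(profile$q))

  r <- seq(0, dmax, length.out = n_points)
  dr <- r[2] - r[1]
  sig <- profile$sigma %||% rep(1, length(profile$q))
  A <- sinc(outer(profile$q, r)) * dr
  Aw <- A / sig
  yw <- profile$intensity / sig
  # pin endpoints to zero by dropping them from the unknowns
  interior <- 2:(n_points - 1)
  Ai <- Aw[, interior, drop = FALSE]
  D <- second_diff_matrix(n_points)[, interior, drop = FALSE]
  scale_ratio <- sum(Ai^2) / sum(D^2)

  solve_alpha <- function(a) {
    M <- rbind(Ai, sqrt(a * scale_ratio) * D)
    rhs <- c(yw, numeric(nrow(D)))
    sol <- pracma::lsqnonneg(M, rhs)
    x <- sol$x
    resid <- yw - Ai %*% x
    chi2 <- sum(resid^2)
    pen <- sum((D %*% x)^2)
    list(x = x, chi2 = chi2, pen = pen)
  }

  if (is.null(alpha)) {
    alphas <- 10^seq(-4, 2, by = 0.5)
    sols <- lapply(alphas, solve_alpha)
    rho <- log10(vapply(sols, `[[`, numeric(1), "chi2") + 1e-300)
    eta <- log10(vapply(sols, `[[`, numeric(1), "pen") + 1e-300)
    # discrete curvature of the L-curve; fall back to the median alpha
    k <- length(alphas)
    curv <- rep(NA_real_, k)
    for (i in 2:(k - 1)) {
      d1 <- c(rho[i + 1] - rho[i - 1], eta[i + 1] - eta[i - 1]) / 2
      d2 <- c(rho[i + 1] - 2 * rho[i] + rho[i - 1],
              eta[i + 1] - 2 * eta[i] + eta[i - 1])
      denom <- (d1[1]^2 + d1[2]^2)^1.5
      if (denom > 0) curv[i] <- (d1[1] * d2[2] - d1[2] * d2[1]) / denom
    }
    best <- if (all(is.na(curv))) ceiling(k / 2) else which.max(curv)
    alpha <- alphas[best]
    sol <- sols[[best]]
  } else {
    check_number(alpha, "alpha", min = 0)
    sol <- solve_alpha(alpha)
  }

  p <- numeric(n_points)
  p[interior] <- sol$x
  m <- p * dr
  total <- sum(m)
  if (total <= 0) stopf("IFT produced an empty P(r); check dmax and the data")
  rg <- sqrt(sum(m * r^2) / (2 * total))
  occupied <- which(m > max(m) * 1e-9)
  dof <- max(length(profile$q) - length(interior) / 2, 1)
  structure(list(r = r, p = p, rg = rg, dmax = r[max(occupied)],
                 bin_width = dr, self_mass0 = 0,
                 chi2_reduced = sol$chi2 / dof,
                 alpha = alpha,
                 resolution_warning = resolution_warning),
            class = "pair_distance_distribution")
}

#' Fit scale and constant background of a model curve to data
#'
#' Interpolates the model curve onto the data grid (linear in `(q, log I)`,
#' extrapolation forbidden) and solves the closed-form weighted linear
#' least-squares problem `min sum[(I_data - c*I_model - b)^2 / sigma^2]`
#' over the fitting window.
#'
#' @param model_curve Noiseless model [saxs_profile()].
#' @param data Experimental [saxs_profile()].
#' @param q_window Fitting window `(qmin, qmax)`, 1/A; the conventional
#'   window 0.05-0.25 1/A avoids inter-particle interference at low q and
#'   noise at high q.
#' @param model_id Optional identifier carried into the result.
#' @return An object of class `fit_result` with fields `scale`,
#'   `background`, `chi2_reduced`, `q_window`, `n_points`, `model_id`.
#' @export
fit_scale_background <- function(model_curve, data, q_window = c(0.05, 0.25),
                                 model_id = NULL) {
  if (!inherits(model_curve, "saxs_profile") || !inherits(data, "saxs_profile"))
    stopf("`model_curve` and `data` must be saxs_profile objects")
  q_window <- as.numeric(q_window)
  if (length(q_window) != 2 || q_window[1] >= q_window[2])
    stopf("`q_window` must be an increasing (qmin, qmax) pair")
  idx <- which(data$q >= q_window[1] & data$q <= q_window[2])
  if (length(idx) < 3) stopf("fewer than 3 data points inside the fit window")
  qd <- data$q[idx]
  if (min(qd) < min(model_curve$q) || max(qd) > max(model_curve$q))
    stopf("model curve does not cover the fit window; extrapolation is forbidden")
  if (any(model_curve$intensity <= 0))
    stopf("model intensities must be positive for log interpolation")
  mI <- exp(stats::approx(model_curve$q, log(model_curve$intensity),
                          xout = qd)$y)
  y <- data$intensity[idx]
  sig <- if (is.null(data$sigma)) rep(1, length(idx)) else data$sigma[idx]
  w <- 1 / sig^2
  # closed-form 2x2 weighted normal equations for (c, b)
  Sw <- sum(w); Sm <- sum(w * mI); Sy <- sum(w * y)
  Smm <- sum(w * mI^2); Smy <- sum(w * mI * y)
  det <- Smm * Sw - Sm^2
  if (abs(det) < .Machine$double.eps * Smm * Sw)
    stopf("degenerate fit: model curve is constant over the window")
  cc <- (Smy * Sw - Sm * Sy) / det
  bb <- (Smm * Sy - Sm * Smy) / det
  resid <- (y - cc * mI - bb) / sig
  structure(list(scale = cc, background = bb,
                 chi2_reduced = sum(resid^2) / (length(idx) - 2),
                 q_window = q_window, n_points = length(idx),
                 model_id = model_id),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result>%s c = %.4g, b = %.4g, chi2_red = %.4g (%d pts, window [%.3g, %.3g])\n",
              if (is.null(x$model_id)) "" else paste0(" [", x$model_id, "]"),
              x$scale, x$background, x$chi2_reduced, x$n_points,
              x$q_window[1], x$q_window[2]))
  invisible(x)
}

#' Rank DNA-unwrapping hypotheses against a scattering profile
#'
#' Builds a nucleosome (or chromatosome) model for every unwrapping
#' candidate, computes its Debye curve, fits scale and background over the
#' fitting window, and returns the candidates sorted by reduced chi-square
#' (ascending), ties broken in favour of less total unwrapping (parsimony).
#'
#' @param data Experimental [saxs_profile()].
#' @param unwrap_grid List of [unwrap_spec()] objects (or 2-column matrix
#'   of `(n_left, n_right)` pairs).
#' @param builder List describing the particle: `total_bp`, `linker_left`,
#'   `linker_right`, optional `geom` ([geometry_params()]) and optional
#'   `h1` ([h1_placement()]) for a chromatosome.
#' @param q_window Fitting window, 1/A.
#' @param q_model q grid for model curves (must cover `q_window`).
#' @param method Debye evaluation method passed to [debye_intensity()].
#' @param model_curves Optional pre-computed list of model curves (same
#'   order as `unwrap_grid`), to amortise model building across repeated
#'   scans of the same grid.
#' @return A data frame of class `unwrap_scan` with columns `n_left`,
#'   `n_right`, `total_unwrapped`, `scale`, `background`, `chi2_reduced`,
#'   sorted ascending by `chi2_reduced`.
#' @export
unwrap_scan <- function(data, unwrap_grid, builder,
                        q_window = c(0.05, 0.25),
                        q_model = default_q_grid(),
                        method = "histogram",
                        model_curves = NULL) {
  if (is.matrix(unwrap_grid)) {
    unwrap_grid <- apply(unwrap_grid, 1, function(r) unwrap_spec(r[1], r[2]),
                         simplify = FALSE)
  }
  if (!length(unwrap_grid)) stopf("`unwrap_grid` must be non-empty")
  if (is.null(model_curves)) {
    model_curves <- lapply(unwrap_grid, function(u) {
      unwrap_model_curve(u, builder, q_model, method)
    })
  }
  rows <- lapply(seq_along(unwrap_grid), function(i) {
    u <- unwrap_grid[[i]]
    id <- sprintf("unwrap_%d_%d", u$n_left, u$n_right)
    fit <- fit_scale_background(model_curves[[i]], data, q_window, model_id = id)
    data.frame(n_left = u$n_left, n_right = u$n_right,
               total_unwrapped = u$n_left + u$n_right,
               scale = fit$scale, background = fit$background,
               chi2_reduced = fit$chi2_reduced)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chi2_reduced, out$total_unwrapped), ]
  rownames(out) <- NULL
  class(out) <- c("unwrap_scan", "data.frame")
  out
}

# build the model for one unwrap hypothesis and return its Debye curve
unwrap_model_curve <- function(unwrap, builder, q_model = default_q_grid(),
                               method = "histogram") {
  geom <- builder$geom %||% geometry_params()
  model <- build_nucleosome(builder$total_bp, builder$linker_left,
                            builder$linker_right, unwrap, geom)
  if (!is.null(builder$h1)) model <- add_linker_histone(model, builder$h1, geom)
  debye_intensity(model, q_model, method = method)
}
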