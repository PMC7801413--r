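# Seeded synthetic-data generators for every input the pipeline consumes.
# Each generator is a pure function of (parameters, seed); analysers never
# share code with the generators for the quantities under test (lattice
# peak positions are computed from the spacing formulas here and recovered
# by peak picking in the mesophase module).

#' Noise specification for synthetic profiles
#'
#' @param model `"gaussian_rel"` (Gaussian with sigma proportional to the
#'   intensity) or `"poisson_like"` (sigma proportional to sqrt of the
#'   intensity).
#' @param sigma0 Relative noise scale (0.02 approximates synchrotron SAXS
#'   counting statistics at moderate exposure).
#' @param floor Absolute intensity floor added inside the sigma model.
#' @param seed RNG seed (mandatory; generators never touch global RNG
#'   state implicitly).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("gaussian_rel", "poisson_like"),
                       sigma0 = 0.02, floor = 0, seed) {
  model <- match.arg(model)
  check_number(sigma0, "sigma0", min = 0)
  check_number(floor, "floor", min = 0)
  if (missing(seed) || !is_count(seed))
    stopf("`seed` must be given explicitly as a non-negative integer")
  structure(list(model = model, sigma0 = sigma0, floor = floor,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

noise_sigma <- function(noise, intensity) {
  switch(noise$model,
         gaussian_rel = noise$sigma0 * (intensity + noise$floor),
         poisson_like = noise$sigma0 * sqrt(pmax(intensity + noise$floor, 0)))
}

#' Simulate a noisy solution SAXS profile of a bead model
#'
#' Debye curve of the model plus Gaussian noise with
#' `sigma(q) = sigma0 * (I(q) + floor)` (or the Poisson-like variant); the
#' sigma column is populated. With `sigma0 = 0` the output is bit-identical
#' to [debye_intensity()] with the same `method`.
#'
#' @param model A [bead_model()].
#' @param q Momentum transfer grid, 1/A.
#' @param noise A [noise_spec()].
#' @param method Debye evaluation method.
#' @return A [saxs_profile()].
#' @export
simulate_solution_saxs <- function(model, q = default_q_grid(), noise,
                                   method = "histogram") {
  if (!inherits(noise, "noise_spec")) stopf("`noise` must be a noise_spec")
  base <- debye_intensity(model, q, method = method)
  if (noise$sigma0 == 0) return(base)
  sig <- noise_sigma(noise, base$intensity)
  I <- with_seed(noise$seed, base$intensity + stats::rnorm(length(q), 0, sig))
  saxs_profile(q, I, sig)
}

#' Condensed-phase diffraction specification
#'
#' Generating parameters for a 1D powder-like diffraction pattern: Bragg
#' or broad Gaussian peaks at the reflection positions implied by the
#' lattice parameters, on a power-law background. Reflection positions:
#' stacking orders at `n * 2*pi/h`; hexagonal reflections at
#' `(4*pi/(sqrt(3)*a_H)) * sqrt(i^2 + i*k + k^2)` (orders 1, 2 meaning the
#' (10) and (11) reflections); lamellar orders at `n * 2*pi/d_L`.
#'
#' @param h Stacking distance, A.
#' @param a_H Hexagonal inter-columnar distance, A, or NULL.
#' @param d_L Lamellar bilayer repeat, A, or NULL.
#' @param fwhm Peak full width at half maximum per series, 1/A: named
#'   vector or single value recycled to `c(stacking=, hex=, lamellar=)`.
#' @param amplitudes Peak heights per series first order (second orders
#'   are generated at 40% of the first).
#' @param background `c(A, p)` of the `A * q^-p` background.
#' @param orders Reflection orders per series, e.g.
#'   `list(stacking = 1:2, hex = 1:2, lamellar = 1:2)`.
#' @return An object of class `condensed_phase_spec`.
#' @export
condensed_phase_spec <- function(h, a_H = NULL, d_L = NULL,
                                 fwhm = 0.004,
                                 amplitudes = c(stacking = 1.5, hex = 1.0,
                                                lamellar = 2.0),
                                 background = c(A = 5e-4, p = 2.2),
                                 orders = list(stacking = 1:2, hex = 1:2,
                                               lamellar = 1:2)) {
  check_number(h, "h", min = 1)
  if (!is.null(a_H)) check_number(a_H, "a_H", min = 1)
  if (!is.null(d_L)) check_number(d_L, "d_L", min = 1)
  if (length(fwhm) == 1) fwhm <- c(stacking = fwhm, hex = fwhm, lamellar = fwhm)
  structure(list(h = h, a_H = a_H, d_L = d_L, fwhm = fwhm,
                 amplitudes = amplitudes, background = background,
                 orders = orders),
            class = "condensed_phase_spec")
}

# reflection table (q position, height, fwhm) implied by a spec
condensed_reflections <- function(spec) {
  rows <- list()
  add <- function(series, q1, mult) {
    for (k in seq_along(mult)) {
      rows[[length(rows) + 1]] <<- data.frame(
        series = series,
        q = q1 * mult[k],
        height = spec$amplitudes[[series]] * if (k == 1) 1 else 0.4,
        fwhm = spec$fwhm[[series]])
    }
  }
  ords <- spec$orders
  add("stacking", 2 * pi / spec$h, ords$stacking)
  if (!is.null(spec$a_H)) {
    # hk multipliers sqrt(h^2 + hk + k^2) for (10), (11), (20), ...
    mults <- c(1, sqrt(3), 2, sqrt(7))[ords$hex]
    add("hex", 4 * pi / (sqrt(3) * spec$a_H), mults)
  }
  if (!is.null(spec$d_L)) add("lamellar", 2 * pi / spec$d_L, ords$lamellar)
  do.call(rbind, rows)
}

#' Simulate a condensed-phase 1D diffraction profile
#'
#' Sum of Gaussian peaks at the lattice reflection positions of `spec`,
#' a power-law background, and seeded noise.
#'
#' @param spec A [condensed_phase_spec()].
#' @param q Momentum transfer grid, 1/A.
#' @param noise A [noise_spec()].
#' @return A [saxs_profile()] (sigma column present when `sigma0 > 0`).
#' @export
simulate_condensed_saxs <- function(spec,
                                    q = seq(0.01, 0.25, by = 0.00025),
                                    noise) {
  if (!inherits(spec, "condensed_phase_spec"))
    stopf("`spec` must be a condensed_phase_spec")
  if (!inherits(noise, "noise_spec")) stopf("`noise` must be a noise_spec")
  I <- spec$background[["A"]] * q^(-spec$background[["p"]])
  refl <- condensed_reflections(spec)
  for (i in seq_len(nrow(refl))) {
    s <- refl$fwhm[i] / (2 * sqrt(2 * log(2)))
    I <- I + refl$height[i] * exp(-(q - refl$q[i])^2 / (2 * s^2))
  }
  if (noise$sigma0 == 0) return(saxs_profile(q, I))
  sig <- noise_sigma(noise, I)
  In <- with_seed(noise$seed, I + stats::rnorm(length(q), 0, sig))
  saxs_profile(q, In, sig)
}

#' Simulate a Mg2+ precipitation/resolubilisation titration
#'
#' The soluble fraction is `1 - S_p(x) * (1 - S_r(x))` on the log10
#' concentration axis, where `S_p` is a rising precipitation sigmoid with
#' midpoint `log10(ec50_precip)` and width `dx_p`, and `S_r` a rising
#' resolubilisation sigmoid with midpoint `log10(ec50_resol)` and width
#' `dx_r`: fully soluble at low salt, fully precipitated between the two
#' transitions, resolubilised at high salt. Gaussian noise with scale
#' `sigma0` is added and the result clipped to `[0, 1.2]`. Defaults mirror
#' a 177 bp nucleosome titration: precipitation midpoint 3.0 mM with the
#' particle essentially fully precipitated by ~10 mM, resolubilisation
#' midpoint 34.2 mM essentially complete above ~100 mM.
#'
#' @param ec50_precip,ec50_resol Generating midpoints, mM
#'   (`ec50_resol > ec50_precip`).
#' @param dx_p,dx_r Sigmoid widths in log10-mM units.
#' @param n_points Number of log-spaced concentrations.
#' @param noise A [noise_spec()].
#' @param conc_range Concentration range, mM.
#' @return A [titration_curve()].
#' @export
simulate_titration <- function(ec50_precip = 3.0, ec50_resol = 34.2,
                               dx_p = 0.17, dx_r = 0.15,
                               n_points = 25, noise,
                               conc_range = c(0.05, 500)) {
  if (!inherits(noise, "noise_spec")) stopf("`noise` must be a noise_spec")
  check_number(ec50_precip, "ec50_precip", min = 1e-6)
  check_number(ec50_resol, "ec50_resol", min = 1e-6)
  if (ec50_resol <= ec50_precip)
    stopf("`ec50_resol` must exceed `ec50_precip` (crossed transitions)")
  if (!is_count(n_points) || n_points < 6) stopf("`n_points` must be >= 6")
  conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                 length.out = n_points)
  x <- log10(conc)
  s_p <- 1 / (1 + exp(-(x - log10(ec50_precip)) / dx_p))
  s_r <- 1 / (1 + exp(-(x - log10(ec50_resol)) / dx_r))
  y <- 1 - s_p * (1 - s_r)
  if (noise$sigma0 > 0) {
    y <- with_seed(noise$seed, y + stats::rnorm(n_points, 0, noise$sigma0))
  }
  titration_curve(conc, pmin(pmax(y, 0), 1.2))
}
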