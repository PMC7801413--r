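# Charge bookkeeping for nucleosome/chromatosome particles and EC50
# analysis of Mg2+ precipitation/resolubilisation titrations.

#' Charge ledger of a nucleosome or chromatosome particle
#'
#' DNA charge uses the unphosphorylated-5' convention `z_dna = -2*(N - 1)`
#' elementary charges for an N bp duplex; the histone octamer and linker
#' histone carry fixed net charges. The net particle charge is the sum of
#' the components.
#'
#' @param dna_bp DNA length in base pairs (>= 2).
#' @param with_h1 Include one bound linker histone (chromatosome)?
#' @param z_histone_octamer Net octamer charge, e.
#' @param z_h1 Net linker histone charge, e.
#' @return An object of class `charge_ledger` with fields `dna_bp`,
#'   `z_dna`, `z_histone_octamer`, `z_h1` (NA without H1) and `z_net`.
#' @examples
#' charge_ledger(177)$z_net              # -206
#' charge_ledger(177, with_h1 = TRUE)$z_net  # -154
#' @export
charge_ledger <- function(dna_bp, with_h1 = FALSE,
                          z_histone_octamer = 146, z_h1 = 52) {
  if (!is_count(dna_bp) || dna_bp < 2) stopf("`dna_bp` must be an integer >= 2")
  z_dna <- -2 * (dna_bp - 1)
  z_net <- z_dna + z_histone_octamer + if (with_h1) z_h1 else 0
  structure(list(dna_bp = as.integer(dna_bp), z_dna = z_dna,
                 z_histone_octamer = z_histone_octamer,
                 z_h1 = if (with_h1) z_h1 else NA_real_,
                 z_net = z_net),
            class = "charge_ledger")
}

#' @export
print.charge_ledger <- function(x, ...) {
  cat(sprintf("<charge_ledger> %d bp DNA: %+d e; octamer %+g e%s; net %+g e\n",
              x$dna_bp, x$z_dna, x$z_histone_octamer,
              if (is.na(x$z_h1)) "" else sprintf("; H1 %+g e", x$z_h1),
              x$z_net))
  invisible(x)
}

#' Percentage reduction in net negative charge between two particles
#'
#' `100 * (|z_a| - |z_b|) / |z_a|` for two net-negative charge ledgers;
#' e.g. the charge reduction of a chromatosome relative to the nucleosome
#' it derives from.
#'
#' @param ledger_a,ledger_b [charge_ledger()] objects (reference first).
#' @return Percentage (not rounded; round to taste).
#' @export
charge_reduction_percent <- function(ledger_a, ledger_b) {
  if (!inherits(ledger_a, "charge_ledger") || !inherits(ledger_b, "charge_ledger"))
    stopf("arguments must be charge_ledger objects")
  if (ledger_a$z_net >= 0 || ledger_b$z_net >= 0)
    stopf("charge reduction is defined for net-negative particles only")
  100 * (abs(ledger_a$z_net) - abs(ledger_b$z_net)) / abs(ledger_a$z_net)
}

#' Particle volume change implied by a radius-of-gyration change
#'
#' Assuming isometric scaling, a change of Rg from `rg_a` to `rg_b`
#' implies a relative volume change of `(rg_b/rg_a)^3 - 1`.
#'
#' @param rg_a,rg_b Radii of gyration, same units.
#' @return Volume change in percent.
#' @export
volume_increase_percent <- function(rg_a, rg_b) {
  check_number(rg_a, "rg_a", min = .Machine$double.eps)
  check_number(rg_b, "rg_b", min = .Machine$double.eps)
  100 * ((rg_b / rg_a)^3 - 1)
}

#' Construct a titration curve
#'
#' @param concentration Cation concentrations, mM, non-negative ascending.
#' @param soluble_fraction Supernatant absorbance normalised to the
#'   zero-salt sample, in `[0, 1.2]`.
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(concentration, soluble_fraction) {
  concentration <- as.numeric(concentration)
  soluble_fraction <- as.numeric(soluble_fraction)
  if (length(concentration) != length(soluble_fraction))
    stopf("`concentration` and `soluble_fraction` must have the same length")
  if (length(concentration) < 6) stopf("a titration curve needs at least 6 points")
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stopf("concentrations must be non-negative and finite")
  if (any(diff(concentration) <= 0)) stopf("concentrations must be ascending")
  if (any(!is.finite(soluble_fraction)) || any(soluble_fraction < 0) ||
      any(soluble_fraction > 1.2))
    stopf("soluble fractions must lie in [0, 1.2]")
  structure(list(concentration = concentration,
                 soluble_fraction = soluble_fraction),
            class = "titration_curve")
}

#' Read a titration CSV (concentration, soluble fraction)
#'
#' Two-column CSV with a header; the second column is either an already
#' normalised soluble fraction or a raw OD260 normalised here to the first
#' (lowest-salt) value when `normalise = TRUE`.
#'
#' @param path CSV path.
#' @param normalise Divide by the first reading?
#' @return A [titration_curve()].
#' @export
read_titration_csv <- function(path, normalise = FALSE) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stopf("'%s': expected two columns (conc_mM, value)", path)
  y <- df[[2]]
  if (normalise) y <- y / y[1]
  titration_curve(df[[1]], pmin(pmax(y, 0), 1.2))
}

#' Split a titration into precipitation and resolubilisation branches
#'
#' Splits at the global minimum of the soluble fraction; when the minimum
#' is a plateau (several points within `plateau_tol` of the minimum), the
#' split is placed at the point nearest the arithmetic midpoint of the
#' plateau's concentration range. Both branches retain the splitting
#' point. A monotonically decreasing curve yields an empty
#' resolubilisation branch and `resolubilisation_missing = TRUE`.
#'
#' @param curve A [titration_curve()].
#' @param plateau_tol Soluble-fraction tolerance defining the minimum
#'   plateau.
#' @return A list with data frames `precipitation` and `resolubilisation`
#'   (columns `concentration`, `soluble_fraction`), `split_at` (mM) and
#'   `resolubilisation_missing`.
#' @export
split_branches <- function(curve, plateau_tol = 0.02) {
  if (!inherits(curve, "titration_curve")) stopf("`curve` must be a titration_curve")
  x <- curve$concentration; y <- curve$soluble_fraction
  n <- length(x)
  ymin <- min(y)
  low <- which(y <= ymin + plateau_tol)
  # maximal contiguous run containing the argmin
  runs <- split(low, cumsum(c(1, diff(low) != 1)))
  argmin <- which.min(y)
  run <- runs[[which(vapply(runs, function(r) argmin %in% r, logical(1)))[1]]]
  mid_conc <- (x[min(run)] + x[max(run)]) / 2
  split_idx <- run[which.min(abs(x[run] - mid_conc))]

  prec <- data.frame(concentration = x[1:split_idx],
                     soluble_fraction = y[1:split_idx])
  missing_resol <- split_idx >= n - 1
  resol <- if (missing_resol) {
    data.frame(concentration = numeric(0), soluble_fraction = numeric(0))
  } else {
    data.frame(concentration = x[split_idx:n],
               soluble_fraction = y[split_idx:n])
  }
  list(precipitation = prec, resolubilisation = resol,
       split_at = x[split_idx],
       resolubilisation_missing = missing_resol)
}

#' Fit a Boltzmann sigmoid to a titration branch
#'
#' Nonlinear least squares for
#' `y = A2 + (A1 - A2) / (1 + exp((x - x0)/dx))` on the log10
#' concentration axis `x = log10(conc/mM)`. Initialisation takes the
#' plateaus from edge medians and the midpoint from the half-amplitude
#' crossing. The midpoint back-transformed to mM is the EC50.
#'
#' @param concentration Concentrations, mM (positive; zero-concentration
#'   points are dropped for the log axis).
#' @param soluble_fraction Responses.
#' @param degenerate_tol Minimum plateau separation below which the branch
#'   is flagged degenerate and no fit is attempted.
#' @return An object of class `boltzmann_fit` with fields `a1`, `a2`,
#'   `x0` (log10 mM), `dx`, `ec50` (mM), `residual_rms`, `degenerate`.
#' @export
fit_boltzmann <- function(concentration, soluble_fraction,
                          degenerate_tol = 0.05) {
  if (is.data.frame(concentration)) {
    soluble_fraction <- concentration$soluble_fraction
    concentration <- concentration$concentration
  }
  keep <- concentration > 0
  x <- log10(concentration[keep]); y <- soluble_fraction[keep]
  if (length(x) < 5) stopf("a Boltzmann fit needs at least 5 positive-concentration points")

  if (diff(range(y)) < degenerate_tol) {
    return(structure(list(a1 = NA_real_, a2 = NA_real_, x0 = NA_real_,
                          dx = NA_real_, ec50 = NA_real_,
                          residual_rms = stats::sd(y),
                          degenerate = TRUE),
                     class = "boltzmann_fit"))
  }

  ne <- max(2L, min(3L, floor(length(x) / 3)))
  a1_0 <- stats::median(y[seq_len(ne)])
  a2_0 <- stats::median(y[seq.int(length(y) - ne + 1, length(y))])
  half <- (a1_0 + a2_0) / 2
  cross <- which(diff(sign(y - half)) != 0)
  x0_0 <- if (length(cross)) {
    i <- cross[1]
    if (abs(y[i + 1] - y[i]) > 1e-12) {
      x[i] + (half - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
    } else {
      (x[i] + x[i + 1]) / 2
    }
  } else {
    stats::median(x)
  }
  if (!is.finite(x0_0)) x0_0 <- stats::median(x)
  dx_0 <- diff(range(x)) / 10 * sign(a1_0 - a2_0 + 1e-12)

  boltz <- function(p) p[2] + (p[1] - p[2]) * stats::plogis(-(x - p[3]) / p[4])
  resid_fn <- function(p) y - boltz(p)
  jac_fn <- function(p) {
    u <- (x - p[3]) / p[4]
    s <- stats::plogis(-u)       # overflow-safe 1/(1 + exp(u))
    core <- (p[1] - p[2]) * s * (1 - s) / p[4]
    -cbind(s, 1 - s, core, core * u)
  }
  out <- minpack.lm::nls.lm(
    par = c(a1 = a1_0, a2 = a2_0, x0 = x0_0, dx = abs(dx_0) + 1e-3),
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!(out$info %in% 1:4))
    stopf("Boltzmann fit failed to converge: %s", out$message)
  p <- out$par
  if (p[["x0"]] < min(x) || p[["x0"]] > max(x))
    warnf("fitted midpoint lies outside the data range; EC50 is an extrapolation")
  structure(list(a1 = p[["a1"]], a2 = p[["a2"]], x0 = p[["x0"]],
                 dx = p[["dx"]], ec50 = 10^p[["x0"]],
                 residual_rms = sqrt(mean(resid_fn(p)^2)),
                 degenerate = FALSE),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<boltzmann_fit> degenerate (plateaus indistinguishable)\n")
  } else {
    cat(sprintf("<boltzmann_fit> EC50 = %.3g mM (A1 = %.3f, A2 = %.3f, dx = %.3f, rms = %.3g)\n",
                x$ec50, x$a1, x$a2, x$dx, x$residual_rms))
  }
  invisible(x)
}

#' Analyse a full precipitation/resolubilisation titration
#'
#' Splits the curve at maximal precipitation, fits a Boltzmann sigmoid to
#' each branch, and reports the two EC50 values together with the maximal
#' concentration window of complete aggregation (soluble fraction below
#' `aggregation_threshold`).
#'
#' When the two transitions overlap (precipitation not complete before
#' resolubilisation begins), the raw midpoint of the second branch is
#' biased upward by the residual precipitation tail. The resolubilisation
#' sigmoid is therefore fitted to the resolubilised fraction of the
#' precipitated material, `(y - F_p) / (1 - F_p)`, where `F_p` is the
#' fitted precipitation-branch curve extrapolated across the second
#' branch; the correction is skipped where the precipitated fraction
#' `1 - F_p` falls below 0.3 (the fraction is then ill-determined) or when
#' the first fit is degenerate. Symmetrically, the precipitation branch is
#' then refitted on `(y - S_r)/(1 - S_r)` with `S_r` the fitted
#' resolubilised fraction, which removes the upward pull of the
#' resolubilisation onset on the precipitation tail.
#'
#' @param curve A [titration_curve()].
#' @param plateau_tol Passed to [split_branches()].
#' @param aggregation_threshold Soluble fraction defining complete
#'   aggregation.
#' @return An object of class `titration_result` with fields
#'   `ec50_precipitation` (mM), `ec50_resolubilisation` (mM or NA),
#'   `full_aggregation_window` (c(lo, hi) mM or NULL), `split_at`, and the
#'   two branch fits.
#' @export
analyze_titration <- function(curve, plateau_tol = 0.02,
                              aggregation_threshold = 0.05) {
  br <- split_branches(curve, plateau_tol)
  fit_p <- fit_boltzmann(br$precipitation)

  # normalised sigmoid shape rising 0 -> 1 with increasing x
  shape_rising <- function(fit, x) {
    g <- fit$a2 + (fit$a1 - fit$a2) / (1 + exp((x - fit$x0) / fit$dx))
    s <- (g - fit$a1) / (fit$a2 - fit$a1)
    pmin(pmax(s, 0), 1)
  }

  fit_r <- if (br$resolubilisation_missing || nrow(br$resolubilisation) < 5) {
    NULL
  } else {
    resol <- br$resolubilisation
    if (!fit_p$degenerate) {
      xr <- log10(resol$concentration)
      # soluble shape of the precipitation transition, 1 -> 0
      Fp <- 1 - shape_rising(fit_p, xr)
      precipitated <- 1 - Fp
      ok <- precipitated > 0.3
      if (sum(ok) >= 5) {
        resol <- data.frame(
          concentration = resol$concentration[ok],
          soluble_fraction = pmin(pmax(
            (resol$soluble_fraction[ok] - Fp[ok]) / precipitated[ok], 0), 1.2))
      }
    }
    fit_boltzmann(resol)
  }

  if (!is.null(fit_r) && !fit_r$degenerate && !fit_p$degenerate) {
    prec <- br$precipitation
    pos <- prec$concentration > 0
    xp <- log10(prec$concentration[pos])
    Sr <- pmin(shape_rising(fit_r, xp), 0.99)
    ok <- Sr < 0.7
    if (sum(ok) >= 5) {
      corrected <- data.frame(
        concentration = prec$concentration[pos][ok],
        soluble_fraction = pmin(pmax(
          (prec$soluble_fraction[pos][ok] - Sr[ok]) / (1 - Sr[ok]), 0), 1.2))
      fit_p <- tryCatch(fit_boltzmann(corrected), error = function(e) fit_p)
    }
  }

  # joint polish: refit the full two-transition curve with both midpoints
  # free, initialised from the branch fits; uses every point and the
  # shared plateaus, which tightens both EC50 estimates
  if (!is.null(fit_r) && !fit_r$degenerate && !fit_p$degenerate) {
    pos <- curve$concentration > 0
    dfj <- data.frame(x = log10(curve$concentration[pos]),
                      y = curve$soluble_fraction[pos])
    joint_resid <- function(p) {
      sp <- 1 / (1 + exp(-(dfj$x - p[3]) / p[4]))
      sr <- 1 / (1 + exp(-(dfj$x - p[5]) / p[6]))
      dfj$y - (p[2] + (p[1] - p[2]) * (1 - sp * (1 - sr)))
    }
    joint <- tryCatch({
      out <- minpack.lm::nls.lm(
        par = c(T = 1, B = 0, xp = fit_p$x0, dp = abs(fit_p$dx),
                xr = fit_r$x0, dr = abs(fit_r$dx)),
        fn = joint_resid,
        control = minpack.lm::nls.lm.control(maxiter = 500))
      if (out$info %in% 1:4) out$par else NULL
    }, error = function(e) NULL)
    if (!is.null(joint) &&
        joint[["xp"]] < joint[["xr"]] &&
        joint[["xp"]] >= min(dfj$x) && joint[["xr"]] <= max(dfj$x)) {
      fit_p$x0 <- joint[["xp"]]; fit_p$dx <- joint[["dp"]]
      fit_p$ec50 <- 10^joint[["xp"]]
      fit_r$x0 <- joint[["xr"]]; fit_r$dx <- joint[["dr"]]
      fit_r$ec50 <- 10^joint[["xr"]]
    }
  }

  x <- curve$concentration; y <- curve$soluble_fraction
  agg <- which(y < aggregation_threshold)
  window <- if (length(agg)) {
    runs <- split(agg, cumsum(c(1, diff(agg) != 1)))
    lens <- vapply(runs, function(r) diff(range(x[r])), numeric(1))
    r <- runs[[which.max(lens)]]
    c(min(x[r]), max(x[r]))
  } else NULL

  structure(list(ec50_precipitation = fit_p$ec50,
                 ec50_resolubilisation = if (is.null(fit_r) || fit_r$degenerate)
                   NA_real_ else fit_r$ec50,
                 full_aggregation_window = window,
                 split_at = br$split_at,
                 resolubilisation_missing = br$resolubilisation_missing,
                 fit_precipitation = fit_p,
                 fit_resolubilisation = fit_r),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("<titration_result> EC50 precipitation = %.3g mM; resolubilisation = %s\n",
              x$ec50_precipitation,
              if (is.na(x$ec50_resolubilisation)) "absent"
              else sprintf("%.3g mM", x$ec50_resolubilisation)))
  if (!is.null(x$full_aggregation_window))
    cat(sprintf("  fully aggregated over [%.3g, %.3g] mM\n",
                x$full_aggregation_window[1], x$full_aggregation_window[2]))
  invisible(x)
}
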