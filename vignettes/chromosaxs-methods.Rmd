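---
title: "Models and methods behind chromosaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromosaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromosaxs)
```

`chromosaxs` analyses three experiments on nucleosome and chromatosome
particles: dilute-solution SAXS against explicit coarse-grained models,
Bragg indexing of Mg²⁺-condensed mesophases, and Mg²⁺
precipitation/resolubilisation titrations. This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## Coarse-grained particle geometry

A particle is a set of weighted spherical beads. Wrapped DNA lies on a
left-handed superhelix (radius 41.9 Å, pitch 25.9 Å, 1.65 turns per fully
wrapped 147 bp — standard crystallographic core-particle values, all
exposed in `geometry_params()`), with the dyad base pair on the +y axis
and the superhelix axis along z. Each wrapped base pair occupies the
centre of an arc segment of width 2π·1.65/147, so a partially unwrapped
core of n_w base pairs spans exactly 1.65·n_w/147 turns. Linker DNA and
unwrapped base pairs continue as straight duplexes (3.4 Å/bp) tangent to
the superhelix at the detachment point, so the DNA path stays continuous
as the ends breathe.

One bead per base pair with a 10 Å effective radius is deliberate: the
analysis window ends at q = 0.25 Å⁻¹, below which duplex cross-sectional
detail is invisible. Each DNA bead carries the volume of a duplex cylinder
slice (π·10²·3.4 Å³), not the volume of its 10 Å form-factor sphere;
with the default DNA:protein contrast of 2.5:1 per unit volume this gives
a total DNA:protein weight ratio of ≈2.9:1, in line with the relative
X-ray excess densities of hydrated DNA and protein. The histone core is a
cylinder (radius 32 Å, height 50 Å) filled with beads on a 5 Å cubic
lattice; histone tails are not modelled separately — in solution they
collapse onto the DNA and their scattering mass is folded into the core
volume. The linker histone's globular domain is an ~80-residue bead
cluster centred on the dyad axis midway between the two linker arms,
displaced 5 Å towards one arm for the tilted on-dyad mode (no metric tilt
value is established experimentally; the default is a plausible choice
exposed in `h1_placement()`); an optional C-terminal-domain bead string
tracks the tilted arm at 10 Å offset.

Because the geometry is synthetic rather than derived from an atomic
structure, absolute sizes (e.g. the model Rg of ≈42.5 Å for the 177 bp
particle) should not be compared directly with experimental Rg values;
the model is built to reproduce curve *shapes* — the superhelical dip
near q = 0.14 Å⁻¹ and its response to end unwrapping — over the fitting
window, with scale and background free parameters of every fit.

## Forward and inverse scattering

`debye_intensity()` evaluates the orientation-averaged Debye sum with
uniform-sphere form factors per bead. The `"histogram"` method bins pair
distances at 0.5 Å, storing each bin's mass-weighted mean distance; on
the default grid (301 points, 0.005–0.30 Å⁻¹) it agrees with the exact
double sum to better than 0.1% and is ~20× faster, so it is the method
used by the unwrap scan.

`pair_distance_distribution()` histograms weighted pair distances and
smears every pair with the exact conditional distance density of two
uniform spheres (the radial density of the difference vector of two
sphere-uniform points, combined with the cosine-angle law), plus the
intra-bead self term. This makes P(r), Rg and the Debye curve mutually
consistent: the sine transform of P(r) reproduces I(q) to <1% on
q ≤ 0.25 Å⁻¹, and the P(r)-moment Rg matches the coordinate-space Rg
(which includes the 3/5·a² sphere term) to <0.5%. Zero-radius beads have
a flat self term in I(q) with no pair-distance counterpart; it is kept
only in the P(r) normalisation.

`guinier_fit()` iterates the window to qmax·Rg ≤ 1.3 and fits ln I
against q² by weighted least squares (weights (I/σ)², or I² when no
uncertainties are present, i.e. a constant-absolute-error assumption for
noiseless model curves). The conventional 1.3 window carries a known
truncation bias for globular shapes — ≈1.7% for an exact sphere,
≈0.9% for the nucleosome model — which shrinks monotonically as the
window is tightened; the limit is a parameter.

`ift_pofr()` solves the regularised indirect Fourier transform:
non-negative least squares (`pracma::lsqnonneg`) on the sine-kernel
forward map with a second-difference penalty, endpoints pinned to zero.
The penalty weight is dimensionless (scaled by the ratio of the norms of
the data and penalty operators) and chosen by an L-curve corner search
over 10⁻⁴–10² when not given. A caveat inherent to any sine-kernel IFT:
a flat (self-term or background) intensity component is represented as
mass at r ≈ 0, so constant offsets should be removed before inversion.

`fit_scale_background()` solves the closed-form weighted least squares
for intensity scale and constant background on the 0.05–0.25 Å⁻¹ window
(below 0.05 Å⁻¹ inter-particle interference contaminates dilute-solution
data; above 0.25 Å⁻¹ noise dominates), interpolating the model linearly
in (q, log I) with extrapolation forbidden. `unwrap_scan()` ranks
end-unwrapping hypotheses by reduced χ², breaking ties in favour of less
unwrapping (parsimony). The dip metric is the log₁₀ ratio of the
geometric mean of the flanking maxima to the minimum within
0.14 ± 0.03 Å⁻¹, zero when no interior minimum exists.

## Mesophase indexing

Condensed-phase 1D patterns are modelled as Bragg (or broad) Gaussian
peaks on a power-law background A·q⁻ᵖ. The analysis pipeline
(`index_condensed_profile()`) estimates the background in log–log space,
picks peaks, re-estimates the background excluding ±2 FWHM around each
peak, re-picks, and classifies.

Peak picking keeps local maxima of the excess whose topographic
prominence exceeds 5% of the maximum excess *and*, when the profile
carries uncertainties, 5σ at the peak — without the significance filter,
noise spikes on the steep low-q background register as spurious sharp
peaks. Centres are refined by a parabola fitted to all contiguous points
above half prominence (reducing to the classic 3-point parabola when only
three points qualify); on a fine grid this keeps the centre estimate
noise-limited well below the grid spacing, which the 1% lattice-parameter
round trip requires. Widths are full widths at half prominence.

Indexing uses d = 2π/q throughout (s = q/2π dialects are not accepted).
The lamellar test is |q₂/q₁ − 2| ≤ 0.05 with the lowest-q compatible pair
winning (largest repeat). The hexagonal root requires a √3 companion —
the (11) reflection — matched within 5% of the expected position widened
by half the candidate peak's width; a ratio-2 (20) companion is recorded
but never sufficient on its own, since lamellar first/second orders and
stacking first/second orders are themselves ratio-2 pairs. The width
allowance exists because in chromatosome condensates the hexagonal (11)
reflection overlaps the stacking peak; one peak may legitimately carry
both labels, and the stacking distance h is always computed from the
dominant peak in the 50–65 Å band. Reflections already assigned as
lamellar orders are excluded as hexagonal roots. `classify_phase()`
returns lamello-columnar only when the sharp peaks (relative width < 0.3)
index both series *and* a stacking reflection exists; any other peaked
pattern is columnar isotropic with h from the dominant 0.09–0.13 Å⁻¹
peak; no peaks means isotropic solution. The sharp/broad width threshold
0.3 and the 5% ratio tolerance encode qualitative "Bragg" vs "broad"
language and are parameters.

## Titrations and electrostatics

Charge ledgers use the unphosphorylated-5′ DNA convention z = −2(N−1) e
(which gives −352 e for 177 bp), +146 e for the histone octamer and
+52 e for H1. EC₅₀ analysis fits the Boltzmann sigmoid on the log₁₀
concentration axis (titrations span 0.05–500 mM; zero-concentration
points are dropped). The curve is split at the global minimum of the
soluble fraction — at the arithmetic midpoint of the minimum plateau when
the bottom is flat — and each branch fitted with plateaus initialised
from edge medians and the midpoint from the half-amplitude crossing.
Optimisation uses `minpack.lm::nls.lm` with an analytic Jacobian; a
branch whose response spans less than 0.05 is flagged degenerate rather
than fitted.

When the two transitions overlap, raw branch midpoints are biased: the
resolubilisation onset lifts the precipitation tail and vice versa. The
analysis therefore (i) fits the resolubilisation sigmoid to the
resolubilised fraction of precipitated material, (y − F_p)/(1 − F_p),
with F_p the normalised fitted precipitation curve, skipping points where
the precipitated fraction is below 0.3; (ii) refits precipitation with
the fitted resolubilisation onset removed; and (iii) polishes both
midpoints with a joint fit of the full two-transition model
y = B + (T−B)·(1 − S_p(1 − S_r)), initialised from the branch fits and
accepted only when it converges with ordered midpoints inside the data
range. On noiseless synthetic curves this recovers both generating EC₅₀
values to <10⁻⁸ relative; the raw branch fits alone are several percent
off whenever the transitions are not fully separated.

## Synthetic data: what the generators emulate

All generators are pure functions of (parameters, seed) and share no
code with the analysers for the quantities under test: condensed-phase
peak positions are *placed* from the lattice formulas and *recovered* by
peak picking; titration EC₅₀s are placed as sigmoid midpoints and
recovered by fitting.

* `simulate_solution_saxs()` adds Gaussian noise with σ(q) = σ₀(I + floor)
  (σ₀ = 0.02 default, approximating synchrotron counting statistics at
  moderate exposure). It does not emulate inter-particle structure
  factors, instrumental smearing, or buffer-subtraction artefacts.
* `simulate_condensed_saxs()` uses Gaussian peaks (no Lorentzian/Voigt
  tails, no paracrystalline disorder) with per-series widths — narrow
  (0.004 Å⁻¹) for Bragg-like, wide (≳0.04 Å⁻¹) for liquid-like order —
  on an A·q⁻ᵖ background.
* `simulate_titration()` builds the soluble fraction as
  1 − S_p·(1 − S_r), the complement of (precipitated × not-resolubilised),
  which is ≈1 at both concentration extremes and ≈0 between the
  transitions, and equals ½ at the precipitation midpoint (times a rising
  factor ≈1 when the transitions are well separated). Default midpoints
  3.0 and 34.2 mM with widths dx_p = 0.17 and dx_r = 0.15 log₁₀ units
  reproduce a nucleosome-like curve that is fully soluble below ~1 mM,
  essentially fully precipitated near 10 mM, and resolubilised above
  ~100 mM; a chromatosome-like curve (midpoints 0.6/51.2 mM, steeper
  resolubilisation dx_r ≈ 0.05) stays completely aggregated across
  roughly 4–35 mM. Noise is Gaussian, clipped to [0, 1.2] as normalised
  absorbance readings are.

Passing round trips on these generators demonstrates that the estimators
are unbiased and precise *under the assumed noise model and peak shapes*;
they do not certify behaviour on real detector data with correlated
noise, smearing, or non-power-law backgrounds.

Two identifiability choices in the tests deserve mention. The
condensed-phase round trip draws lattice parameters with the stacking and
hexagonal (11) reflections separated by at least twice the peak width:
when a_H ≈ 2h the two reflections coincide exactly and no 1D analysis can
separate them. And the unwrap-scan trials use symmetric unwrapping
candidates at 5 bp granularity — mirror-symmetric pairs (n, m)/(m, n)
produce congruent models with identical spectra, so only the sorted pair
is identifiable from solution scattering.

## Numerical details and degenerate inputs

* Histogram Debye bin 0.5 Å; P(r) bin 0.5 Å; sphere-pair smearing uses a
  32-point midpoint rule on the offset density, normalised to unit mass.
* `sinc` and the sphere form factor switch to series below 10⁻⁶ and 10⁻³
  argument respectively; logistic terms use `plogis` against overflow.
* Problem sizes in the tests: 1596-bead particle models, 301-point
  solution curves, 961-point condensed patterns, 25-point titrations,
  20–200 seeded replicates per property — sizes at which every statistic
  stabilises while the whole suite runs in about a minute.
* Degenerate inputs fail loudly with informative errors: empty models,
  non-ascending q, windows outside the data, flat profiles (no Guinier
  region), monotone titrations (flagged missing resolubilisation),
  constant branches (degenerate-plateau flag).

## Known limitations

No absolute-intensity calibration, hydration layer, or structure factor;
no sequence-dependent DNA geometry or energy minimisation; no 2D pattern
reduction, Scherrer domain-size analysis, or 3D indexing; no
polyelectrolyte theory linking charge to EC₅₀ beyond the monotonic rule
used in the synthetic tests. The bead models approximate atomic
structures geometrically, so model-to-data fits are meaningful in curve
shape (χ² over the fitting window), not in absolute Rg.
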