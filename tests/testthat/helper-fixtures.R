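# Shared fixtures, memoised across test files (model building and Debye
# curves are the expensive steps; everything is generated in code).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

ncp177 <- function() fixture("ncp177", function() build_nucleosome(177, 15, 15))

ncp177_curve <- function() {
  fixture("ncp177_curve",
          function() debye_intensity(ncp177(), method = "histogram"))
}

builder177 <- function() list(total_bp = 177, linker_left = 15, linker_right = 15)

sym_unwraps <- function() {
  list(unwrap_spec(0, 0), unwrap_spec(5, 5), unwrap_spec(10, 10),
       unwrap_spec(15, 15))
}

sym_curves <- function() {
  fixture("sym_curves", function() {
    lapply(sym_unwraps(), function(u)
      chromosaxs:::unwrap_model_curve(u, builder177()))
  })
}

# exhaustive 4x4 grid of (n_left, n_right) in {0, 5, 10, 15}^2
grid16 <- function() {
  fixture("grid16", function() {
    g <- expand.grid(n_left = c(0, 5, 10, 15), n_right = c(0, 5, 10, 15))
    lapply(seq_len(nrow(g)), function(i) unwrap_spec(g$n_left[i], g$n_right[i]))
  })
}

grid16_curves <- function() {
  fixture("grid16_curves", function() {
    lapply(grid16(), function(u)
      chromosaxs:::unwrap_model_curve(u, builder177()))
  })
}

# add relative Gaussian noise to a noiseless curve under a fixed seed
noisy_from <- function(curve, seed, sigma0 = 0.02) {
  sig <- sigma0 * curve$intensity
  I <- chromosaxs:::with_seed(seed,
    curve$intensity + stats::rnorm(length(sig), 0, sig))
  saxs_profile(curve$q, I, sig)
}

# sharp Bragg peak list at the condensed-phase chromatosome positions
chromatosome_peaks <- function(fwhm = 0.004) {
  pk <- data.frame(q_center = c(0.0278, 0.056, 0.066, 0.1075, 0.21),
                   height = c(2, 0.8, 1, 1.5, 0.4),
                   fwhm = fwhm)
  pk$relative_width <- pk$fwhm / pk$q_center
  class(pk) <- c("saxs_peaks", "data.frame")
  pk
}

random_cloud <- function(n, seed, radius = 0, box = 50) {
  pos <- chromosaxs:::with_seed(seed, matrix(stats::runif(3 * n, -box, box), ncol = 3))
  w <- chromosaxs:::with_seed(seed + 1, stats::runif(n, 0.5, 2))
  bead_model(pos, w, radius, "dna_core")
}
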