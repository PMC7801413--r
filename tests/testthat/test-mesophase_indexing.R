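test_that("power-law background estimation is exact on clean inputs", {
  q <- seq(0.01, 0.25, by = 0.001)
  bg <- estimate_background(saxs_profile(q, 3 * q^-2))
  expect_equal(bg$A, 3, tolerance = 1e-6)
  expect_equal(bg$p, 2, tolerance = 1e-6)

  flat <- estimate_background(saxs_profile(q, rep(4, length(q))))
  expect_equal(flat$p, 0, tolerance = 1e-9)

  withpeak <- 3 * q^-2 + 5 * exp(-(q - 0.11)^2 / (2 * 0.003^2))
  bg2 <- estimate_background(saxs_profile(q, withpeak),
                             exclusion_windows = list(c(0.09, 0.13)))
  expect_equal(bg2$A, 3, tolerance = 0.01)
  expect_equal(bg2$p, 2, tolerance = 0.01)

  expect_error(estimate_background(saxs_profile(q[1:5], rep(1, 5))), "10 points")
})

test_that("peak picking refines centres below the grid spacing", {
  q <- seq(0.01, 0.25, by = 0.0005)
  bg_true <- 5e-4 * q^-2.2
  y <- bg_true + 1.5 * exp(-(q - 0.1075)^2 / (2 * 0.002^2))
  bg <- estimate_background(saxs_profile(q, y),
                            exclusion_windows = list(c(0.09, 0.125)))
  pk <- pick_peaks(saxs_profile(q, y), bg)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$q_center - 0.1075), 5e-4)

  mono <- pick_peaks(saxs_profile(q, bg_true), bg)
  expect_equal(nrow(mono), 0L)

  centers <- c(0.0278, 0.056, 0.066, 0.1075)
  y4 <- bg_true
  for (qc in centers) y4 <- y4 + exp(-(q - qc)^2 / (2 * 0.0017^2))
  bg4 <- estimate_background(saxs_profile(q, y4),
                             exclusion_windows = lapply(centers, function(qc) qc + c(-0.01, 0.01)))
  pk4 <- pick_peaks(saxs_profile(q, y4), bg4)
  expect_equal(nrow(pk4), 4L)
  expect_true(all(abs(pk4$q_center - centers) < 5e-4))
})

test_that("lamellar and hexagonal series index by their ratio signatures", {
  lam <- index_lamellar(c(0.0314159, 0.0628318))
  expect_true(lam$found)
  expect_equal(lam$d_L, 200, tolerance = 1e-4)
  expect_false(index_lamellar(c(0.03, 0.07))$found)

  lam2 <- index_lamellar(chromatosome_peaks())
  expect_true(lam2$found)
  expect_equal(lam2$d_L, 2 * pi / 0.0278, tolerance = 1e-9)
  expect_equal(lam2$d_L, 226, tolerance = 0.002)

  hex <- index_hexagonal(c(0.1, 0.17320, 0.2))
  expect_true(hex$found)
  expect_equal(hex$a_H, 4 * pi / (sqrt(3) * 0.1), tolerance = 1e-6)
  expect_equal(hex$a_H, 72.55, tolerance = 1e-3)
  expect_false(index_hexagonal(c(0.1, 0.15))$found)

  hex2 <- index_hexagonal(chromatosome_peaks())
  expect_true(hex2$found)
  expect_equal(hex2$assignments[["q10"]], 0.066)
  expect_equal(hex2$a_H, 110, tolerance = 0.001)

  expect_equal(stacking_distance(0.1075), 58.45, tolerance = 1e-4)
  expect_equal(stacking_distance(2 * pi), 1, tolerance = 1e-12)
  expect_equal(stacking_distance(0.11), 57.1, tolerance = 1e-3)
})

test_that("d-spacing identities hold and indexing is scale covariant", {
  pk <- chromatosome_peaks()
  ph <- classify_phase(pk)
  expect_equal(ph$h * ph$assignments$stacking[["q1h"]], 2 * pi, tolerance = 1e-12)
  expect_equal(ph$d_L * ph$assignments$lamellar[["q1L"]], 2 * pi, tolerance = 1e-12)
  expect_equal(ph$a_H * ph$assignments$hexagonal[["q10"]], 4 * pi / sqrt(3),
               tolerance = 1e-12)

  # the series indexers are scale covariant: q -> k*q divides every
  # reported distance by k exactly
  k <- 1.7
  pk2 <- pk
  pk2$q_center <- pk$q_center * k
  pk2$fwhm <- pk$fwhm * k
  lam <- index_lamellar(pk); lam2 <- index_lamellar(pk2)
  expect_equal(lam2$d_L, lam$d_L / k, tolerance = 1e-12)
  hex <- index_hexagonal(pk); hex2 <- index_hexagonal(pk2)
  expect_equal(hex2$a_H, hex$a_H / k, tolerance = 1e-12)
  expect_equal(stacking_distance(0.1075 * k), stacking_distance(0.1075) / k,
               tolerance = 1e-12)
})

test_that("phase classification separates the three condensate regimes", {
  ph <- classify_phase(chromatosome_peaks())
  expect_equal(ph$phase, "lamello_columnar")
  expect_equal(ph$h, 58.45, tolerance = 1e-4)
  expect_equal(ph$a_H, 110, tolerance = 0.001)
  expect_equal(ph$d_L, 226, tolerance = 0.002)
  # the overlapping reflection carries both the hexagonal (11) and the
  # stacking label
  expect_equal(ph$assignments$hexagonal[["q11"]], 0.1075)
  expect_equal(ph$assignments$stacking[["q1h"]], 0.1075)
  expect_equal(ph$assignments$lamellar[["q2L"]], 0.056)

  broad <- data.frame(q_center = c(0.05, 0.11, 0.175),
                      height = c(0.5, 1, 0.3),
                      fwhm = c(0.02, 0.045, 0.07))
  broad$relative_width <- broad$fwhm / broad$q_center
  class(broad) <- c("saxs_peaks", "data.frame")
  phb <- classify_phase(broad)
  expect_equal(phb$phase, "columnar_isotropic")
  expect_equal(phb$h, 2 * pi / 0.11, tolerance = 1e-9)
  expect_true(is.na(phb$a_H))

  none <- classify_phase(chromatosome_peaks()[0, ])
  expect_equal(none$phase, "isotropic_solution")
})

test_that("simulated condensed spectra round-trip through the indexer", {
  spec <- condensed_phase_spec(h = 58.45, a_H = 110, d_L = 226)
  prof <- simulate_condensed_saxs(spec, noise = noise_spec(sigma0 = 0.02, seed = 1))
  ph <- index_condensed_profile(prof)
  expect_equal(ph$phase, "lamello_columnar")
  expect_equal(ph$h, 58.45, tolerance = 0.01)
  expect_equal(ph$a_H, 110, tolerance = 0.01)
  expect_equal(ph$d_L, 226, tolerance = 0.01)

  broad <- condensed_phase_spec(h = 57, fwhm = 0.045,
                                orders = list(stacking = 1))
  profb <- simulate_condensed_saxs(broad, noise = noise_spec(sigma0 = 0.02, seed = 2))
  phb <- index_condensed_profile(profb)
  expect_equal(phb$phase, "columnar_isotropic")
  expect_equal(phb$h, 57, tolerance = 0.02)
})
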