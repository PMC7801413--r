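test_that("Debye intensity matches closed forms and scales quadratically", {
  q <- default_q_grid()
  one <- bead_model(matrix(0, 1, 3), 3, 0, "dna_core")
  I1 <- debye_intensity(one, q, method = "exact")
  expect_equal(I1$intensity, rep(9, length(q)), tolerance = 1e-12)

  d <- 35
  two <- bead_model(rbind(c(0, 0, 0), c(0, 0, d)), 1, 0, "dna_core")
  I2 <- debye_intensity(two, q, method = "exact")
  expect_equal(I2$intensity, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)

  cloud <- random_cloud(40, seed = 5, radius = 4)
  Ia <- debye_intensity(cloud, q, method = "exact")
  cloud2 <- cloud; cloud2$weights <- 3 * cloud$weights
  Ib <- debye_intensity(cloud2, q, method = "exact")
  expect_equal(Ib$intensity, 9 * Ia$intensity, tolerance = 1e-12)

  # intensity extrapolates to (sum w f(0))^2 at q -> 0
  I0 <- debye_intensity(cloud, 1e-5, method = "exact")$intensity
  expect_equal(I0, sum(cloud$weights)^2, tolerance = 1e-6)
})

test_that("histogram Debye agrees with the exact double sum", {
  cloud <- random_cloud(100, seed = 21, radius = 3)
  q <- default_q_grid()
  Ie <- debye_intensity(cloud, q, method = "exact")
  Ih <- debye_intensity(cloud, q, method = "histogram")
  expect_lt(max(abs(Ih$intensity - Ie$intensity) / Ie$intensity), 2e-3)
})

test_that("model P(r) reproduces pair distances, Rg and Dmax", {
  d <- 60
  two <- bead_model(rbind(c(0, 0, 0), c(0, 0, d)), 1, 0, "dna_core")
  pd <- pair_distance_distribution(two, bin_width = 0.5)
  occupied <- pd$r[pd$p > 0]
  expect_length(occupied, 1L)
  expect_lt(abs(occupied - d), 0.5)
  expect_equal(pd$rg, d / 2, tolerance = 5e-3)

  rod <- make_straight_duplex(40, geom = geometry_params(dna_bead_radius = 1e-6))
  pdr <- pair_distance_distribution(rod, bin_width = 0.5)
  expect_lt(abs(pdr$dmax - 39 * 3.4), 1)
  # rod P(r): monotone (linearly decaying envelope) after the first bins
  pk <- which.max(pdr$p)
  expect_lt(pdr$r[pk], 15)
  expect_true(all(pd$p >= 0))

  ncp <- ncp177()
  pdn <- pair_distance_distribution(ncp)
  expect_equal(pdn$rg, rg_of_model(ncp), tolerance = 5e-3)
  expect_lt(abs(pdn$dmax - dmax_of_model(ncp)), 0.5 + 1e-9)
})

test_that("P(r) forward-transforms back to the Debye intensity", {
  ncp <- ncp177()
  pd <- pair_distance_distribution(ncp)
  Ih <- ncp177_curve()
  If <- pofr_intensity(pd, Ih$q)
  sel <- Ih$q <= 0.25
  expect_lt(max(abs(If$intensity[sel] - Ih$intensity[sel]) / Ih$intensity[sel]),
            0.01)
})

test_that("Guinier slope of the model curve recovers the coordinate Rg", {
  ncp <- ncp177()
  gf <- guinier_fit(ncp177_curve())
  expect_equal(gf$rg, rg_of_model(ncp), tolerance = 0.01)
  expect_lte(gf$q_window[2] * gf$rg, 1.3 + 1e-6)
  expect_gt(gf$r_squared, 0.999)
})

test_that("dip metric quantifies the q ~ 0.14 wrapping depression", {
  # constructed piecewise profile with a dip of exactly a factor 10
  q <- seq(0.08, 0.2, length.out = 121)
  y <- rep(10, 121)
  y[q > 0.13 & q < 0.15] <- 1
  prof <- saxs_profile(q, y)
  expect_equal(dip_metric(prof), 1.0, tolerance = 1e-12)

  mono <- saxs_profile(q, exp(-20 * q))
  expect_equal(dip_metric(mono), 0)

  expect_error(dip_metric(saxs_profile(seq(0.2, 0.3, 0.01), rep(1, 11))),
               "cover")

  wrapped <- sym_curves()[[1]]
  unwrapped20 <- chromosaxs:::unwrap_model_curve(unwrap_spec(20, 20), builder177())
  expect_gt(dip_metric(wrapped), dip_metric(unwrapped20))
})
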