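test_that("Guinier fit recovers the Rg of an ideal sphere", {
  q <- default_q_grid()
  R <- 30
  I <- chromosaxs:::sphere_form_factor(q, R)^2
  # the conventional qmax*Rg <= 1.3 window carries the sphere's known
  # truncation bias (~2%); a stricter window removes it
  gf <- guinier_fit(saxs_profile(q, I))
  expect_equal(gf$rg, sqrt(3 / 5) * R, tolerance = 0.02)
  gf1 <- guinier_fit(saxs_profile(q, I), qmax_rg_limit = 0.8)
  expect_equal(gf1$rg, sqrt(3 / 5) * R, tolerance = 0.01)
  expect_lt(abs(gf1$rg - sqrt(3 / 5) * R), abs(gf$rg - sqrt(3 / 5) * R))

  flat <- saxs_profile(q, rep(2, length(q)))
  expect_error(guinier_fit(flat), "Guinier")
})

test_that("IFT recovers a point pair distance and obeys regularisation limits", {
  q <- seq(0.005, 0.3, length.out = 301)
  prof <- saxs_profile(q, chromosaxs:::sinc(q * 60))
  pd <- ift_pofr(prof, dmax = 80)
  expect_lt(abs(pd$r[which.max(pd$p)] - 60), 0.8 + 1e-9)

  # chi2 grows monotonically as the smoothness penalty dominates
  base <- ncp177_curve()
  withsig <- saxs_profile(base$q, base$intensity, 0.01 * base$intensity)
  chis <- vapply(c(1e-4, 1e-1, 1e2), function(a) {
    ift_pofr(withsig, dmax = 140, alpha = a)$chi2_reduced
  }, numeric(1))
  expect_true(all(diff(chis) >= 0))

  expect_warning(ift_pofr(withsig, dmax = 5000), "resolvable")
})

test_that("IFT round trip on a nucleosome curve is self-consistent", {
  ncp <- ncp177()
  base <- ncp177_curve()
  withsig <- saxs_profile(base$q, base$intensity, 0.01 * base$intensity)
  pd <- ift_pofr(withsig, dmax = dmax_of_model(ncp))
  expect_equal(pd$rg, rg_of_model(ncp), tolerance = 0.02)
  expect_lte(pd$chi2_reduced, 1.5)

  # dual-route Rg: Guinier slope versus P(r) moments agree within 3%
  gf <- guinier_fit(base)
  expect_equal(gf$rg, pd$rg, tolerance = 0.03)
})

test_that("scale/background fitting is exact, calibrated and discriminating", {
  m <- ncp177_curve()
  exact <- saxs_profile(m$q, 2 * m$intensity + 5, sigma = 0.02 * m$intensity)
  f <- fit_scale_background(m, exact)
  expect_equal(f$scale, 2, tolerance = 1e-9)
  expect_equal(f$background, 5, tolerance = 1e-6)
  expect_lt(f$chi2_reduced, 1e-15)

  noisy <- noisy_from(m, seed = 99)
  fn <- fit_scale_background(m, noisy)
  expect_gt(fn$chi2_reduced, 0.7)
  expect_lt(fn$chi2_reduced, 1.3)

  wrong <- sym_curves()[[4]]  # unwrap (15,15) model vs (0,0) data
  fw <- fit_scale_background(wrong, noisy)
  expect_gt(fw$chi2_reduced, fn$chi2_reduced)

  expect_error(fit_scale_background(m, exact, q_window = c(0.31, 0.35)),
               "fewer than 3")
})

test_that("unwrap scan ranks the generating model first on noiseless data", {
  grid <- grid16()
  curves <- grid16_curves()
  for (i in seq_along(grid)) {
    sc <- unwrap_scan(curves[[i]], grid, builder177(), model_curves = curves)
    expect_equal(c(sc$n_left[1], sc$n_right[1]),
                 c(grid[[i]]$n_left, grid[[i]]$n_right))
  }
})

test_that("unwrap scan recovers noisy data and handles a one-element grid", {
  grid <- sym_unwraps()
  curves <- sym_curves()
  dat <- noisy_from(curves[[3]], seed = 314)  # truth = (10,10)
  sc <- unwrap_scan(dat, grid, builder177(), model_curves = curves)
  expect_equal(c(sc$n_left[1], sc$n_right[1]), c(10, 10))
  expect_gt(sc$chi2_reduced[2] - sc$chi2_reduced[1], 0)

  one <- unwrap_scan(dat, list(unwrap_spec(5, 5)), builder177(),
                     model_curves = curves[2])
  expect_equal(nrow(one), 1L)
  expect_equal(one$total_unwrapped, 10)
})
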