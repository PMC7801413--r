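test_that("charge ledgers follow the -2(N-1) DNA convention and add up", {
  nuc <- charge_ledger(177)
  expect_equal(nuc$z_dna, -352)
  expect_equal(nuc$z_net, -206)

  chr <- charge_ledger(177, with_h1 = TRUE)
  expect_equal(chr$z_net, -154)

  ncp <- charge_ledger(147)
  expect_equal(ncp$z_dna, -292)
  expect_equal(ncp$z_net, -146)

  # ledger additivity: chromatosome minus nucleosome equals z_H1 exactly
  for (bp in c(147, 160, 177, 197, 211)) {
    a <- charge_ledger(bp); b <- charge_ledger(bp, with_h1 = TRUE)
    expect_identical(b$z_net - a$z_net, 52)
  }
})

test_that("charge reduction and Rg-implied volume arithmetic", {
  a <- charge_ledger(177); b <- charge_ledger(177, with_h1 = TRUE)
  expect_equal(charge_reduction_percent(a, b), 100 * 52 / 206, tolerance = 1e-12)
  expect_equal(round(charge_reduction_percent(a, b)), 25)
  expect_equal(charge_reduction_percent(a, a), 0)

  # direct synthetic ledgers for the -100 vs -50 arithmetic case
  l100 <- structure(list(z_net = -100), class = "charge_ledger")
  l50 <- structure(list(z_net = -50), class = "charge_ledger")
  expect_equal(charge_reduction_percent(l100, l50), 50)
  expect_error(charge_reduction_percent(l100,
                                        structure(list(z_net = 10),
                                                  class = "charge_ledger")),
               "negative")

  expect_equal(volume_increase_percent(47.6, 49.4),
               100 * ((49.4 / 47.6)^3 - 1), tolerance = 1e-12)
  expect_equal(round(volume_increase_percent(47.6, 49.4)), 12)
})

test_that("branch splitting handles minima, plateaus and monotone curves", {
  conc <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  v <- titration_curve(conc, c(1, 0.9, 0.6, 0.3, 0.05, 0.3, 0.7, 1))
  br <- split_branches(v)
  expect_equal(br$split_at, 10)
  expect_equal(max(br$precipitation$concentration), 10)
  expect_equal(min(br$resolubilisation$concentration), 10)
  expect_false(br$resolubilisation_missing)

  conc2 <- c(0.5, 1, 2, 4, 8, 12, 19.5, 27, 35, 50, 100, 200)
  y2 <- c(1, 0.9, 0.5, 0, 0, 0, 0, 0, 0, 0.4, 0.8, 1)
  br2 <- split_branches(titration_curve(conc2, y2))
  expect_equal(br2$split_at, 19.5)

  mono <- titration_curve(conc, c(1, 0.95, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05))
  br3 <- split_branches(mono)
  expect_true(br3$resolubilisation_missing)
  expect_equal(nrow(br3$resolubilisation), 0L)
})

test_that("Boltzmann fits are exact noiseless and flag degeneracy", {
  x <- seq(-1.3, 2.7, length.out = 25)
  y <- 0.05 + (1.0 - 0.05) / (1 + exp((x - 0.6) / 0.3))
  f <- fit_boltzmann(10^x, y)
  expect_equal(f$a1, 1.0, tolerance = 1e-6)
  expect_equal(f$a2, 0.05, tolerance = 1e-6)
  expect_equal(f$x0, 0.6, tolerance = 1e-6)
  expect_equal(abs(f$dx), 0.3, tolerance = 1e-6)
  expect_equal(f$ec50, 10^0.6, tolerance = 1e-6)

  flatfit <- fit_boltzmann(10^x, rep(0.5, 25))
  expect_true(flatfit$degenerate)

  # rising branch (resolubilisation-like) fits equally well
  yr <- 1 / (1 + exp(-(x - 1.5) / 0.2))
  fr <- fit_boltzmann(10^x, yr)
  expect_equal(fr$ec50, 10^1.5, tolerance = 1e-6)
})

test_that("EC50 estimation is accurate at realistic noise", {
  # single-transition branches, sigma 0.02, n = 25, 200 seeds
  errs <- vapply(0:199, function(s) {
    x <- seq(log10(0.2), log10(150), length.out = 25)
    y <- 1 / (1 + exp((x - log10(5)) / 0.25))
    yn <- chromosaxs:::with_seed(s, y + stats::rnorm(25, 0, 0.02))
    f <- fit_boltzmann(10^x, pmin(pmax(yn, 0), 1.2))
    abs(f$ec50 / 5 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
  expect_lt(unname(stats::quantile(errs, 0.95)), 0.08)
})

test_that("full titration analysis recovers both transitions", {
  tc <- simulate_titration(noise = noise_spec(sigma0 = 0.02, seed = 7))
  res <- analyze_titration(tc)
  expect_equal(res$ec50_precipitation, 3.0, tolerance = 0.05)
  expect_equal(res$ec50_resolubilisation, 34.2, tolerance = 0.05)

  # precipitation-only curve: resolubilisation absent
  conc <- 10^seq(-1, 2, length.out = 12)
  x <- log10(conc)
  mono <- titration_curve(conc, 1 / (1 + exp((x - 0.5) / 0.3)))
  resm <- analyze_titration(mono)
  expect_true(is.na(resm$ec50_resolubilisation))

  # chromatosome-like conditions: complete aggregation spanning [5, 30] mM
  tc2 <- simulate_titration(0.6, 51.2, dx_p = 0.17, dx_r = 0.05,
                            noise = noise_spec(sigma0 = 0.02, seed = 3))
  res2 <- analyze_titration(tc2)
  expect_lte(res2$full_aggregation_window[1], 5)
  expect_gte(res2$full_aggregation_window[2], 30)
})

test_that("lower net charge shifts precipitation to lower EC50", {
  # charge-coupled synthetic rule: generating EC50 proportional to |z_net|
  zs <- c(206, 154, 100)
  ec50s <- vapply(seq_along(zs), function(i) {
    ec_gen <- 3.0 * zs[i] / 206
    tc <- simulate_titration(ec_gen, 60, noise = noise_spec(sigma0 = 0.02, seed = 40 + i))
    analyze_titration(tc)$ec50_precipitation
  }, numeric(1))
  expect_true(all(diff(ec50s) < 0))
})
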