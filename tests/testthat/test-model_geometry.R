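test_that("straight duplexes have collinear bp spacing and rod-like Rg", {
  rod <- make_straight_duplex(15)
  expect_equal(max(dist(rod$positions)), 14 * 3.4, tolerance = 1e-12)
  expect_true(all(rod$labels == "dna_linker"))

  single <- make_straight_duplex(1, origin = c(1, 2, 3))
  expect_equal(nrow(single$positions), 1L)
  expect_equal(as.numeric(single$positions), c(1, 2, 3))

  expect_error(make_straight_duplex(0), "positive integer")
  expect_error(make_straight_duplex(5, direction = c(0, 0, 2)), "unit")

  # discrete rod: Rg = rise * sqrt((N^2 - 1)/12); the continuous closed
  # form L/sqrt(12) agrees to well under 1%
  rod177 <- make_straight_duplex(177)
  pts <- bead_model(rod177$positions, 1, 0, "dna_linker")
  expect_equal(rg_of_model(pts), 3.4 * sqrt((177^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(rg_of_model(pts), (176 * 3.4) / sqrt(12), tolerance = 0.01)
})

test_that("wrapped DNA sits on the superhelix with correct bookkeeping", {
  geom <- geometry_params()
  core_only <- build_nucleosome(147)
  dna <- core_only$positions[core_only$labels == "dna_core", , drop = FALSE]
  expect_equal(nrow(dna), 147L)
  radial <- sqrt(rowSums(dna[, 1:2]^2))
  expect_true(all(abs(radial - geom$superhelix_radius) < 1e-6))

  ncp <- ncp177()
  expect_equal(sum(ncp$labels %in% c("dna_core", "dna_linker", "dna_unwrapped")),
               177L)
  expect_equal(sum(ncp$labels == "dna_linker"), 30L)

  # unwrapping 10 bp per side leaves 127 wrapped bp spanning
  # 1.65 * 127/147 turns (one arc segment per bp)
  u <- build_nucleosome(177, 15, 15, unwrap_spec(10, 10))
  expect_equal(sum(u$labels == "dna_core"), 127L)
  expect_equal(sum(u$labels == "dna_unwrapped"), 20L)
  dphi <- 2 * pi * geom$total_turns_147 / 147
  expect_equal(127 * dphi / (2 * pi), 1.65 * 127 / 147, tolerance = 1e-12)

  expect_error(build_nucleosome(177, 10, 15), "must equal")
  expect_error(unwrap_spec(80, 80), "supported range")
})

test_that("Rg grows with linker length and Dmax with unwrapping", {
  rgs <- vapply(c(0, 5, 10, 15), function(L) {
    rg_of_model(build_nucleosome(147 + 2 * L, L, L))
  }, numeric(1))
  expect_true(all(diff(rgs) > 0))

  dmaxs <- vapply(c(0, 5, 10, 15, 20), function(u) {
    dmax_of_model(build_nucleosome(177, 15, 15, unwrap_spec(u, u)))
  }, numeric(1))
  expect_true(all(diff(dmaxs) >= 0))
})

test_that("swapping left/right unwrapping yields a congruent model", {
  a <- build_nucleosome(177, 15, 15, unwrap_spec(3, 7))
  b <- build_nucleosome(177, 15, 15, unwrap_spec(7, 3))
  da <- sort(as.vector(dist(a$positions)))
  db <- sort(as.vector(dist(b$positions)))
  expect_equal(da, db, tolerance = 1e-6)
})

test_that("Rg and Dmax match closed forms and a brute-force oracle", {
  one <- bead_model(matrix(0, 1, 3), 1, 7, "histone_core")
  expect_equal(rg_of_model(one), sqrt(3 / 5) * 7, tolerance = 1e-12)

  two <- bead_model(rbind(c(0, 0, 0), c(0, 0, 10)), 1, 0, "dna_core")
  expect_equal(rg_of_model(two), 5, tolerance = 1e-12)
  expect_equal(dmax_of_model(two), 10, tolerance = 1e-12)
  expect_error(dmax_of_model(one), "two beads")

  th <- 2 * pi * seq_len(1000) / 1000
  ring <- bead_model(cbind(41.9 * cos(th), 41.9 * sin(th), 0), 1, 0, "dna_core")
  expect_equal(rg_of_model(ring), 41.9, tolerance = 1e-9)

  cloud <- random_cloud(50, seed = 11, radius = 0)
  cloud$radii <- chromosaxs:::with_seed(12, stats::runif(50, 0, 5))
  brute <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    brute <- max(brute, sqrt(sum((cloud$positions[i, ] - cloud$positions[j, ])^2)) +
                   cloud$radii[i] + cloud$radii[j])
  }
  expect_equal(dmax_of_model(cloud), brute, tolerance = 1e-12)
})

test_that("linker histone placement is on-dyad, tilted on request, additive", {
  ncp <- ncp177()
  n0 <- nrow(ncp$positions)

  sym <- add_linker_histone(ncp, h1_placement(mode = "on_dyad_symmetric"))
  h1 <- sym$positions[sym$labels == "h1_globular", , drop = FALSE]
  cen <- colMeans(h1)
  expect_lt(abs(cen[1]), 1e-6)
  expect_lt(abs(cen[3]), 1e-6)
  # pre-existing beads preserved bit-exactly
  expect_identical(sym$positions[seq_len(n0), ], ncp$positions)
  expect_identical(sym$weights[seq_len(n0)], ncp$weights)

  tl <- add_linker_histone(ncp, h1_placement(tilt_arm = "left"))
  h1t <- colMeans(tl$positions[tl$labels == "h1_globular", , drop = FALSE])
  arm_l <- colMeans(ncp$positions[ncp$arm == "left" & !is.na(ncp$arm), , drop = FALSE])
  arm_r <- colMeans(ncp$positions[ncp$arm == "right" & !is.na(ncp$arm), , drop = FALSE])
  expect_lt(sum((h1t - arm_l)^2), sum((h1t - arm_r)^2))

  # cluster size is deterministic for a given geometry
  expect_equal(nrow(tl$positions) - n0,
               sum(tl$labels == "h1_globular"))
  expect_gt(sum(tl$labels == "h1_globular"), 50)

  expect_error(add_linker_histone(build_nucleosome(147), h1_placement()),
               "both arms")

  ctd <- add_linker_histone(ncp, h1_placement(include_ctd = TRUE, ctd_beads = 5))
  expect_equal(sum(ctd$labels == "h1_ctd"), 5L)
})
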