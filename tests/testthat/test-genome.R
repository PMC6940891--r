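test_that("genome intervals partition 6 Gbp in the stated class fractions", {
  set.seed(51)
  g <- build_genome()
  v <- g$voxels
  expect_equal(v$bp_start[1], 0)
  expect_equal(v$bp_end[nrow(v)], 6e9, tolerance = 1)
  expect_equal(v$bp_start[-1], v$bp_end[-nrow(v)], tolerance = 1e-6)
  eu_bp <- sum(v$bp_end[v$class == "euchromatin"] -
                 v$bp_start[v$class == "euchromatin"])
  expect_lt(abs(eu_bp / 6e9 - 0.52), 0.02 * 0.52 + 0.02)
  # density ratio approximately the configured compaction
  dens <- g$density_bp_um3
  expect_lt(abs(dens["heterochromatin"] / dens["euchromatin"] - 2), 0.2)
})

test_that("degenerate all-euchromatin genome is uniform", {
  set.seed(52)
  g <- build_genome(eu_fraction = 1, het_fraction = 0)
  expect_true(all(g$voxels$class == "euchromatin"))
  d <- g$voxels$bp_end - g$voxels$bp_start
  expect_lt(diff(range(d)), 1e-6)
})

test_that("hit assignment respects probabilities, subvolumes and locality", {
  set.seed(53)
  g <- build_genome()
  n <- 2e4
  # uniform sites inside the nucleus
  pts <- matrix(nrow = 0, ncol = 3)
  while (nrow(pts) < n) {
    cand <- cbind(stats::runif(n, -9.5, 9.5), stats::runif(n, -5.1, 5.1),
                  stats::runif(n, -1, 1))
    ok <- (cand[, 1] / 9.5)^2 + (cand[, 2] / 5.1)^2 <= 1
    pts <- rbind(pts, cand[ok, ])
  }
  pts <- pts[1:n, ]
  sites <- data.frame(x_nm = pts[, 1] * 1000, y_nm = pts[, 2] * 1000,
                      z_nm = pts[, 3] * 1000, energy_eV = 30,
                      kind = "ionization", track_id = 1L)
  hits <- assign_hits(sites, g, force_hit = TRUE)
  # sites hugging the elliptical boundary can fall outside the voxel
  # lattice; everything else must hit under force_hit
  expect_gt(nrow(hits), 0.98 * n)
  # forced hits with a pure-deoxyribose genome
  g1 <- build_genome(subvolume_fractions = c(deoxyribose = 1, phosphate = 0,
                                             hydration_shell = 0, base = 0,
                                             histone = 0))
  h1 <- assign_hits(sites[1:500, ], g1, force_hit = TRUE)
  expect_true(all(h1$subvolume == "deoxyribose"))
  # zero hit probability yields no hits
  g0 <- build_genome(hit_prob_eu = 0)
  expect_identical(nrow(assign_hits(sites, g0)), 0L)
  # class share of hits ~ bp share (volume x density weighting)
  set.seed(54)
  hits2 <- assign_hits(sites, g)
  p_eu <- mean(hits2$class == "euchromatin")
  se <- sqrt(0.52 * 0.48 / nrow(hits2))
  expect_lt(abs(p_eu - 0.52), 4 * se)
  # locality: two sites 2 nm apart map within one sub-cell's bp content
  near <- data.frame(x_nm = c(100, 102), y_nm = c(50, 50), z_nm = c(10, 10),
                     energy_eV = 30, kind = "ionization", track_id = 1L)
  set.seed(55)
  hn <- assign_hits(near, g, force_hit = TRUE)
  expect_lt(abs(diff(hn$bp_index)), 2 * 500000 / 15625 + 1)
})

test_that("downstream DSB counts are invariant under genomic translation", {
  set.seed(56)
  g <- build_genome()
  gs <- genome_shift(g, 1.7e8)
  sites <- data.frame(
    x_nm = rep(stats::runif(40, -5000, 5000), each = 4) +
      stats::rnorm(160, 0, 3),
    y_nm = rep(stats::runif(40, -3000, 3000), each = 4) +
      stats::rnorm(160, 0, 3),
    z_nm = rep(stats::runif(40, -800, 800), each = 4) +
      stats::rnorm(160, 0, 3),
    energy_eV = 30, kind = "ionization", track_id = 1L)
  set.seed(57); h1 <- assign_hits(sites, g, force_hit = TRUE)
  set.seed(57); h2 <- assign_hits(sites, gs, force_hit = TRUE)
  b1 <- score_direct_breaks(h1)
  b2 <- score_direct_breaks(h2)
  c1 <- cluster_dsb(b1); c2 <- cluster_dsb(b2)
  expect_identical(nrow(c1$dsb), nrow(c2$dsb))
  expect_identical(sort(c1$dsb$n_breaks), sort(c2$dsb$n_breaks))
})
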