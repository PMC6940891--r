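test_that("every completed track conserves energy exactly", {
  set.seed(21)
  for (E in c(0.5, 5, 50)) {
    tr <- transport_electron(E)
    expect_equal(sum(tr$sites$energy_eV) + tr$escape_eV, E * 1000,
                 tolerance = 1e-9)
    expect_identical(tr$escape_eV, 0)          # unbounded medium
    expect_true(all(tr$sites$energy_eV > 0))
  }
})

test_that("bounded transport books escaping energy", {
  set.seed(22)
  tr <- transport_electron(30, bbox_nm = c(-50, 50, -50, 50, -50, 50))
  expect_gt(tr$escape_eV, 0)
  expect_equal(sum(tr$sites$energy_eV) + tr$escape_eV, 30000,
               tolerance = 1e-9)
})

test_that("100 eV electrons travel nanometers", {
  set.seed(23)
  d <- replicate(400, {
    t <- transport_electron(0.1)
    max(sqrt(t$sites$x_nm^2 + t$sites$y_nm^2 + t$sites$z_nm^2))
  })
  # paper-scale range: a few nm
  expect_gt(mean(d), 1)
  expect_lt(mean(d), 12)
  expect_lt(stats::median(d), 10)
})

test_that("primary path length agrees with CSDA quadrature within 20%", {
  set.seed(24)
  for (E in c(2, 10, 50)) {
    pl <- mean(replicate(150, transport_electron(E)$primary_path_nm))
    expect_lt(abs(pl - csda_range(E)) / csda_range(E), 0.20)
  }
})

test_that("tracks are reproducible under a fixed seed", {
  set.seed(25); a <- transport_electron(10)
  set.seed(25); b <- transport_electron(10)
  expect_identical(a$sites, b$sites)
})

test_that("synthetic clouds have the advertised moments", {
  set.seed(26)
  tracks <- synthesize_deposition_cloud(5000, mean_sites = 7,
                                        energy_eV = 50)
  ns <- vapply(tracks, function(t) nrow(t$sites), numeric(1))
  expect_lt(abs(mean(ns) - 7), 3 * sqrt(7 / 5000))
  # mean energy per track = E[N] E[eps], by independent summation
  etot <- vapply(tracks, function(t) sum(t$sites$energy_eV), numeric(1))
  se <- stats::sd(etot) / sqrt(length(etot))
  expect_lt(abs(mean(etot) - 7 * 50), 3 * se)
})

test_that("a single fixed deposit flows through unchanged", {
  set.seed(27)
  tr <- synthesize_deposition_cloud(1, mean_sites = 1, sites_dist = "fixed",
                                    energy_eV = 123)
  expect_identical(nrow(tr[[1]]$sites), 1L)
  expect_identical(tr[[1]]$sites$energy_eV, 123)
})
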