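test_that("nucleus phantoms have the stated volume and do not overlap", {
  set.seed(41)
  nuc <- place_nuclei(150, 1200, 1200, 5)
  expect_equal(nuc$volume_um3[1], pi * 9.5 * 5.1 * 2.0, tolerance = 1e-9)
  expect_equal(nuc$volume_um3[1], 304.4, tolerance = 1e-3)
  expect_true(all(nuc$cz_um == 2.5))   # 1.5 um clearance on both sides
  # brute-force O(N^2) overlap check on a 100-nucleus subsample
  sub <- nuc[1:100, ]
  for (i in 1:99) {
    j <- (i + 1):100
    lhs <- ((sub$cx_um[i] - sub$cx_um[j]) / (2 * 9.5))^2 +
           ((sub$cy_um[i] - sub$cy_um[j]) / (2 * 5.1))^2
    expect_true(all(lhs >= 1))
  }
  expect_silent(place_nuclei(1, 100, 100, 5))
  expect_error(place_nuclei(1e5, 500, 500, 5), "packing")
})

test_that("specific energy follows the unit-conversion arithmetic", {
  set.seed(42)
  nuc <- place_nuclei(5, 300, 300, 5)
  mk <- function(e) {
    structure(list(track_id = 1L, primary_keV = e / 1e3, escape_eV = 0,
                   sites = data.frame(x_nm = nuc$cx_um[1] * 1000,
                                      y_nm = nuc$cy_um[1] * 1000,
                                      z_nm = 2500, energy_eV = e,
                                      kind = "ionization")),
              class = "deposition_track")
  }
  pop <- score_specific_energy(list(mk(1000)), nuc)
  expect_equal(max(pop$z_Gy), 1000 * 1.602176634e-19 / (304.4e-15),
               tolerance = 1e-3)
  # additivity: two identical deposits exactly double z
  pop2 <- score_specific_energy(list(mk(1000), mk(1000)), nuc)
  expect_equal(max(pop2$z_Gy), 2 * max(pop$z_Gy), tolerance = 1e-12)
  # geometry miss leaves all z at zero
  miss <- mk(1000)
  miss$sites$x_nm <- -5e5
  expect_identical(score_specific_energy(list(miss), nuc)$z_Gy,
                   rep(0, 5))
})

test_that("f(z;D) recovers a known normal population", {
  set.seed(43)
  z <- stats::rnorm(1e4, 0.25, 0.02)
  f <- build_fzD(z, 0.25)
  expect_lt(abs(f$fit_mean - 0.25), 3 * 0.02 / sqrt(1e4))
  expect_lt(abs(f$fit_sigma - 0.02) / 0.02, 0.05)
  expect_equal(f$sigma_z_rel, f$fit_sigma / 0.25, tolerance = 1e-12)
  # histogram integrates to one
  w <- f$histogram$bin_high - f$histogram$bin_low
  expect_equal(sum(w * f$histogram$density), 1, tolerance = 1e-6)
  expect_error(build_fzD(rep(0.25, 200), 0.25), "degenerate")
})

test_that("compound-Poisson populations match the analytic spread", {
  set.seed(44)
  z1 <- 0.0018
  p <- compound_poisson_population(rep(z1, 50), 0.25, 20000)
  # constant z1 reduces to Poisson counting: sigma_rel = sqrt(z1/D)
  expect_equal(analytic_sigma_oracle(z1, z1^2, 0.25), sqrt(z1 / 0.25),
               tolerance = 1e-12)
  expect_lt(abs(p$sigma_z_rel / sqrt(z1 / 0.25) - 1), 0.05)
  # mean of f(z;D) equals D within 3 SE
  expect_lt(abs(p$mean_z - 0.25), 3 * p$sigma_z / sqrt(2e4))
  # doubling D halves sigma_rel^2 exactly in the oracle
  expect_equal(analytic_sigma_oracle(z1, z1^2, 0.5)^2,
               analytic_sigma_oracle(z1, z1^2, 0.25)^2 / 2,
               tolerance = 1e-12)
  expect_error(analytic_sigma_oracle(z1, z1^2, -1), "positive")
})

test_that("pair cumulation doubles dose, halves the population and scales the spread by 1/sqrt(2)", {
  set.seed(45)
  p <- compound_poisson_population(rep(0.002, 40), 0.25, 10000)
  p2 <- cumulate_pairs(p)
  expect_identical(length(p2$z_Gy), 5000L)
  expect_identical(p2$D_Gy, 0.5)
  expect_lt(abs(p2$mean_z - 0.5), 3 * p2$sigma_z / sqrt(5000))
  expect_lt(abs(p2$sigma_z_rel / (p$sigma_z_rel / sqrt(2)) - 1), 0.05)
  # three cumulation steps: 10^4 -> 1250 at 8x the dose
  p3 <- cumulate_pairs(cumulate_pairs(p2))
  expect_identical(length(p3$z_Gy), 1250L)
  expect_identical(p3$D_Gy, 2)
  expect_error(cumulate_pairs(compound_poisson_population(0.1, 1, 2),
                              min_separation_um = 1e9), "separation")
})

test_that("spread decreases with dose and respects the pair separation", {
  set.seed(46)
  sm <- sigma_zrel_vs_dose(stats::rexp(500, 1 / 0.002),
                           c(0.25, 0.5, 1, 2), 3000)
  cp <- sm[sm$method == "compound_poisson", ]
  expect_true(all(diff(cp$sigma_z_rel) < 0))
  pc <- sm[sm$method == "pair_cumulation", ]
  expect_true(all(diff(pc$sigma_z_rel) < 0))
})
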