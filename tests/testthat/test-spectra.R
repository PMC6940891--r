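test_that("filtered 40 kVp spectrum reproduces the stated beam quality", {
  s40 <- build_kvp_spectrum(40)
  # mean photon energy 25.6 keV (attenuation-data dependent, +/-10%)
  expect_lt(abs(s40$mean_energy - 25.6) / 25.6, 0.10)
  # aluminum HVL 0.852 mm (+/-15%)
  expect_lt(abs(compute_hvl(s40) - 0.852) / 0.852, 0.15)
  # normalization
  expect_equal(sum(s40$weight), 1, tolerance = 1e-9)
})

test_that("monoenergetic and unfiltered spectra follow closed forms", {
  mono <- photon_spectrum(80, 1)
  expect_identical(mono$mean_energy, 80)
  # HVL of a single line is ln(2)/mu exactly
  mu <- linear_attenuation("aluminum", 80)
  expect_equal(compute_hvl(mono), log(2) / mu, tolerance = 1e-5)
  # unfiltered Kramers mean by direct quadrature of (peak-E)/E
  s <- build_kvp_spectrum(40, inherent_mm_be = 0, added_mm_al = 0,
                          anode_equiv_mm_al = 0, grid_step = 0.25)
  e <- s$energy_keV
  w <- (40 - e) / e
  expect_equal(s$mean_energy, sum(e * w) / sum(w), tolerance = 1e-9)
})

test_that("two-line spectrum HVL matches a dense root scan", {
  s <- photon_spectrum(c(30, 60), c(0.5, 0.5))
  mu <- linear_attenuation("aluminum", c(30, 60))
  kw <- c(0.5, 0.5) * c(30, 60) * cross_section("air", c(30, 60), "muen")
  kw <- kw / sum(kw)
  tgrid <- seq(0, 10, by = 1e-4)
  trans <- vapply(tgrid, function(t) sum(kw * exp(-mu * t)), numeric(1))
  t_scan <- tgrid[which.min(abs(trans - 0.5))]
  expect_equal(compute_hvl(s), t_scan, tolerance = 1e-3)
})

test_that("beam hardening: filtration increases HVL", {
  s_unf <- build_kvp_spectrum(40, inherent_mm_be = 0, added_mm_al = 0,
                              anode_equiv_mm_al = 0)
  s_fil <- build_kvp_spectrum(40)
  expect_gt(compute_hvl(s_fil), compute_hvl(s_unf))
})

test_that("interaction partition matches the 40 kVp photoelectric share", {
  p40 <- partition_interactions(build_kvp_spectrum(40))
  expect_lt(abs(p40$p_photoelectric - 0.689), 0.05)
  expect_equal(p40$p_photoelectric + p40$p_compton + p40$p_pair, 1,
               tolerance = 1e-12)
  expect_identical(p40$p_pair, 0)
})

test_that("partition of a single line equals normalized table coefficients", {
  s <- photon_spectrum(100, 1)
  p <- partition_interactions(s)
  tau <- cross_section("water", 100, "photoelectric")
  sig <- cross_section("water", 100, "compton")
  expect_equal(p$p_photoelectric, tau / (tau + sig), tolerance = 1e-12)
  expect_equal(p$p_compton, sig / (tau + sig), tolerance = 1e-12)
})

test_that("photoelectric share decreases 40 kVp -> 220 kVp -> 4 MV", {
  pe <- vapply(list(build_kvp_spectrum(40), build_kvp_spectrum(220),
                    mv4_spectrum()),
               function(s) partition_interactions(s)$p_photoelectric,
               numeric(1))
  expect_true(all(diff(pe) < 0))
  # pair production appears only above threshold
  expect_gt(partition_interactions(mv4_spectrum())$p_pair, 0)
})

test_that("4 MV spectrum has the tabulated 1.3 MeV mean", {
  expect_equal(mv4_spectrum()$mean_energy, 1300, tolerance = 1e-6)
})

test_that("spectrum files round-trip", {
  s <- build_kvp_spectrum(40)
  p <- tempfile(fileext = ".tsv")
  write_spectrum_file(s, p)
  s2 <- read_spectrum_file(p)
  expect_equal(s2$energy_keV, s$energy_keV, tolerance = 1e-5)
  expect_equal(s2$mean_energy, s$mean_energy, tolerance = 1e-5)
})
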