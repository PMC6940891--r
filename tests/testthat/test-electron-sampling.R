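test_that("Compton recoil energies respect the Compton edge", {
  set.seed(11)
  T <- sample_compton_electron(1000, 2e5)
  tmax <- 2 * 1000^2 / (511 + 2 * 1000)
  expect_true(all(T <= tmax + 1e-9))
  expect_true(all(T >= 0))
  # low-energy limit: recoil vanishes
  expect_lt(max(sample_compton_electron(0.01, 1e4)), 0.01 * 0.01 / 2)
})

test_that("Compton sampler matches the Klein-Nishina quadrature density", {
  set.seed(12)
  E <- 500
  T <- sample_compton_electron(E, 1e6)
  d <- klein_nishina_recoil_density(E)
  dT <- diff(d$T_keV)
  mid_dens <- (d$density[-1] + d$density[-nrow(d)]) / 2
  w <- dT * mid_dens
  cdf <- cumsum(w) / sum(w)
  Tmid <- (d$T_keV[-1] + d$T_keV[-nrow(d)]) / 2
  # mean within 3 SE of the quadrature mean
  mq <- sum(Tmid * w) / sum(w)
  vq <- sum(Tmid^2 * w) / sum(w) - mq^2
  expect_lt(abs(mean(T) - mq), 3 * sqrt(vq / length(T)))
  # Kolmogorov distance of the empirical CDF below 0.01
  emp <- stats::ecdf(T)
  expect_lt(max(abs(emp(Tmid) - cdf)), 0.01)
})

test_that("photoelectron energy is photon energy minus binding", {
  r <- sample_photoelectron(30, shell_binding_eV = 540)
  expect_equal(r$electron_keV, 29.46)
  expect_equal(sample_photoelectron(12.3, 0)$electron_keV, 12.3)
  expect_error(sample_photoelectron(0.0001), "binding")
})

test_that("mean photoelectron energy follows the shell-weighted arithmetic", {
  set.seed(13)
  s40 <- build_kvp_spectrum(40)
  E <- sample_photon_energy(s40, 1e5)
  r <- sample_photoelectron(E)
  sh <- water_shell_table()
  expected <- mean(E) - sum(sh$binding_eV * sh$weight) / 1000
  se <- stats::sd(r$electron_keV) / sqrt(length(E))
  expect_lt(abs(mean(r$electron_keV) - expected), 4 * se)
})
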