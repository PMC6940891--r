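test_that("40 kVp phase space is dominated by electrons created in the layer", {
  set.seed(31)
  ps <- generate_phase_space(build_kvp_spectrum(40), sarrp_stack(), 1.5e6)
  expect_gt(nrow(ps), 200)
  frac <- mean(ps$origin_flag == "created_inside")
  expect_lt(abs(frac - 0.85), 0.05)
  # direction cosines are unit vectors
  expect_equal(max(abs(ps$ux^2 + ps$uy^2 + ps$uz^2 - 1)), 0,
               tolerance = 1e-9)
  expect_true(all(ps$z_um >= 0 & ps$z_um <= 5))
})

test_that("a soft photon line in a bare cell layer yields photo-lines", {
  # single 5 keV line, no upstream material: essentially every
  # interaction is photoelectric inside the layer; record energies are
  # photon minus a shell binding, or the Auger energy
  set.seed(32)
  stack <- layer_stack("water", 0.005, TRUE)
  ps <- generate_phase_space(photon_spectrum(5, 1), stack, 5e6)
  expect_gt(nrow(ps), 20)
  expect_true(all(ps$origin_flag == "created_inside"))
  sh <- water_shell_table()
  lines <- c(5 - sh$binding_eV / 1000, 0.5)
  ok <- vapply(ps$E_keV, function(e) any(abs(e - lines) < 1e-6), logical(1))
  # a sub-percent Compton admixture remains at 5 keV; its recoils stay
  # below the Compton edge
  expect_gt(mean(ok), 0.99)
  tmax <- 2 * 5^2 / (511 + 2 * 5)
  expect_true(all(ps$E_keV[!ok] <= tmax + 1e-9))
})

test_that("phase space is byte-identical under a fixed seed", {
  s40 <- build_kvp_spectrum(40)
  a <- generate_phase_space(s40, sarrp_stack(), 2e5, seed = 99)
  b <- generate_phase_space(s40, sarrp_stack(), 2e5, seed = 99)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_phase_space(a, f1); write_phase_space(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("phase-space files round-trip through the documented format", {
  set.seed(33)
  ps <- generate_phase_space(build_kvp_spectrum(40), sarrp_stack(), 3e5)
  p <- tempfile(fileext = ".tsv")
  write_phase_space(ps, p)
  expect_match(readLines(p, n = 1), "microdsb-phase-space")
  ps2 <- read_phase_space(p)
  expect_equal(ps2$E_keV, ps$E_keV, tolerance = 1e-6)
  expect_identical(ps2$origin_flag, ps$origin_flag)
  expect_error(suppressWarnings(read_phase_space(tempfile())))
})

test_that("4 MV electrons enter from the boundary with a depleted sub-cut region", {
  set.seed(34)
  ps <- generate_phase_space(mv4_spectrum(), linac_stack(), 3e5)
  expect_gt(nrow(ps), 500)
  entered <- ps[ps$origin_flag == "entered_boundary", ]
  inside <- ps[ps$origin_flag == "created_inside", ]
  expect_gt(nrow(entered) / nrow(ps), 0.9)
  # boundary-entering electrons never fall below the production cut
  expect_true(all(entered$E_keV >= 0.1))
  # the mean-energy ordering across beams
  set.seed(35)
  ps40 <- generate_phase_space(build_kvp_spectrum(40), sarrp_stack(), 5e5)
  ps220 <- generate_phase_space(build_kvp_spectrum(220), sarrp_stack(), 5e5)
  expect_lt(mean(ps40$E_keV), mean(ps220$E_keV))
  expect_lt(mean(ps220$E_keV) * 5, mean(ps$E_keV))
})
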