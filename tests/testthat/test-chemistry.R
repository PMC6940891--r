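test_that("the reaction network matches the printed tables", {
  rt <- reaction_table()
  expect_identical(nrow(rt), 10L)
  expect_equal(rt$k_1e10[rt$a == "OH" & rt$b == "OH"], 0.44)
  expect_equal(rt$k_1e10[rt$a == "H3Op" & rt$b == "OHm"], 14.3)
  dt <- dna_reaction_table()
  expect_identical(nrow(dt), 13L + 1L)  # 13 species-DNA rows + deoxyribose/H
  # the source table has no guanine + H entry
  expect_false(any(dt$target == "guanine" & dt$species == "H"))
  expect_equal(dt$k_1e9[dt$target == "deoxyribose" & dt$species == "OH"], 1.8)
  st <- chem_species_table()
  expect_identical(nrow(st), 7L)
})

test_that("species creation follows the branching channels", {
  cfg <- chemistry_config()
  expect_identical(nrow(initialize_species(
    data.frame(x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
               kind = character(0)), cfg)), 0L)
  set.seed(61)
  ion <- data.frame(x_nm = 1:50, y_nm = 0, z_nm = 0, kind = "ionization")
  sp <- initialize_species(ion, cfg)
  st <- chem_species_table()
  cnt <- table(st$name[sp$type + 1])
  expect_identical(as.integer(cnt[c("OH", "H3Op", "eaq")]), rep(50L, 3))
  expect_identical(nrow(sp), 150L)
  # mixed branching: excitation dissociates with the configured fraction
  set.seed(62)
  exc <- data.frame(x_nm = 1:20000, y_nm = 0, z_nm = 0, kind = "excitation")
  spe <- initialize_species(exc, cfg)
  n_oh <- sum(st$name[spe$type + 1] == "OH")
  p <- cfg$p_excitation_dissociation
  expect_lt(abs(n_oh - 20000 * p), 3 * sqrt(20000 * p * (1 - p)))
  expect_identical(n_oh, sum(st$name[spe$type + 1] == "H"))
})

test_that("reaction events conserve the bookkeeping of the network", {
  # two OH radicals in contact react to one H2O2
  set.seed(63)
  sp <- data.frame(x_nm = c(0, 0.05), y_nm = 0, z_nm = 0, type = 1L)
  res <- run_chemistry(sp, genome = NULL, chemistry_config(end_time_ns = 1))
  expect_identical(nrow(res$reactions), 1L)
  expect_identical(res$reactions$a, "OH")
  expect_identical(res$reactions$b, "OH")
  expect_identical(res$n_survivors, 1L)   # the H2O2 product
  # no species, no events
  res0 <- run_chemistry(sp[0, ], NULL, chemistry_config())
  expect_identical(nrow(res0$encounters), 0L)
  expect_identical(nrow(res0$reactions), 0L)
})

test_that("well-mixed OH self-reaction follows second-order kinetics within 5%", {
  set.seed(64)
  k <- 0.44e10; c0 <- 0.01; t_ns <- 5
  closed <- 1 / (1 / c0 + 2 * k * t_ns * 1e-9)
  sim <- mean(replicate(3, well_mixed_box("OH", n = 250, conc_M = c0,
                                          time_ns = t_ns)$conc_M))
  expect_lt(abs(sim - closed) / closed, 0.05)
})

test_that("non-reacting species diffuse with MSD = 6 D t within 2%", {
  set.seed(65)
  st <- chem_species_table()
  n <- 10000
  mat <- microdsb:::reaction_matrices()
  zero <- matrix(0, 7, 3)
  res <- microdsb:::cpp_chemistry_spur(
    matrix(0, n, 3), rep(2L, n), mat$D, mat$R, mat$p1, mat$p2, mat$p3,
    zero, zero, zero, integer(0), c(0L, 0L, 0L), c(0, 0, 0), 1,
    integer(0), 2, 1e-3, 0.05, 0)
  msd <- mean(rowSums(res$survivors[, 1:3]^2))
  D <- st$D_nm2_ns[st$name == "H2"]
  expect_lt(abs(msd - 6 * D * 2) / (6 * D * 2), 0.02)
})

test_that("OH-deoxyribose encounters accumulate monotonically in time", {
  set.seed(66)
  g <- build_genome()
  sites <- data.frame(x_nm = stats::rnorm(60, 0, 20),
                      y_nm = stats::rnorm(60, 0, 20),
                      z_nm = stats::rnorm(60, 0, 20),
                      energy_eV = 30, kind = "ionization")
  cfg <- chemistry_config(end_time_ns = 10)
  sp <- initialize_species(sites, cfg)
  res <- run_chemistry(sp, g, cfg)
  enc <- res$encounters
  n25 <- sum(enc$time_ns <= 2.5 & enc$species == "OH" &
               enc$target == "deoxyribose")
  n10 <- sum(enc$species == "OH" & enc$target == "deoxyribose")
  expect_gte(n10, n25)
  expect_true(all(enc$time_ns <= 10 + 1e-9))
})

test_that("indirect breaks occur in 40% of OH-deoxyribose encounters", {
  set.seed(67)
  n <- 1e5
  enc <- data.frame(time_ns = stats::runif(n, 0, 2.5), species = "OH",
                    target = "deoxyribose", x_nm = 0, y_nm = 0, z_nm = 0,
                    voxel_id = 1L, class = "euchromatin",
                    bp_index = seq_len(n) * 100, strand = 0L,
                    break_u = stats::runif(n), track_id = 1L)
  br <- score_indirect_breaks(enc, p_break = 0.4)
  expect_lt(abs(nrow(br) - 0.4 * n), 3 * sqrt(n * 0.4 * 0.6))
  expect_identical(nrow(score_indirect_breaks(enc, p_break = 0)), 0L)
  expect_identical(nrow(score_indirect_breaks(enc, p_break = 1)), as.integer(n))
  expect_true(all(br$origin == "indirect"))
})
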