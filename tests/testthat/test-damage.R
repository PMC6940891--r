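mk_hits <- function(bp, strand, sub, eV) {
  data.frame(track_id = 1L, bp_index = bp, strand = strand,
             subvolume = sub, energy_eV = eV, class = "euchromatin",
             voxel_id = 1L)
}

mk_breaks <- function(bp, strand) {
  data.frame(bp_index = bp, strand = strand, origin = "direct",
             track_id = 1L, class = "euchromatin")
}

test_that("direct-break threshold is strict and cumulative per nucleotide", {
  # a single 17.6 eV deoxyribose hit breaks; 17.5 eV does not
  expect_identical(nrow(score_direct_breaks(
    mk_hits(100, 0, "deoxyribose", 17.6))), 1L)
  expect_identical(nrow(score_direct_breaks(
    mk_hits(100, 0, "deoxyribose", 17.5))), 0L)
  # 10 eV + 8 eV on phosphate + hydration shell of one nucleotide cumulate
  h <- mk_hits(c(100, 100), c(0, 0), c("phosphate", "hydration_shell"),
               c(10, 8))
  expect_identical(nrow(score_direct_breaks(h)), 1L)
  # base and histone hits never contribute
  h2 <- mk_hits(c(100, 100), c(0, 0), c("base", "histone"), c(50, 50))
  expect_identical(nrow(score_direct_breaks(h2)), 0L)
  # different strands do not cumulate
  h3 <- mk_hits(c(100, 100), c(0, 1), c("deoxyribose", "deoxyribose"),
                c(10, 10))
  expect_identical(nrow(score_direct_breaks(h3)), 0L)
  expect_error(score_direct_breaks(mk_hits(1, 0, "deoxyribose", -2)),
               "negative")
})

test_that("duplicate breaks at one site merge", {
  a <- mk_breaks(100, 0)
  b <- mk_breaks(c(100, 105), c(0, 1)); b$origin <- "indirect"
  m <- merge_breaks(a, b)
  expect_identical(nrow(m), 2L)
  expect_identical(m$origin[m$bp_index == 100], "direct")
})

test_that("DSB definition: two breaks under 10 bp on opposite strands", {
  r <- cluster_dsb(mk_breaks(c(100, 105), c(0, 1)))
  expect_identical(nrow(r$dsb), 1L)
  expect_identical(r$dsb$complexity, "simple")
  # separation of exactly 10 bp is not a DSB
  r2 <- cluster_dsb(mk_breaks(c(100, 110), c(0, 1)))
  expect_identical(nrow(r2$dsb), 0L)
  expect_identical(r2$n_ssb, 2L)
  # transitive merge: 100/s0, 104/s1, 109/s0 forms one complex DSB
  r3 <- cluster_dsb(mk_breaks(c(100, 104, 109), c(0, 1, 0)))
  expect_identical(nrow(r3$dsb), 1L)
  expect_identical(r3$dsb$n_breaks, 3L)
  expect_identical(r3$dsb$complexity, "complex")
  # same-strand clusters remain SSBs
  r4 <- cluster_dsb(mk_breaks(c(100, 104, 108), c(0, 0, 0)))
  expect_identical(nrow(r4$dsb), 0L)
  expect_identical(r4$n_ssb, 3L)
})

test_that("density scan equals brute-force transitive closure on 1000 instances", {
  set.seed(71)
  for (i in 1:1000) {
    br <- random_breaks(sample(2:50, 1))
    fast <- cluster_dsb(br)
    slow <- bf_cluster(br)
    expect_identical(sort(fast$dsb$n_breaks), as.integer(slow$sizes))
    # identical partitions, not just counts
    bf_members <- lapply(stats::na.omit(unique(slow$assignment)),
                         function(g) br[which(slow$assignment == g), ])
    expect_identical(partition_signature(br, fast$members),
                     partition_signature(br, bf_members))
  }
})

test_that("cluster partition is invariant under input order", {
  set.seed(72)
  for (i in 1:50) {
    br <- random_breaks(30)
    p1 <- cluster_dsb(br)
    p2 <- cluster_dsb(br[sample(nrow(br)), , drop = FALSE])
    expect_identical(partition_signature(br, p1$members),
                     partition_signature(br, p2$members))
  }
})

test_that("adding a break can upgrade but never dissolve a DSB", {
  set.seed(73)
  for (i in 1:100) {
    br <- random_breaks(20)
    base <- cluster_dsb(br)
    extra <- random_breaks(1)
    aug <- cluster_dsb(merge_breaks(br, extra))
    sig_base <- partition_signature(br, base$members)
    sig_aug <- partition_signature(br, aug$members)
    # every original DSB's members are still jointly inside some DSB
    for (s in sig_base) {
      expect_true(any(vapply(sig_aug, function(t) {
        all(strsplit(s, ";")[[1]] %in% strsplit(t, ";")[[1]])
      }, logical(1))))
    }
  }
})

test_that("complexity classes follow the break count", {
  expect_identical(classify_complexity(2), "simple")
  expect_identical(classify_complexity(3), "complex")
  expect_identical(classify_complexity(7), "complex")
  expect_error(classify_complexity(1), "at least two")
})

test_that("yields and per-nucleus conversions are exact arithmetic", {
  expect_equal(dsb_per_nucleus(3.5, 1, 6), 21.0, tolerance = 1e-12)
  expect_equal(dsb_per_nucleus(2.8, 1, 6), 16.8, tolerance = 1e-12)
  y <- compute_yields(n_dsb_per_batch = rep(21, 10),
                      dose_per_batch = rep(1, 10), genome_gbp = 6,
                      n_simple = 180, n_complex = 30)
  expect_equal(y$dsb_per_gy_per_gbp, 3.5, tolerance = 1e-12)
  expect_equal(y$simple_fraction + y$complex_fraction, 1)
  expect_equal(compute_yields(rep(0, 10), rep(1, 10))$dsb_per_gy_per_gbp, 0)
  expect_error(compute_yields(1, 0), "dose")
})

test_that("RBE is the yield ratio with propagated errors", {
  r <- compute_rbe(4.7, 3.6, 0.3, 0.3)
  expect_equal(r$rbe, 4.7 / 3.6, tolerance = 1e-12)
  expect_equal(round(r$rbe, 1), 1.3)
  expect_equal(r$sd, (4.7 / 3.6) * sqrt((0.3 / 4.7)^2 + (0.3 / 3.6)^2),
               tolerance = 1e-12)
  expect_equal(compute_rbe(3.5, 3.5, 0.1, 0.1)$rbe, 1.0)
  expect_equal(compute_rbe(3.5, 2.8, 0.1, 0.1)$rbe, 1.25)
  expect_error(compute_rbe(1, 0), "positive")
})

test_that("chromatin split recounts cluster centroids", {
  set.seed(74)
  g <- build_genome()
  v <- g$voxels
  eu_mid <- (v$bp_start[v$class == "euchromatin"][1] +
               v$bp_end[v$class == "euchromatin"][1]) / 2
  het_mid <- (v$bp_start[v$class == "heterochromatin"][1] +
                v$bp_end[v$class == "heterochromatin"][1]) / 2
  dsb <- data.frame(centroid_bp = c(rep(eu_mid, 11), rep(het_mid, 9)))
  s <- summarize_chromatin_split(dsb, g)
  expect_equal(unname(s["euchromatin"]), 0.55)
  expect_equal(unname(s["heterochromatin"]), 0.45)
  expect_equal(sum(s), 1)
})
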