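#!/usr/bin/env Rscript
# Derivation of the genome-exposure calibration constants.
#
# The statistical genome target has no atomistic DNA volumes, so two
# constants stand in for the missing geometry:
#   * hit_prob_eu    - probability that a deposition site in euchromatin
#                      hits DNA-associated volume (het = 2x),
#   * dna_exposure   - fraction of the nominal local molarity that is
#                      within diffusion reach of a radical,
# plus the effective histone molarity (2.4 x [deoxyribose]) that sets
# how fast OH radicals are scavenged.
#
# Calibration targets (all literature-level, fixed before tuning):
#   1. total SSB yield in the low-LET band (~150-300 SSB/Gy/Gbp),
#   2. DSB yield within the PFGE band 2-8 DSB/Gy/Gbp at 40 kVp,
#   3. direct:indirect break split near 55:45,
#   4. OH removal rate ~0.55/ns in euchromatin so that break growth
#      between 2.5 and 10 ns corresponds to a ~1.3 DSB end-time ratio
#      (break-count growth ~ sqrt(1.3) since DSBs scale quadratically
#      with local break density).
#
# This script reruns the pilot grid at reduced size and prints the same
# diagnostics that fixed the defaults hit_prob_eu = 0.020 and
# dna_exposure = 0.27.

library(microdsb)

seed <- 20260901
n_electrons <- 250    # reduced pilot; the original scan used 400-800

set.seed(child_seed(seed, "calib_ps"))
s40 <- build_kvp_spectrum(40)
ps <- generate_phase_space(s40, sarrp_stack(), 1e6)

grid <- expand.grid(hit_prob_eu = c(0.015, 0.020, 0.030),
                    dna_exposure = c(0.20, 0.27, 0.40))
rows <- list()
for (i in seq_len(nrow(grid))) {
  set.seed(child_seed(seed, paste0("calib_", i)))
  g <- build_genome(hit_prob_eu = grid$hit_prob_eu[i])
  src <- sample_electron_sources(ps, n_electrons)
  run <- run_damage_chain(src, g,
                          chemistry_config(end_time_ns = 10,
                                           dna_exposure =
                                             grid$dna_exposure[i]),
                          end_times_ns = c(2.5, 10))
  e25 <- run$end_times[["2.5"]]; e10 <- run$end_times[["10"]]
  rows[[i]] <- data.frame(
    grid[i, ],
    ssb_per_gy_gbp = e25$n_ssb / run$dose_total_Gy / 6,
    dsb_yield_2p5 = e25$yield$dsb_per_gy_per_gbp,
    dsb_yield_10 = e10$yield$dsb_per_gy_per_gbp,
    direct_share = e25$n_direct / max(1, e25$n_breaks),
    break_growth = e10$n_breaks / max(1, e25$n_breaks))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/calibration_scan.csv", row.names = FALSE)
print(tab, digits = 3)
cat("\nChosen defaults: hit_prob_eu = 0.020, dna_exposure = 0.27",
    "(break growth ~1.16 corresponds to a ~1.3 DSB end-time ratio;",
    "DSB counts at this pilot size carry ~30% Monte Carlo error, so",
    "the scan targets the break-level diagnostics, not the noisy DSB",
    "counts themselves).\n")
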