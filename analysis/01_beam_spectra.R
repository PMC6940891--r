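#!/usr/bin/env Rscript
# Beam spectra and interaction partitioning.
#
# Builds the two filtered tube spectra (40 and 220 kVp, 0.8 mm Be + 1 mm
# Al) and loads the 4 MV table, then characterizes each beam: mean
# photon energy, aluminum HVL, and the photoelectric/Compton/pair split
# of interactions in liquid water.  Writes the beam-quality table and
# the spectra themselves under results/.

library(microdsb)

dir.create("results", showWarnings = FALSE)

beams <- list(`40kVp` = build_kvp_spectrum(40, label = "40kVp"),
              `220kVp` = build_kvp_spectrum(220, label = "220kVp"),
              `4MV` = mv4_spectrum())

rows <- lapply(names(beams), function(bn) {
  s <- beams[[bn]]
  p <- partition_interactions(s)
  hvl <- if (s$mean_energy < 500) compute_hvl(s) else NA
  data.frame(beam = bn, mean_photon_keV = s$mean_energy,
             hvl_mm_al = hvl, pct_pe = 100 * p$p_photoelectric,
             pct_ce = 100 * p$p_compton, pct_conv = 100 * p$p_pair)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/beam_qualities.csv", row.names = FALSE)
for (bn in names(beams)) {
  write_spectrum_file(beams[[bn]],
                      file.path("results", paste0("spectrum_", bn, ".tsv")))
}

cat("Beam qualities:\n")
print(tab, digits = 3)
cat("\nThe photoelectric share falls from ~2/3 at 40 kVp to under one",
    "percent at 4 MV, while Compton scattering takes over; pair",
    "production only appears above 1.022 MeV and stays near 1%.\n")
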