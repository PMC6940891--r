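# microdsb

Micro- and nanodosimetry of X-ray irradiated endothelial-cell
monolayers, at desk scale: from photon spectra to secondary-electron
phase spaces, specific-energy distributions across a cell-nucleus
population, and prompt DNA double-strand-break (DSB) yields with
direct and water-radiolysis (indirect) damage, for 40 kVp, 220 kVp and
4 MV beams.

The scientific question: beams of very different photon energy can
deposit the *same* macroscopic dose yet damage cells differently. Two
quantities capture the difference. The **microdosimetric spread**
σ<sub>z,rel</sub> = σ<sub>z</sub>/D measures how unevenly the specific
energy z (energy imparted / mass, the stochastic analogue of dose) is
distributed over a population of cell nuclei; f(z;D) is a compound
Poisson over the track count ν per nucleus,
f(z;D) = Σ<sub>ν</sub> p(ν)·f<sub>ν</sub>(z), p(ν) = e<sup>−n</sup>n<sup>ν</sup>/ν!,
giving σ<sub>z,rel</sub> = √(E[z₁²]/(D·E[z₁])) in terms of single-track
moments. The **DSB yield** (DSB per Gy per Gbp) counts clustered
backbone lesions: direct breaks where >17.5 eV accumulates in the
sugar-phosphate subvolumes of one nucleotide, indirect breaks where a
diffusing OH• radical reaches a deoxyribose (40% conversion), clustered
into DSBs when ≥2 breaks fall within <10 bp with opposite-strand
involvement (simple = 2 breaks, complex = ≥3). The ratio of yields
between beams is the relative biological effectiveness (RBE).

The package implements the whole chain as testable units: filtered
Kramers tube spectra and an embedded 4 MV table; interaction
partitioning and Klein–Nishina / photoelectric electron sampling; a
two-tier electron transport (coarse phase-space tier with a 100 eV cut,
fine track-structure tier down to 7.4 eV); elliptical-cylinder nucleus
phantoms (304.4 µm³) with pair-cumulation dose doubling; a statistical
6 Gbp hetero/euchromatin genome target; Brownian-dynamics radiolysis
with the full 10-reaction radical network and histone scavenging; and
density-scan DSB clustering with complexity classification.

## Worked example

```r
library(microdsb)
set.seed(1)

s40 <- build_kvp_spectrum(40)          # 0.8 mm Be + 1 mm Al filtration
s40$mean_energy                        # 25.61 keV
compute_hvl(s40)                       # 0.944 mm Al
partition_interactions(s40)$p_photoelectric   # 0.686

ps  <- generate_phase_space(s40, sarrp_stack(), 1e6)
mean(ps$E_keV)                         # 11.0 keV mean secondary electron
mean(ps$origin_flag == "created_inside")      # 0.86

genome <- build_genome()               # 6 Gbp, 52% eu / 48% het
src <- sample_electron_sources(ps, 400)
run <- run_damage_chain(src, genome,
                        chemistry_config(end_time_ns = 10),
                        end_times_ns = c(2.5, 10))
print(run)
#> <damage_run: 400 electrons, total dose 0.346 Gy>
#>   2.5 ns: 5.78 +/- 1.56 DSB/Gy/Gbp, 12 DSBs (329 direct + 241 indirect breaks)
#>   10 ns: 5.78 +/- 1.56 DSB/Gy/Gbp, 12 DSBs (329 direct + 305 indirect breaks)

sm <- sigma_zrel_vs_dose(run$per_track$z1_Gy, c(0.25, 0.5, 1, 2))
round(subset(sm, method == "compound_poisson")$sigma_z_rel, 4)
#> 0.1386 0.0978 0.0694 0.0488   (spread narrows as dose grows)
```

The yield sits in the photon PFGE band (2-8 DSB/Gy/Gbp) with a batch
error near 30% at this small run — here the 64 extra indirect breaks
gained between 2.5 and 10 ns happened not to complete a new DSB, a tie
that disappears at the 1200+ electron scale the analysis scripts use.
Repeating with the 4 MV beam gives a much narrower f(z;D): its ~MeV
electrons each deposit only ~0.2 mGy per nucleus traversal, so equal
dose means many more, more uniform, tracks.

The numbered scripts under `analysis/` run the full study:
`00_calibration.R` (derivation of the two genome-exposure constants),
`01_beam_spectra.R`, `02_phase_space.R`, `03_microdosimetry.R`,
`04_damage_yields.R`, `05_rbe_comparison.R`, each writing its tables
under `results/`. The methods vignette (`vignettes/methods.Rmd`)
documents every model and default.

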