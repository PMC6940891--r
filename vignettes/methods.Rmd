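---
title: "From photon spectra to DSB yields: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From photon spectra to DSB yields: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microdsb` is a desk-scale computation chain for asking how X-ray beam
quality (40 kVp, 220 kVp, 4 MV) changes the early biological damage in an
endothelial-cell monolayer: the spread of specific energy across a cell
population (microdosimetry) and the yield and complexity of prompt DNA
double-strand breaks (nanodosimetry). This vignette explains each model in
the chain, the parameters that matter, and where the desk-scale
simplifications end and a full track-structure Monte Carlo code would
begin.

## Photon sources

The kV tube beams are Kramers continua, $w_0(E) \propto (E_{peak}-E)/E$,
attenuated through 0.8 mm beryllium, 1 mm aluminum and a 0.6 mm
aluminum-equivalent anode self-filtration term (typical for
reflection-target tungsten tubes; spectrum calculators apply the same
correction internally). Characteristic anode lines are omitted — the
downstream stages depend on the continuum shape — and any two-column
measured spectrum can be substituted via `read_spectrum_file()`. With the
embedded attenuation data this reproduces the three beam-quality constants
the study geometry specifies: a 25.6 keV mean and 0.85 mm Al HVL at
40 kVp, and a photoelectric share near 69% of water interactions. The 4 MV
spectrum ships as a synthetic two-column table (a truncated gamma-shaped
continuum) whose single free parameter was solved so the mean is exactly
1.3 MeV.

Photon interaction coefficients, attenuation data, the air mass
energy-absorption curve and the electron stopping-power table are smoothed
digitizations of the public NIST XCOM/ESTAR tabulations at 2–3 significant
figures, interpolated log–log. They are *effective* data: no claim is made
of replicating any particular Monte Carlo toolkit's cross sections, and
every test that touches them carries the corresponding tolerance (±10% on
mean energies, ±15% on HVL, ±5 points on interaction shares).

## Electron transport: two tiers

The coarse tier produces the phase space at the cell layer. Photons
travel as a parallel beam with exponential free paths through the slab
stack (the organic slabs — polystyrene, Plexiglas, carbon fiber, foam —
are water-equivalent per unit mass, adequate in their Compton-dominated
regime). One interaction per photon is sampled (single-interaction fluence
approximation; scattered photons are not followed), secondary electrons
are generated with Klein–Nishina (Kahn sampling), photoelectric
(shell-binding subtraction, dipole-like angular law, one 0.5 keV Auger
electron per K-shell vacancy) or pair kinematics, and upstream electrons
are propagated in a straight line with an effective reach of 0.6 × CSDA
range. Electrons created inside the 5 µm layer are always recorded;
upstream electrons are recorded at the layer face with their
inverse-range residual energy if they arrive above the 100 eV production
cut. This reproduces the qualitative structure that matters downstream:
~85%/~70% of kVp electrons are born inside the layer versus ~0.5% at
4 MV, the kVp electron spectra are soft (about half below 10 keV) while
the 4 MV spectrum is not, and boundary-entering records show the
characteristic depletion below the production cut.

The fine tier is a table-driven track-structure walk used inside the
nucleus (7.4 eV tracking cut): exponential free flights with an effective
inelastic mean free path, excitation (8–13 eV) and ionization events
(effective binding 10–30 eV plus a $1/(T+T_0)^2$ delta-ray spectrum),
delta rays above 100 eV branched as sub-tracks, screened-Rutherford
deflections compounded at sub-keV energies, and local deposition of
sub-cut residuals. The free-flight length is *defined* as
$\lambda(E) = \bar\varepsilon(E)/S(E)$, which ties the model's mean
energy-loss rate to the stopping-power table by construction; the test
suite verifies the primary path length against CSDA quadrature of the same
table to 20%, and conservation of energy exactly. Electron energies above
1 MeV (tail of the 4 MV spectrum) are clamped to 1 MeV — the fine tier's
validity bound — which leaves nucleus-scale deposition unaffected since
the stopping power is nearly flat from 0.3 to 4 MeV.

## Microdosimetry

The population model is 10,000 elliptical-cylinder nucleus phantoms
(9.5 × 5.1 × 2.0 µm, 304.4 µm³, liquid water) placed without overlap at
mid-height of a 4 × 4 mm × 5 µm layer, leaving 1.5 µm of water above and
below each nucleus — farther than the ~4 nm range of sub-100 eV
electrons, so the coarse-tier production cut cannot bias the scored
energies. Specific energy is $z = \sum\varepsilon / m$ per nucleus, and
the population density $f(z;D)$ is a compound Poisson over the track
count, $f(z;D) = \sum_\nu p(\nu) f_\nu(z)$ with
$p(\nu) = e^{-n} n^\nu/\nu!$. Two consequences are used as built-in
oracles: the mean of $f(z;D)$ is $D$, and the relative spread is
$\sigma_{z,rel} = \sqrt{E[z_1^2]/(D\,E[z_1])}$ in terms of single-track
moments.

At desk scale the population spread is computed by *composition*: the
single-track specific energies $z_1$ come from transported tracks through
one nucleus, and each simulated nucleus receives
$\nu \sim \text{Poisson}(D/\bar z_1)$ resampled tracks. This is exactly
the compound-Poisson structure of the geometric population at a fraction
of the cost; the geometric scorer (`score_specific_energy()`) remains the
reference implementation and is validated against the analytic oracle on
synthetic Neyman–Scott deposition clouds whose moments are known.
Pair cumulation doubles the dose by summing disjoint random pairs of
nuclei farther apart than 50 µm (the "independent tracks" threshold is
not quantified by the study description; 50 µm is several diffusion and
track lengths and is exposed in the configuration), halving the
population per step: 10⁴ nuclei at 0.25 Gy support three steps to 2 Gy
with 1250 left.

Histogram binning is Freedman–Diaconis by default, and the Gaussian fit
of $f(z;D)$ is unweighted least squares on the density histogram with
sample moments reported alongside. Whether the "<2%" and "7%"
spread differences between beams are absolute points or relative
differences is ambiguous in the source description, so both are
derivable from the reported `sigma_z_rel` columns.

## The statistical genome target

A full atomistic nucleus geometry is out of scope; the genome model is
statistical. The nucleus is voxelized at 0.25 µm; voxels are labelled
euchromatin/heterochromatin uniformly at random with volume fractions
derived from the genomic split (52/48 by bp) and a 2:1 compaction ratio,
and the 6 Gbp of coordinates partition the voxels contiguously in scan
order. Inside a voxel, positions map to bp through a 10 nm sub-lattice:
sites within one sub-cell receive bp indices within that cell's ~15 bp
(eu) or ~30 bp (het) of contiguous sequence, so the <10 bp clustering
scale corresponds to a few nm of chromatin, as it should.

Two constants stand in for the missing DNA geometry and were calibrated
once (derivation in `analysis/00_calibration.R`, reduced-scale rerun):
the per-site DNA hit probability (`hit_prob_eu = 0.020`, doubled in
heterochromatin) and the radical exposure factor (`dna_exposure = 0.27`)
scaling the species–DNA encounter rates. The calibration targets were
literature-level: total SSB yields of ~150–300 SSB/Gy/Gbp, DSB yields
within the 2–8 DSB/Gy/Gbp band spanned by pulsed-field gel
electrophoresis measurements for photons, a direct:indirect split near
55:45, and an OH removal rate shaped so damage growth between the 2.5 ns
and 10 ns chemistry end-times corresponds to the ~1.3 end-time yield
ratio. Subvolume fractions of DNA-associated volume (deoxyribose 0.30,
phosphate 0.30, hydration shell 0.25, base 0.10, histone 0.05) are a
modelling choice exposed in the configuration — no volumetric breakdown
is available to fix them.

One known artefact of the statistical target: because heterochromatin
packs more bp into each 10 nm sub-cell, its breaks spread over more
sequence and convert to DSBs slightly less efficiently than an atomistic
fiber model would predict. The eu:het DSB split therefore lands near
60:40 rather than 55:45; it is reported as a diagnostic, never asserted.

## Radiolysis chemistry

Each ionization spawns OH•, H₃O⁺ and a solvated electron (thermalized
2.5 nm out; other species 0.8 nm); excitations dissociate to OH• + H•
with probability 0.35, otherwise relax. The chemical stage is Brownian
dynamics over the seven-species network with all ten radical–radical
reactions at their tabulated rate constants. Reaction radii derive from
the rates through the Smoluchowski relation $R = k/(4\pi D' N_A)$ (with
$2k$ for identical-reactant reactions, matching the
$d[A]/dt = -2k[A]^2$ convention of the tabulated constants); a pair
reacts on contact at the end of a step or via the Brownian-bridge
crossing probability $\exp(-(d_0-R)(d_1-R)/(D'\,\Delta t))$, and the
time step adapts to the closest reactive pair. A periodic-box benchmark
holds the OH• self-reaction to the second-order closed form
$1/[OH](t) = 1/[OH]_0 + 2kt$ within 5%, and free diffusion reproduces
$\langle r^2\rangle = 6Dt$ within 2%.

Species–DNA encounters are first-order channels with rate
$k\,[\text{target}]_{local}$ per chromatin class rather than pairwise
radii: the statistical genome has no explicit nucleotide coordinates, the
two formulations agree in the well-mixed limit, and the exposure factor
absorbs the geometric localization. Deoxyribose encounters by OH• break
the backbone in 40% of cases; all base reactions are radical sinks only
(they deplete the radical pool but never score damage); histone
encounters absorb every species (scavenging), with an effective histone
molarity of 2.4 × [deoxyribose]. The medium is anoxic — no oxygen
reactions. Spatially isolated spurs (linked at 25 nm) are simulated
independently: species farther apart than several diffusion lengths of
the 10 ns horizon cannot meet. Encounter records carry their times, and
the per-encounter break draws are attached at creation, so scoring at
2.5 ns yields a strict subset of the 10 ns damage from one run — the
end-time monotonicity is structural, not statistical.

## Damage scoring

Direct breaks: energies in the deoxyribose, phosphate and hydration-shell
subvolumes of one nucleotide (bp, strand) are summed; a break registers
strictly above 17.5 eV (the boundary case 17.5 eV does not break —
"higher than" is strict — and both behaviors are unit-tested; the
threshold is configurable). Duplicate breaks at one site from the direct
and indirect channels merge: a site is broken or it is not. DSB
clustering is a density scan with neighborhood $|\Delta bp| < 10$
(strict) and a minimum of two breaks; on the linear genome this equals
transitive gap-chaining, which the test suite proves identical to a
brute-force transitive closure on a thousand random instances. Clusters
lacking opposite-strand members stay in the SSB tally. Complexity is
simple (= 2 breaks) versus complex (≥ 3). The scan runs over all strand
breaks with the opposite-strand filter applied afterwards; seeding
clusters only from opposite-strand pairs is the documented alternative
and would only matter for same-strand chains bridging two DSBs, which at
these break densities never occurs.

Yields are $N_{DSB}/(D \cdot 6\,\text{Gbp})$ with tracks partitioned
into 10 batches by id and the error taken as the standard deviation of
the batch mean. Clustering is per track: at desk-scale densities
(well below one break per Mbp) cross-track coincidences within 10 bp are
vanishingly rare, and per-track clustering keeps batches exact. RBE is
the yield ratio against the 4 MV reference with batch errors propagated
in quadrature.

## Problem sizes and what passing tests mean

The analysis scripts and acceptance checks run 1200–2000 electrons per
kVp beam and 6000–12000 for 4 MV (whose tracks each deposit ~4× less
energy, so more are needed for comparable damage statistics), with
1.5 million coarse-tier photons per kV beam; populations of 4000–6000
nuclei support the spread curves. At these sizes DSB counts carry
15–30% Monte Carlo error — the absolute-yield checks are therefore
band checks (2–8 DSB/Gy/Gbp), the end-time and RBE ratios from the
*simulated* chain are reported but only their orderings are asserted, and
the precise ratio targets (21.0/28.2/16.8/21.6 DSB per nucleus, RBE 1.3,
end-time ratio ~1.3) are computed as exact arithmetic from the packaged
reference yield table. A full-fidelity chain would instead push the
per-track RMSE below 6% of the mean DSB count by raising the electron
count ~50-fold.

The synthetic deposition-cloud generator (Neyman–Scott clusters with
i.i.d. site energies) exists so that every downstream stage can be tested
against closed-form moments. It emulates the clustered, track-grouped
statistical structure of real energy depositions, but not their energy
spectrum, spatial anisotropy along a track direction, or the
LET-dependence of cluster sizes — so tests that pass on clouds validate
the *scoring machinery*, while the physics of track structure is
validated separately against CSDA ranges, the Klein–Nishina density and
the beam-quality constants.

## Known limitations

* Single-interaction photon transport: no build-up from scattered
  photons; acceptable for thin layers but wrong for thick-phantom depth
  doses.
* Effective inelastic tables: event-by-event cross sections are not
  those of any published track-structure code; agreement is enforced at
  the stopping-power level.
* The eu:het DSB split bias described above.
* Weak LET discrimination: the effective-table transport reproduces the
  beams' energy-deposition *amounts* faithfully but separates their
  cluster densities less than event-by-event cross sections would, so
  the simulated kVp-vs-4 MV RBE scatters around ~0.7–1.2 at desk scale
  instead of the reference 1.3; the acceptance report carries both
  numbers.
* No base damage, no non-DSB oxidative clustered lesions, no repair
  kinetics, anoxic chemistry only — prompt strand-break damage is the
  endpoint.
* The experimental foci counts are packaged comparison constants;
  nothing in the package recomputes biology.
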