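# Embedded photon/electron interaction data for liquid water, aluminum,
# beryllium and air.
#
# Provenance: the values are smoothed digitizations of the public NIST
# XCOM / ESTAR tabulations (mass attenuation and mass energy-absorption
# coefficients in cm^2/g; collision stopping power converted to eV/nm at
# unit density), rounded to 2-3 significant figures and interpolated
# log-log between grid points.  They are *effective* tables: the package
# does not promise replication of any particular Monte Carlo toolkit's
# cross-section set, and every downstream check that depends on them
# carries a documented data-fidelity tolerance.

# ---- photon interaction coefficients (cm^2/g) -------------------------------

.tab_energy_keV <- c(
  1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100,
  150, 200, 300, 400, 500, 600, 800, 1000, 1250, 1500, 2000, 3000, 4000, 5000
)

# photoelectric, liquid water
.tab_water_pe <- c(
  4076, 1374, 615, 192, 82.0, 41.9, 24.1, 9.92, 4.94, 1.40, 0.566,
  0.157, 0.0629, 0.0310, 0.0174, 0.00700, 0.00346,
  0.000975, 0.000395, 0.000112, 4.5e-5, 2.25e-5, 1.30e-5, 5.2e-6,
  2.7e-6, 1.55e-6, 9.0e-7, 4.3e-7, 1.5e-7, 7.5e-8, 4.5e-8
)

# incoherent (Compton), liquid water
.tab_water_incoh <- c(
  0.0135, 0.0280, 0.0420, 0.0700, 0.0900, 0.1060, 0.1170, 0.1270, 0.1350,
  0.1530, 0.1650, 0.1720, 0.1760, 0.1760, 0.1740, 0.1680, 0.1630,
  0.1470, 0.1350, 0.1175, 0.1055, 0.0965, 0.0893, 0.0785,
  0.0706, 0.0630, 0.0571, 0.0479, 0.0356, 0.0279, 0.0222
)

# pair production (nuclear + electron field), liquid water
.tab_water_pair <- c(
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0,
  0.00015, 0.00042, 0.00145, 0.0040, 0.0061, 0.0080
)

# total mass attenuation, aluminum (with coherent; narrow-beam geometry)
.tab_al_total <- c(
  1185, 3957, 2263, 788, 360.5, 193.4, 115.3, 50.33, 26.23, 7.955, 3.441,
  1.128, 0.5685, 0.3681, 0.2778, 0.2018, 0.1704,
  0.1378, 0.1223, 0.1042, 0.0928, 0.0844, 0.0780, 0.0684,
  0.0615, 0.0550, 0.0501, 0.0432, 0.0354, 0.0311, 0.0284
)

# total mass attenuation, beryllium
.tab_be_total <- c(
  604.1, 179.7, 74.69, 21.27, 8.685, 4.369, 2.527, 1.124, 0.6466, 0.3070,
  0.2251, 0.1792, 0.1640, 0.1554, 0.1493, 0.1401, 0.1328,
  0.1190, 0.1089, 0.0946, 0.0850, 0.0778, 0.0721, 0.0634,
  0.0569, 0.0511, 0.0464, 0.0400, 0.0325, 0.0287, 0.0262
)

# mass energy-absorption coefficient, dry air (kerma weighting)
.tab_air_muen <- c(
  3599, 1188, 527, 160.1, 76.4, 39.31, 22.7, 9.446, 4.742, 1.334, 0.5389,
  0.1537, 0.0683, 0.0410, 0.0304, 0.0241, 0.0233,
  0.0250, 0.0267, 0.0287, 0.0295, 0.0297, 0.0295, 0.0288,
  0.0279, 0.0267, 0.0255, 0.0235, 0.0206, 0.0187, 0.0174
)

# ---- electron collision stopping power, liquid water (eV/nm) ----------------

.tab_estop_keV <- c(
  0.0074, 0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.7,
  1, 2, 3, 5, 7, 10, 20, 30, 50, 70, 100, 200, 300, 500, 700,
  1000, 2000, 4000
)
.tab_estop_eVnm <- c(
  1.5, 2.5, 6.0, 15.0, 22.0, 24.0, 24.0, 22.0, 18.0, 15.5,
  12.6, 7.7, 5.9, 4.2, 3.2, 2.26, 1.20, 0.88, 0.66, 0.53,
  0.412, 0.279, 0.235, 0.203, 0.192, 0.185, 0.183, 0.190
)

# approximate liquid-water shell structure used for photoelectron emission:
# oxygen K shell dominates photoabsorption above ~1 keV; the remainder is
# lumped into two effective valence levels.
.water_shells <- data.frame(
  binding_eV = c(539.7, 32.2, 18.0),
  weight     = c(0.90, 0.07, 0.03)
)

.material_density <- c(
  water = 1.0, aluminum = 2.699, beryllium = 1.848,
  polystyrene = 1.06, plexiglas = 1.19, carbon_fiber = 0.55,
  foam = 0.03, air = 0.0012
)

#' Log-log table interpolation
#'
#' Interpolates positive-valued physics tables linearly in log-log space,
#' with constant extrapolation beyond the grid.  Zero table entries (e.g.
#' pair production below threshold) are handled by interpolating on
#' \code{log(y + tiny)} only over the non-zero tail.
#'
#' @param e energies (keV) at which to evaluate.
#' @param etab table energy grid (keV), strictly increasing.
#' @param ytab table values.
#' @return interpolated values, same length as \code{e}.
#' @keywords internal
loglog_interp <- function(e, etab, ytab) {
  stopifnot(length(etab) == length(ytab), all(diff(etab) > 0))
  pos <- ytab > 0
  out <- numeric(length(e))
  if (!any(pos)) return(out)
  et <- etab[pos]; yt <- ytab[pos]
  le <- log(pmin(pmax(e, et[1]), et[length(et)]))
  out <- exp(stats::approx(log(et), log(yt), xout = le, rule = 2)$y)
  # a zero-valued leading region in the table (threshold process) stays zero
  if (!pos[1]) out[e < et[1]] <- 0
  out
}

#' Embedded photon cross-section / attenuation table
#'
#' Returns the embedded per-process photon interaction coefficients
#' (cm^2/g) for a material at the requested energies.  Processes for
#' liquid water are \code{"photoelectric"}, \code{"compton"} and
#' \code{"pair"}; for the attenuators (\code{aluminum}, \code{beryllium})
#' and for air only totals are tabulated (\code{"total"}, and
#' \code{"muen"} for air).  Light organic media (polystyrene, Plexiglas,
#' carbon fiber, foam) are treated as water-equivalent per unit mass,
#' which is adequate for the Compton-dominated regime they are used in.
#'
#' @param material material identifier.
#' @param energy_keV photon energies in keV.
#' @param process process name (see Details).
#' @return coefficient values in cm^2/g.
#' @export
cross_section <- function(material, energy_keV,
                          process = c("total", "photoelectric", "compton",
                                      "pair", "muen")) {
  process <- match.arg(process)
  material <- match_material(material)
  waterlike <- material %in% c("water", "polystyrene", "plexiglas",
                               "carbon_fiber", "foam")
  if (waterlike) {
    val <- switch(process,
      photoelectric = loglog_interp(energy_keV, .tab_energy_keV, .tab_water_pe),
      compton       = loglog_interp(energy_keV, .tab_energy_keV, .tab_water_incoh),
      pair          = ifelse(energy_keV < 1022, 0,
                             loglog_interp(energy_keV, .tab_energy_keV,
                                           .tab_water_pair)),
      total         = loglog_interp(energy_keV, .tab_energy_keV, .tab_water_pe) +
                      loglog_interp(energy_keV, .tab_energy_keV, .tab_water_incoh) +
                      ifelse(energy_keV < 1022, 0,
                             loglog_interp(energy_keV, .tab_energy_keV,
                                           .tab_water_pair)),
      muen          = stop("muen tabulated for air only")
    )
    return(val)
  }
  if (material == "aluminum") {
    if (process != "total")
      stop("only total attenuation is tabulated for aluminum")
    return(loglog_interp(energy_keV, .tab_energy_keV, .tab_al_total))
  }
  if (material == "beryllium") {
    if (process != "total")
      stop("only total attenuation is tabulated for beryllium")
    return(loglog_interp(energy_keV, .tab_energy_keV, .tab_be_total))
  }
  if (material == "air") {
    if (process != "muen")
      stop("air is tabulated for kerma weighting (muen) only")
    return(loglog_interp(energy_keV, .tab_energy_keV, .tab_air_muen))
  }
  stop("unknown material: ", material)
}

match_material <- function(material) {
  m <- tolower(gsub("[ -]", "_", material))
  if (m %in% c("al")) m <- "aluminum"
  if (m %in% c("be")) m <- "beryllium"
  if (m %in% c("pmma")) m <- "plexiglas"
  if (!m %in% names(.material_density))
    stop("unknown material: ", material)
  m
}

#' Material mass density
#' @param material material identifier.
#' @return density in g/cm^3.
#' @export
material_density <- function(material) {
  unname(.material_density[match_material(material)])
}

#' Linear attenuation coefficient
#'
#' Total linear attenuation (per mm) of a material at the given photon
#' energies, from the embedded tables and densities.
#'
#' @inheritParams cross_section
#' @return mu in mm^-1.
#' @export
linear_attenuation <- function(material, energy_keV) {
  mu_rho <- cross_section(material, energy_keV, "total")   # cm^2/g
  mu_rho * material_density(material) / 10                 # cm^-1 -> mm^-1
}

#' Electron collision stopping power in liquid water
#'
#' @param energy_keV electron kinetic energies (keV).
#' @return stopping power in eV/nm (at density 1.0 g/cm^3).
#' @export
stopping_power <- function(energy_keV) {
  loglog_interp(energy_keV, .tab_estop_keV, .tab_estop_eVnm)
}

#' CSDA range in liquid water by quadrature of the stopping-power table
#'
#' Integrates dE/S(E) from \code{e_min} to the electron energy on a dense
#' log grid.  Used as the independent yardstick for the stochastic
#' transport model.
#'
#' @param energy_keV electron kinetic energy (keV), scalar or vector.
#' @param e_min_keV lower integration limit (keV); defaults to the
#'   tracking cut of 7.4 eV.
#' @param n quadrature points.
#' @return range in nm.
#' @export
csda_range <- function(energy_keV, e_min_keV = 0.0074, n = 4000) {
  vapply(energy_keV, function(E) {
    if (E <= e_min_keV) return(0)
    eg <- exp(seq(log(e_min_keV), log(E), length.out = n))
    s  <- stopping_power(eg)
    # integrate dE/S in eV / (eV/nm) = nm
    sum(diff(eg * 1000) * 2 / (s[-1] + s[-n]))
  }, numeric(1))
}

#' Water shell-binding table for photoelectron emission
#'
#' Approximate liquid-water shell binding energies (eV) with relative
#' photoabsorption weights.  The oxygen K shell carries most of the
#' photoelectric cross section above 1 keV.
#'
#' @return data.frame with columns \code{binding_eV}, \code{weight}.
#' @export
water_shell_table <- function() .water_shells
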