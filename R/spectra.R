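# Photon beam spectra: filtered bremsstrahlung for the kV tube beams, a
# tabulated megavoltage spectrum, half-value layers and interaction
# partitioning in liquid water.

#' Construct a photon spectrum
#'
#' A photon spectrum is a discretized relative fluence: strictly
#' increasing bin energies (bin centers, half-open bins) with
#' non-negative weights that are normalized to sum to one.
#'
#' @param energy_keV strictly increasing photon energies (keV).
#' @param weight relative fluence per bin; normalized internally.
#' @param label beam identifier.
#' @return object of class \code{photon_spectrum} with fields
#'   \code{energy_keV}, \code{weight}, \code{label}, \code{mean_energy}.
#' @export
photon_spectrum <- function(energy_keV, weight, label = "beam") {
  stopifnot(length(energy_keV) == length(weight), length(weight) >= 1)
  if (any(diff(energy_keV) <= 0)) stop("energy grid must be strictly increasing")
  if (any(weight < 0)) stop("negative fluence weight")
  s <- sum(weight)
  if (s <= 0) stop("spectrum has zero total fluence")
  w <- weight / s
  structure(
    list(energy_keV = energy_keV, weight = w, label = label,
         mean_energy = sum(energy_keV * w)),
    class = "photon_spectrum"
  )
}

#' @export
print.photon_spectrum <- function(x, ...) {
  cat(sprintf("<photon_spectrum '%s': %d bins, %.1f-%.1f keV, mean %.1f keV>\n",
              x$label, length(x$energy_keV), min(x$energy_keV),
              max(x$energy_keV), x$mean_energy))
  invisible(x)
}

#' Filtered kV bremsstrahlung spectrum (Kramers seed shape)
#'
#' Builds an X-ray tube spectrum as a Kramers continuum,
#' \eqn{w_0(E) \propto (E_{peak} - E)/E}, attenuated through the tube's
#' inherent beryllium filtration and added aluminum filtration using the
#' embedded attenuation tables.  Characteristic anode lines are omitted;
#' measured spectra can be substituted via \code{\link{read_spectrum_file}}.
#'
#' @param peak_kV tube peak voltage (kV), between 10 and 300.
#' @param inherent_mm_be inherent filtration, mm of beryllium.
#' @param added_mm_al added filtration, mm of aluminum.
#' @param anode_equiv_mm_al tungsten-anode self-filtration expressed as an
#'   aluminum-equivalent thickness (mm); 0.6 mm is a typical value for
#'   reflection-target tubes and is applied in addition to the stated
#'   filtrations, as spectrum calculators do internally.
#' @param grid_step energy grid step (keV).
#' @param label beam identifier; defaults to "<peak> kVp".
#' @return a \code{\link{photon_spectrum}}.
#' @export
build_kvp_spectrum <- function(peak_kV, inherent_mm_be = 0.8,
                               added_mm_al = 1.0, anode_equiv_mm_al = 0.6,
                               grid_step = 0.5, label = NULL) {
  stopifnot(peak_kV >= 10, peak_kV <= 300,
            inherent_mm_be >= 0, added_mm_al >= 0)
  if (peak_kV <= grid_step) stop("peak voltage below the grid step")
  e <- seq(grid_step, peak_kV - grid_step / 2, by = grid_step)
  w0 <- (peak_kV - e) / e
  att <- exp(-linear_attenuation("beryllium", e) * inherent_mm_be -
             linear_attenuation("aluminum", e) *
               (added_mm_al + anode_equiv_mm_al))
  w <- w0 * att
  keep <- w / max(w) > 1e-9
  photon_spectrum(e[keep], w[keep],
                  label = label %||% sprintf("%g kVp", peak_kV))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two-column spectrum file
#'
#' Plain text, whitespace separated columns \code{energy_keV weight};
#' lines beginning with \code{#} are comments.
#'
#' @param path file path.
#' @param label beam identifier; defaults to the file name.
#' @return a \code{\link{photon_spectrum}}.
#' @export
read_spectrum_file <- function(path, label = NULL) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy_keV", "weight"))
  photon_spectrum(tab$energy_keV, tab$weight,
                  label = label %||% basename(path))
}

#' Write a spectrum to a two-column text file
#' @param spectrum a \code{\link{photon_spectrum}}.
#' @param path output path.
#' @export
write_spectrum_file <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spectrum: %s", spectrum$label), con)
  writeLines("# energy_keV weight", con)
  writeLines(sprintf("%.6g %.8g", spectrum$energy_keV, spectrum$weight), con)
  invisible(path)
}

#' The 4 MV linac photon spectrum
#'
#' Loads the embedded two-column table approximating a 4 MV medical linac
#' spectrum after the collimator.  The table is synthetic (a truncated
#' gamma-shaped continuum, see \code{inst/extdata}); its parameters were
#' solved so that the mean photon energy is 1.3 MeV.
#'
#' @return a \code{\link{photon_spectrum}} labelled "4 MV".
#' @export
mv4_spectrum <- function() {
  path <- system.file("extdata", "mv4_spectrum_synthetic.tsv",
                      package = "microdsb", mustWork = TRUE)
  read_spectrum_file(path, label = "4 MV")
}

#' Sample photon energies from a spectrum
#' @param spectrum a \code{\link{photon_spectrum}}.
#' @param n number of samples.
#' @return numeric vector of energies (keV).
#' @export
sample_photon_energy <- function(spectrum, n) {
  spectrum$energy_keV[sample.int(length(spectrum$weight), n, replace = TRUE,
                                 prob = spectrum$weight)]
}

#' Half-value layer of an attenuator for a beam
#'
#' Thickness of \code{material} halving the air-kerma-weighted
#' transmitted intensity,
#' \eqn{K(t) = \sum_i w_i E_i (\mu_{en}/\rho)_{air}(E_i) e^{-\mu_i t}},
#' found by bisection to a relative tolerance of 1e-6.
#'
#' @param spectrum a \code{\link{photon_spectrum}}.
#' @param material attenuator id (default aluminum).
#' @param t_max upper bracket for the search (mm).
#' @return thickness in mm.
#' @export
compute_hvl <- function(spectrum, material = "aluminum", t_max = 100) {
  e <- spectrum$energy_keV
  kw <- spectrum$weight * e * cross_section("air", e, "muen")
  mu <- linear_attenuation(material, e)
  k0 <- sum(kw)
  f <- function(t) sum(kw * exp(-mu * t)) / k0 - 0.5
  if (f(0) < 0 || f(t_max) > 0) stop("HVL search interval does not bracket")
  stats::uniroot(f, c(0, t_max), tol = 1e-6 * t_max)$root
}

#' Partition photon interactions in liquid water
#'
#' Probabilities that a photon interaction in liquid water is
#' photoelectric, Compton or pair production, weighted over the spectrum.
#' The default weighting (\code{"interaction"}) weights each fluence bin
#' by its total interaction coefficient, matching a tally of interactions
#' in a thin water layer; \code{"fluence"} averages the per-energy
#' process fractions with fluence weights only.
#'
#' @param spectrum a \code{\link{photon_spectrum}}.
#' @param weighting see Details.
#' @return list with fields \code{p_photoelectric}, \code{p_compton},
#'   \code{p_pair} (summing to one).
#' @export
partition_interactions <- function(spectrum,
                                   weighting = c("interaction", "fluence")) {
  weighting <- match.arg(weighting)
  e <- spectrum$energy_keV
  w <- spectrum$weight
  tau <- cross_section("water", e, "photoelectric")
  sig <- cross_section("water", e, "compton")
  kap <- cross_section("water", e, "pair")
  tot <- tau + sig + kap
  if (weighting == "interaction") {
    p <- c(sum(w * tau), sum(w * sig), sum(w * kap)) / sum(w * tot)
  } else {
    p <- c(sum(w * tau / tot), sum(w * sig / tot), sum(w * kap / tot))
  }
  out <- list(p_photoelectric = p[1], p_compton = p[2], p_pair = p[3])
  stopifnot(abs(sum(p) - 1) < 1e-12)
  out
}

# ---- secondary-electron energy sampling -------------------------------------

#' Sample Compton recoil-electron energies (Klein-Nishina)
#'
#' Kahn's composition-rejection sampling of the Klein-Nishina scattered
#' photon energy; the recoil electron carries the remainder.  Valid for
#' all photon energies and guaranteed to terminate.
#'
#' @param photon_keV photon energies (keV); recycled against \code{n}.
#' @param n number of samples (defaults to \code{length(photon_keV)}).
#' @return electron kinetic energies (keV) in \code{[0, Tmax]} with
#'   \eqn{T_{max} = 2E^2/(m_ec^2 + 2E)}.
#' @export
sample_compton_electron <- function(photon_keV, n = length(photon_keV)) {
  e <- rep_len(photon_keV, n)
  stopifnot(all(e > 0))
  alpha <- e / 511
  x <- numeric(n)            # kappa = E / E'
  todo <- seq_len(n)
  while (length(todo)) {
    a <- alpha[todo]
    r1 <- stats::runif(length(todo))
    r2 <- stats::runif(length(todo))
    r3 <- stats::runif(length(todo))
    b1 <- r1 <= (2 * a + 1) / (2 * a + 9)
    xx <- ifelse(b1, 1 + 2 * a * r2, (1 + 2 * a) / (1 + 2 * a * r2))
    ct <- 1 - (xx - 1) / a
    acc <- ifelse(b1,
                  r3 <= 4 * (1 / xx - 1 / xx^2),
                  r3 <= 0.5 * (ct^2 + 1 / xx))
    ok <- which(acc & ct >= -1 & ct <= 1)
    if (length(ok)) {
      x[todo[ok]] <- xx[ok]
      todo <- todo[-ok]
    }
  }
  e * (1 - 1 / x)
}

#' Klein-Nishina recoil-energy density by quadrature
#'
#' Deterministic density of the Compton recoil-electron energy obtained
#' by change of variables from the angular Klein-Nishina cross section on
#' a fine scattering-angle grid; independent yardstick for the sampler.
#'
#' @param photon_keV photon energy (keV), scalar.
#' @param n grid size.
#' @return data.frame with columns \code{T_keV}, \code{density}
#'   (unnormalized) ordered by \code{T_keV}.
#' @export
klein_nishina_recoil_density <- function(photon_keV, n = 20000) {
  a <- photon_keV / 511
  ct <- seq(-1, 1, length.out = n)[-c(1, n)]
  eprat <- 1 / (1 + a * (1 - ct))                 # E'/E
  T_keV <- photon_keV * (1 - eprat)
  dsdo <- eprat^2 * (eprat + 1 / eprat - (1 - ct^2))
  # dT/dcos(theta) = E * a * eprat^2  => density in T per unit T
  dens <- dsdo / (photon_keV * a * eprat^2)
  o <- order(T_keV)
  data.frame(T_keV = T_keV[o], density = dens[o])
}

#' Sample photoelectron energies
#'
#' Photoelectron kinetic energy equals the photon energy minus the shell
#' binding energy; the shell is drawn from the embedded water shell table
#' unless a binding energy is supplied.
#'
#' @param photon_keV photon energies (keV).
#' @param shell_binding_eV optional fixed binding energy (eV); if NULL the
#'   shell is sampled per photon from \code{\link{water_shell_table}}
#'   among shells the photon can ionize.
#' @return list with \code{electron_keV} and \code{binding_eV}.
#' @export
sample_photoelectron <- function(photon_keV, shell_binding_eV = NULL) {
  n <- length(photon_keV)
  if (!is.null(shell_binding_eV)) {
    b <- rep_len(shell_binding_eV, n)
    if (any(photon_keV * 1000 <= b)) stop("photon below shell binding energy")
  } else {
    sh <- water_shell_table()
    if (min(photon_keV) * 1000 > max(sh$binding_eV)) {
      idx <- sample.int(nrow(sh), n, replace = TRUE, prob = sh$weight)
      b <- sh$binding_eV[idx]
    } else {
      b <- numeric(n)
      for (i in seq_len(n)) {
        open <- sh$binding_eV < photon_keV[i] * 1000
        if (!any(open)) stop("photon below all shell binding energies")
        b[i] <- sample(sh$binding_eV[open], 1, prob = sh$weight[open])
      }
    }
  }
  list(electron_keV = photon_keV - b / 1000, binding_eV = b)
}
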