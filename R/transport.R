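# Fine-tier electron transport (track-structure walk) and the synthetic
# deposition-cloud generator used to exercise the downstream stages with
# analytically known statistics.

.microdsb_env <- new.env(parent = emptyenv())

# Mean primary energy loss per inelastic event (eV) under the event model
# of the walk kernel: excitations lose Uniform(8,13) eV; ionizations lose
# an effective binding Uniform(10,30) eV plus a delta-ray energy from a
# 1/(T+T0)^2 spectrum truncated at (E-B)/2.
mean_event_loss <- function(E_eV, p_excitation = 0.4, T0 = 15) {
  Bbar <- 20
  Tm <- pmax((E_eV - Bbar) / 2, 0)
  Tbar <- ifelse(Tm > 0,
                 (log((Tm + T0) / T0) - Tm / (Tm + T0)) /
                   (1 / T0 - 1 / (Tm + T0)),
                 0)
  p_excitation * 10.5 + (1 - p_excitation) * (Bbar + Tbar)
}

#' Effective inelastic mean-free-path table
#'
#' The walk kernel's free-flight length is tied to the embedded stopping
#' power: lambda(E) = (mean energy loss per event)/S(E), so the model's
#' average energy-loss rate reproduces the stopping-power table by
#' construction.
#'
#' @param cut_eV tracking cut (eV).
#' @param p_excitation excitation fraction of inelastic events.
#' @param n grid size.
#' @return list with \code{logE} (log eV) and \code{log_lambda} (log nm).
#' @export
transport_tables <- function(cut_eV = 7.4, p_excitation = 0.4, n = 300) {
  key <- sprintf("tt_%g_%g_%d", cut_eV, p_excitation, n)
  if (!is.null(.microdsb_env[[key]])) return(.microdsb_env[[key]])
  E <- exp(seq(log(cut_eV), log(4.2e6), length.out = n))
  m <- mean_event_loss(E, p_excitation)
  S <- stopping_power(E / 1000)        # eV/nm
  tab <- list(logE = log(E), log_lambda = log(m / S))
  .microdsb_env[[key]] <- tab
  tab
}

#' Transport one electron through liquid water
#'
#' Fine-tier track-structure walk: exponential free flights from the
#' effective inelastic mean free path, excitation/ionization events with
#' stochastic energy losses, delta-ray branching above 100 eV, and
#' screened-Rutherford deflections.  Residual energy below the tracking
#' cut deposits locally.  Energy is conserved exactly: site energies plus
#' the energy carried out of the bounding box equal the start energy.
#'
#' @param energy_keV start kinetic energy (keV), at most 1 MeV for the
#'   fine tier.
#' @param position_nm start position (nm), length 3.
#' @param direction start direction (normalized internally), length 3.
#' @param tracking_cut_eV tracking cut (eV), default 7.4.
#' @param bbox_nm optional bounding box
#'   \code{c(xmin, xmax, ymin, ymax, zmin, zmax)} in nm; sites outside are
#'   not scored and the electron's remaining energy is recorded as escaped.
#' @param track_id integer id stored on the output.
#' @param p_excitation excitation fraction of inelastic events.
#' @param screening_const screened-Rutherford screening constant.
#' @return a \code{deposition_track}: list with \code{track_id},
#'   \code{primary_keV}, \code{escape_eV} and \code{sites}, a data.frame
#'   with columns \code{x_nm, y_nm, z_nm, energy_eV, kind}
#'   (\code{"ionization"}, \code{"excitation"}, \code{"termination"}).
#' @export
transport_electron <- function(energy_keV, position_nm = c(0, 0, 0),
                               direction = c(0, 0, 1),
                               tracking_cut_eV = 7.4, bbox_nm = NULL,
                               track_id = 1L, p_excitation = 0.4,
                               screening_const = 6.5e-5) {
  stopifnot(energy_keV > 0, energy_keV <= 1000)
  if (is.null(bbox_nm)) bbox_nm <- c(-1, 1, -1, 1, -1, 1) * 1e12
  tab <- transport_tables(tracking_cut_eV, p_excitation)
  res <- cpp_transport_electron(energy_keV * 1000, position_nm, direction,
                                tracking_cut_eV, tab$logE, tab$log_lambda,
                                bbox_nm, p_excitation, 100, screening_const,
                                5e6)
  kinds <- c("ionization", "excitation", "termination")
  sites <- data.frame(
    x_nm = res$sites[, 1], y_nm = res$sites[, 2], z_nm = res$sites[, 3],
    energy_eV = res$sites[, 4], kind = kinds[res$kind]
  )
  structure(list(track_id = as.integer(track_id),
                 primary_keV = energy_keV,
                 escape_eV = res$escape_eV,
                 primary_path_nm = res$primary_path_nm,
                 sites = sites),
            class = "deposition_track")
}

#' @export
print.deposition_track <- function(x, ...) {
  cat(sprintf(
    "<deposition_track #%d: %.3g keV, %d sites, %.3g eV deposited, %.3g eV escaped>\n",
    x$track_id, x$primary_keV, nrow(x$sites), sum(x$sites$energy_eV),
    x$escape_eV))
  invisible(x)
}

#' Synthetic deposition clouds with analytically known moments
#'
#' Generates deposition tracks without transport physics: each track has
#' a Neyman-Scott structure (a parent point uniform in the region, sites
#' scattered isotropically Gaussian around it) with an independently
#' sampled site count and i.i.d. site energies.  All moments follow from
#' the parameters, which makes these clouds the oracle inputs for the
#' microdosimetry and damage stages.
#'
#' @param track_count number of tracks.
#' @param mean_sites mean number of sites per track.
#' @param sites_dist \code{"poisson"} or \code{"fixed"}.
#' @param energy_eV site-energy law: a single number for fixed energies,
#'   or \code{list(kind = "exp", mean = m)} / \code{list(kind = "unif",
#'   min, max)}.
#' @param cluster_scale_nm Gaussian scatter of sites around the parent.
#' @param region_um list with \code{x}, \code{y}, \code{z} ranges (um) for
#'   the parent points.
#' @return list of \code{deposition_track} objects (positions in nm).
#' @export
synthesize_deposition_cloud <- function(track_count, mean_sites = 10,
                                        sites_dist = c("poisson", "fixed"),
                                        energy_eV = 50,
                                        cluster_scale_nm = 50,
                                        region_um = list(x = c(0, 10),
                                                         y = c(0, 10),
                                                         z = c(0, 2))) {
  sites_dist <- match.arg(sites_dist)
  stopifnot(track_count >= 1, mean_sites >= 0)
  ns <- switch(sites_dist,
               poisson = stats::rpois(track_count, mean_sites),
               fixed   = rep(as.integer(round(mean_sites)), track_count))
  draw_energy <- function(k) {
    if (is.numeric(energy_eV)) return(rep(energy_eV[1], k))
    switch(energy_eV$kind,
           exp  = stats::rexp(k, 1 / energy_eV$mean),
           unif = stats::runif(k, energy_eV$min, energy_eV$max),
           stop("unknown energy law"))
  }
  lapply(seq_len(track_count), function(i) {
    k <- ns[i]
    cx <- stats::runif(1, region_um$x[1], region_um$x[2]) * 1000
    cy <- stats::runif(1, region_um$y[1], region_um$y[2]) * 1000
    cz <- stats::runif(1, region_um$z[1], region_um$z[2]) * 1000
    sites <- data.frame(
      x_nm = cx + stats::rnorm(k, 0, cluster_scale_nm),
      y_nm = cy + stats::rnorm(k, 0, cluster_scale_nm),
      z_nm = cz + stats::rnorm(k, 0, cluster_scale_nm),
      energy_eV = draw_energy(k),
      kind = rep("ionization", k)
    )
    structure(list(track_id = i, primary_keV = sum(sites$energy_eV) / 1000,
                   escape_eV = 0, sites = sites),
              class = "deposition_track")
  })
}

#' Bind deposition tracks into one site table
#' @param tracks list of \code{deposition_track}s.
#' @return data.frame with a \code{track_id} column prepended to the site
#'   columns.
#' @export
bind_tracks <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr) {
    if (nrow(tr$sites) == 0) return(NULL)
    cbind(track_id = tr$track_id, tr$sites)
  }))
}
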