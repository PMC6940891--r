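# Coarse-tier photon transport through the irradiation layer stacks and
# scoring of the secondary-electron phase space at the cell layer.
#
# Photons travel as a parallel beam along +z through the slab stack with
# exponential free paths from the embedded attenuation data (organic slabs
# are water-equivalent per unit mass).  Secondary electrons created inside
# the cell layer are always recorded; electrons created upstream are
# propagated with an effective straight-line reach (detour factor times
# the CSDA range) and recorded at the layer face with their residual
# energy if they arrive above the production cut.  Scattered photons are
# not followed (single-interaction fluence approximation).

#' Irradiation layer stacks
#'
#' \code{sarrp_stack()} is the kV X-ray cabinet geometry: 3 mm of culture
#' medium (liquid water), the 5 um liquid-water cell layer, and 3 mm of
#' polystyrene chamber bottom, beam entering through the medium.
#' \code{linac_stack()} is the 4 MV geometry irradiated from below
#' through the treatment table: 2 mm carbon fiber, 46 mm foam, 2 mm
#' carbon fiber, 5 mm Plexiglas build-up, 3 mm polystyrene chamber
#' bottom, the 5 um cell layer, then 3 mm of medium.
#'
#' @return a \code{layer_stack} data.frame with columns \code{material},
#'   \code{thickness_mm}, \code{cell_layer}.
#' @export
sarrp_stack <- function() {
  layer_stack(
    material = c("water", "water", "polystyrene"),
    thickness_mm = c(3, 0.005, 3),
    cell_layer = c(FALSE, TRUE, FALSE)
  )
}

#' @rdname sarrp_stack
#' @export
linac_stack <- function() {
  layer_stack(
    material = c("carbon_fiber", "foam", "carbon_fiber", "plexiglas",
                 "polystyrene", "water", "water"),
    thickness_mm = c(2, 46, 2, 5, 3, 0.005, 3),
    cell_layer = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Build a layer stack
#' @param material material ids (see \code{\link{cross_section}}).
#' @param thickness_mm slab thicknesses (mm), beam order.
#' @param cell_layer logical, exactly one TRUE.
#' @return a \code{layer_stack} data.frame.
#' @export
layer_stack <- function(material, thickness_mm, cell_layer) {
  stopifnot(length(material) == length(thickness_mm),
            length(material) == length(cell_layer))
  if (length(material) == 0) stop("empty stack")
  if (sum(cell_layer) != 1) stop("stack must contain exactly one cell layer")
  if (any(thickness_mm <= 0)) stop("slab thicknesses must be positive")
  structure(data.frame(material = material, thickness_mm = thickness_mm,
                       cell_layer = cell_layer),
            class = c("layer_stack", "data.frame"))
}

range_table <- function() {
  tab <- .microdsb_env[["range_tab"]]
  if (is.null(tab)) {
    E <- exp(seq(log(0.05), log(4000), length.out = 250))
    R <- csda_range(E)
    tab <- list(logR = log(R), logE = log(E))
    .microdsb_env[["range_tab"]] <- tab
  }
  tab
}

# fast memoized interpolation of csda_range for bulk phase-space work
csda_range_fast <- function(energy_keV) {
  tab <- range_table()
  exp(stats::approx(tab$logE, tab$logR,
                    xout = log(pmax(pmin(energy_keV, 4000), 0.05)),
                    rule = 2)$y)
}

# inverse of csda_range: residual energy at a given residual range
residual_energy_keV <- function(range_nm) {
  tab <- range_table()
  out <- exp(stats::approx(tab$logR, tab$logE,
                           xout = log(pmax(range_nm, 1e-6)), rule = 2)$y)
  out[range_nm <= 0] <- 0
  out
}

#' Generate a secondary-electron phase space at the cell layer
#'
#' @param beam a \code{\link{photon_spectrum}}.
#' @param stack a \code{\link{layer_stack}}.
#' @param n_photons number of primary photons.
#' @param production_cut_eV transport cut for the coarse tier (eV, default
#'   100): upstream electrons arriving below it are dropped (they deposit
#'   locally), while electrons *created* in the cell layer are recorded at
#'   any energy.
#' @param window_mm lateral extent (x, y) of the scored field, mm.
#' @param detour ratio of effective straight-line penetration to CSDA
#'   range for upstream electrons.
#' @param auger_keV energy of the single Auger electron emitted per
#'   K-shell photo-ionization.
#' @param seed optional seed.
#' @return a data.frame of phase-space records: \code{x_um, y_um, z_um}
#'   (z measured from the upstream cell-layer face), direction cosines
#'   \code{ux, uy, uz}, \code{E_keV}, and \code{origin_flag}
#'   (\code{"created_inside"} or \code{"entered_boundary"}).
#' @export
generate_phase_space <- function(beam, stack, n_photons,
                                 production_cut_eV = 100,
                                 window_mm = c(125, 85), detour = 0.6,
                                 auger_keV = 0.5, seed = NULL) {
  stopifnot(n_photons > 0, production_cut_eV >= 10)
  if (!is.null(seed)) set.seed(seed)
  zb <- cumsum(c(0, stack$thickness_mm))
  icell <- which(stack$cell_layer)
  zc0 <- zb[icell]; zc1 <- zb[icell + 1]

  E <- sample_photon_energy(beam, n_photons)
  # per-layer optical depth, photons x layers
  nl <- nrow(stack)
  od <- vapply(seq_len(nl), function(l) {
    linear_attenuation(stack$material[l], E) * stack$thickness_mm[l]
  }, numeric(n_photons))
  od <- matrix(od, nrow = n_photons)
  cum <- matrix(0, n_photons, nl + 1)
  for (l in seq_len(nl)) cum[, l + 1] <- cum[, l] + od[, l]
  xi <- -log(stats::runif(n_photons))
  interacts <- xi < cum[, nl + 1]
  if (!any(interacts)) {
    return(empty_phase_space())
  }
  idx <- which(interacts)
  xi <- xi[idx]; E <- E[idx]
  cum <- cum[idx, , drop = FALSE]; od <- od[idx, , drop = FALSE]
  lay <- max.col(xi >= cum[, seq_len(nl), drop = FALSE], "last")
  frac <- (xi - cum[cbind(seq_along(idx), lay)]) / od[cbind(seq_along(idx), lay)]
  z_int <- zb[lay] + frac * stack$thickness_mm[lay]

  # process choice in the local material (water-equivalent everywhere here)
  tau <- cross_section("water", E, "photoelectric")
  sig <- cross_section("water", E, "compton")
  kap <- cross_section("water", E, "pair")
  tot <- tau + sig + kap
  u <- stats::runif(length(E))
  proc <- ifelse(u < tau / tot, "pe", ifelse(u < (tau + sig) / tot, "ce", "pp"))

  elec <- make_secondaries(E, z_int, proc, auger_keV)
  rec <- propagate_to_layer(elec, zc0, zc1, production_cut_eV, detour)
  if (nrow(rec) == 0) return(empty_phase_space())

  rec$x_um <- stats::runif(nrow(rec), -window_mm[1] / 2, window_mm[1] / 2) * 1000
  rec$y_um <- stats::runif(nrow(rec), -window_mm[2] / 2, window_mm[2] / 2) * 1000
  rec$z_um <- (rec$z_mm - zc0) * 1000
  rec[, c("x_um", "y_um", "z_um", "ux", "uy", "uz", "E_keV", "origin_flag")]
}

empty_phase_space <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             ux = numeric(0), uy = numeric(0), uz = numeric(0),
             E_keV = numeric(0), origin_flag = character(0))
}

# one row per secondary electron: energy, creation depth, direction
make_secondaries <- function(E, z_int, proc, auger_keV) {
  out <- list()
  pe <- proc == "pe"
  if (any(pe)) {
    ph <- sample_photoelectron(E[pe])
    cth <- sample_dipole_cos(sum(pe))
    out$pe <- data.frame(E_keV = ph$electron_keV, z_mm = z_int[pe],
                         cos_z = cth)
    kshell <- ph$binding_eV > 500
    if (any(kshell)) {
      out$auger <- data.frame(E_keV = rep(auger_keV, sum(kshell)),
                              z_mm = z_int[pe][kshell],
                              cos_z = stats::runif(sum(kshell), -1, 1))
    }
  }
  ce <- proc == "ce"
  if (any(ce)) {
    T <- sample_compton_electron(E[ce])
    alpha <- E[ce] / 511
    eprat <- pmax(1 - T / E[ce], 1e-12)
    cth_ph <- pmin(pmax(1 - (1 / eprat - 1) / alpha, -1), 1)  # photon angle
    t2 <- sqrt(pmax((1 - cth_ph) / (1 + cth_ph), 0))
    phi <- atan2(1, (1 + alpha) * t2)                          # electron polar
    out$ce <- data.frame(E_keV = T, z_mm = z_int[ce], cos_z = cos(phi))
  }
  pp <- proc == "pp"
  if (any(pp)) {
    avail <- E[pp] - 1022
    f <- stats::runif(sum(pp), 0.2, 0.8)
    cs <- function(n) cos(abs(stats::rnorm(n, 0, 0.3)))
    out$pp <- data.frame(E_keV = c(f * avail, (1 - f) * avail),
                         z_mm = rep(z_int[pp], 2),
                         cos_z = cs(2 * sum(pp)))
  }
  do.call(rbind, out)
}

# dipole-like photoelectron polar angle: p(c) ~ (1 - c^2), c = cos angle
# to the beam axis
sample_dipole_cos <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    c0 <- stats::runif(2 * n, -1, 1)
    out <- c(out, c0[stats::runif(2 * n) < 1 - c0^2])
  }
  out[seq_len(n)]
}

propagate_to_layer <- function(elec, zc0, zc1, production_cut_eV, detour) {
  if (is.null(elec) || nrow(elec) == 0) {
    return(cbind(empty_phase_space()[0, ], z_mm = numeric(0))[, ])
  }
  inside <- elec$z_mm >= zc0 & elec$z_mm <= zc1
  res <- list()
  if (any(inside)) {
    k <- sum(inside)
    phi <- stats::runif(k, 0, 2 * pi)
    sz <- sqrt(pmax(1 - elec$cos_z[inside]^2, 0))
    res$inside <- data.frame(
      z_mm = elec$z_mm[inside],
      ux = sz * cos(phi), uy = sz * sin(phi), uz = elec$cos_z[inside],
      E_keV = elec$E_keV[inside], origin_flag = "created_inside"
    )
  }
  up <- which(!inside & elec$E_keV * 1000 >= production_cut_eV)
  if (length(up)) {
    e <- elec[up, ]
    towards_down <- e$z_mm < zc0 & e$cos_z > 1e-9
    towards_up <- e$z_mm > zc1 & e$cos_z < -1e-9
    tdist <- rep(Inf, nrow(e))
    tdist[towards_down] <- (zc0 - e$z_mm[towards_down]) / e$cos_z[towards_down]
    tdist[towards_up] <- (zc1 - e$z_mm[towards_up]) / e$cos_z[towards_up]
    reach_mm <- detour * csda_range_fast(e$E_keV) / 1e6
    ok <- which(is.finite(tdist) & tdist < reach_mm)
    if (length(ok)) {
      path_used <- tdist[ok] / detour * 1e6       # nm of CSDA path consumed
      E_res <- residual_energy_keV(csda_range_fast(e$E_keV[ok]) - path_used)
      keep <- E_res * 1000 >= production_cut_eV
      if (any(keep)) {
        kk <- ok[keep]
        phi <- stats::runif(length(kk), 0, 2 * pi)
        sz <- sqrt(pmax(1 - e$cos_z[kk]^2, 0))
        res$entered <- data.frame(
          z_mm = ifelse(e$cos_z[kk] > 0, zc0, zc1),
          ux = sz * cos(phi), uy = sz * sin(phi), uz = e$cos_z[kk],
          E_keV = E_res[keep], origin_flag = "entered_boundary"
        )
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(z_mm = numeric(0), ux = numeric(0), uy = numeric(0),
                      uz = numeric(0), E_keV = numeric(0),
                      origin_flag = character(0)))
  }
  do.call(rbind, res)
}

#' Write / read a phase-space file
#'
#' Tab-separated columns \code{x_um y_um z_um ux uy uz E_keV origin_flag}
#' under a versioned magic header line.
#'
#' @param ps phase-space data.frame.
#' @param path file path.
#' @export
write_phase_space <- function(ps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# microdsb-phase-space v1", con)
  utils::write.table(ps, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phase_space
#' @export
read_phase_space <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# *microdsb-phase-space", first))
    stop("not a phase-space file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
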