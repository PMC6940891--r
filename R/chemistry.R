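# Water radiolysis: physico-chemical species creation, Brownian-dynamics
# chemistry with the radical-radical reaction network, species-DNA
# encounter channels, histone scavenging, and indirect strand-break
# scoring.  Anoxic medium: no oxygen reactions.

#' The seven radiolysis species
#'
#' Species names with diffusion coefficients (nm^2/ns, i.e. 1e-9 m^2/s),
#' standard dilute-aqueous values.
#'
#' @return data.frame with \code{name}, \code{code} (0-based, as used by
#'   the simulation kernel), \code{D_nm2_ns}.
#' @export
chem_species_table <- function() {
  data.frame(
    name = c("H", "OH", "H2", "H2O2", "OHm", "H3Op", "eaq"),
    code = 0:6,
    D_nm2_ns = c(7.0, 2.8, 4.8, 2.3, 5.0, 9.0, 4.9)
  )
}

#' Radical-radical reaction network
#'
#' The ten default reactions of the chemistry stage with rate constants
#' in units of 1e10 M^-1 s^-1.
#'
#' @return data.frame with reactants \code{a}, \code{b}, rate \code{k_1e10}
#'   and a comma-separated \code{products} field ("" for water only).
#' @export
reaction_table <- function() {
  data.frame(
    a = c("H", "H", "H", "H2", "H2O2", "H3Op", "H3Op", "OH", "OH", "eaq"),
    b = c("eaq", "OH", "H", "OH", "eaq", "eaq", "OHm", "eaq", "OH", "eaq"),
    k_1e10 = c(2.65, 1.44, 1.20, 4.17e-3, 1.41, 2.11, 14.3, 2.95, 0.44, 0.50),
    products = c("OHm,H2", "", "H2", "H", "OHm,OH", "H", "", "OHm",
                 "H2O2", "OHm,OHm,H2")
  )
}

#' Species-DNA reaction rates
#'
#' Rate constants (1e9 M^-1 s^-1) for radical attack on the
#' 2-deoxyribose and the four bases, as used by the encounter channels.
#' Base reactions act as radical sinks only (they deplete radicals but
#' never score damage); only the OH-deoxyribose channel can break the
#' backbone.  There is no guanine + H entry in the source table.
#'
#' @return data.frame with \code{target}, \code{species}, \code{k_1e9}.
#' @export
dna_reaction_table <- function() {
  data.frame(
    target = c("deoxyribose", "adenine", "guanine", "thymine", "cytosine",
               "deoxyribose", "adenine", "guanine", "thymine", "cytosine",
               "deoxyribose", "adenine", "thymine", "cytosine"),
    species = c(rep("OH", 5), rep("eaq", 5), rep("H", 4)),
    k_1e9 = c(1.8, 6.1, 9.2, 6.4, 6.1,
              0.01, 9.0, 14.0, 18.0, 13.0,
              0.029, 0.10, 0.57, 0.092)
  )
}

# Smoluchowski reaction radius (nm) from k (M^-1 s^-1) and the mutual
# diffusion coefficient (nm^2/ns): R = k_molecular / (4 pi D'),
# k_molecular = k / N_A converted to nm^3/ns.
smoluchowski_radius <- function(k_M_s, D_mutual_nm2_ns) {
  k_nm3_ns <- k_M_s * 1e24 / 6.02214076e23 * 1e-9
  k_nm3_ns / (4 * pi * D_mutual_nm2_ns)
}

# pair radius and product matrices for the kernel (0-based type codes)
reaction_matrices <- function() {
  st <- chem_species_table()
  n <- nrow(st)
  Rp <- matrix(0, n, n)
  p1 <- matrix(-1L, n, n); p2 <- matrix(-1L, n, n); p3 <- matrix(-1L, n, n)
  rt <- reaction_table()
  code <- function(nm) st$code[match(nm, st$name)]
  for (i in seq_len(nrow(rt))) {
    a <- code(rt$a[i]); b <- code(rt$b[i])
    Dm <- st$D_nm2_ns[a + 1] + st$D_nm2_ns[b + 1]
    # identical reactants: the tabulated k follows d[A]/dt = -2k[A]^2,
    # while the Brownian pair-encounter rate gives -k_enc[A]^2; the
    # radius therefore derives from 2k
    kk <- rt$k_1e10[i] * 1e10 * ifelse(a == b, 2, 1)
    R <- smoluchowski_radius(kk, Dm)
    prods <- strsplit(rt$products[i], ",")[[1]]
    prods <- prods[nzchar(prods)]
    pc <- if (length(prods)) code(prods) else integer(0)
    for (idx in list(c(a, b), c(b, a))) {
      Rp[idx[1] + 1, idx[2] + 1] <- R
      p1[idx[1] + 1, idx[2] + 1] <- if (length(pc) >= 1) pc[1] else -1L
      p2[idx[1] + 1, idx[2] + 1] <- if (length(pc) >= 2) pc[2] else -1L
      p3[idx[1] + 1, idx[2] + 1] <- if (length(pc) >= 3) pc[3] else -1L
    }
  }
  list(R = Rp, p1 = p1, p2 = p2, p3 = p3, D = st$D_nm2_ns)
}

#' Chemistry stage configuration
#'
#' @param end_time_ns chemistry end-time (ns); 2.5 by default, 10 as the
#'   longer alternative.
#' @param p_indirect_break probability that an OH-deoxyribose encounter
#'   breaks the backbone (0.4).
#' @param dna_exposure calibration factor scaling all species-DNA
#'   encounter rates (the fraction of the nominal local molarity that is
#'   actually within diffusion reach; see the calibration script).
#' @param histone_k_M_s generic diffusion-limited rate for histone
#'   scavenging (all radicals absorbed on arrival).
#' @param p_excitation_dissociation fraction of excited water molecules
#'   that dissociate to OH + H.
#' @param thermalization_nm Gaussian jitter of nascent species around
#'   the deposition site; the solvated electron thermalizes farther out.
#' @param dt_min_ns,dt_max_ns adaptive time-step bounds.
#' @param spur_link_nm spatial linking distance for splitting a track's
#'   species into independently simulated spurs.
#' @return list of class \code{chemistry_config}.
#' @export
chemistry_config <- function(end_time_ns = 2.5, p_indirect_break = 0.4,
                             dna_exposure = 0.27, histone_k_M_s = 1.0e10,
                             p_excitation_dissociation = 0.35,
                             thermalization_nm = c(default = 0.8, eaq = 2.5),
                             dt_min_ns = 1e-3, dt_max_ns = 0.05,
                             spur_link_nm = 25) {
  stopifnot(end_time_ns > 0, p_indirect_break >= 0, p_indirect_break <= 1)
  structure(list(end_time_ns = end_time_ns,
                 p_indirect_break = p_indirect_break,
                 dna_exposure = dna_exposure,
                 histone_k_M_s = histone_k_M_s,
                 p_excitation_dissociation = p_excitation_dissociation,
                 thermalization_nm = thermalization_nm,
                 dt_min_ns = dt_min_ns, dt_max_ns = dt_max_ns,
                 spur_link_nm = spur_link_nm),
            class = "chemistry_config")
}

#' Create radiolysis species from deposition sites
#'
#' Ionized water yields OH + H3O+ + e-aq (the ejected electron
#' thermalizes and solvates nearby); excited water dissociates to
#' OH + H with the configured branching, otherwise relaxes without
#' radical production.  Sub-cut termination deposits produce no species.
#'
#' @param sites data.frame with \code{x_nm, y_nm, z_nm, kind}.
#' @param cfg a \code{\link{chemistry_config}}.
#' @return data.frame \code{x_nm, y_nm, z_nm, type} (0-based species
#'   code).
#' @export
initialize_species <- function(sites, cfg = chemistry_config()) {
  st <- chem_species_table()
  code <- function(nm) st$code[match(nm, st$name)]
  out <- list()
  ion <- sites[sites$kind == "ionization", , drop = FALSE]
  if (nrow(ion)) {
    out$ion <- data.frame(
      x_nm = rep(ion$x_nm, 3), y_nm = rep(ion$y_nm, 3),
      z_nm = rep(ion$z_nm, 3),
      type = rep(code(c("OH", "H3Op", "eaq")), each = nrow(ion))
    )
  }
  exc <- sites[sites$kind == "excitation", , drop = FALSE]
  if (nrow(exc)) {
    diss <- stats::runif(nrow(exc)) < cfg$p_excitation_dissociation
    if (any(diss)) {
      e <- exc[diss, , drop = FALSE]
      out$exc <- data.frame(
        x_nm = rep(e$x_nm, 2), y_nm = rep(e$y_nm, 2), z_nm = rep(e$z_nm, 2),
        type = rep(code(c("OH", "H")), each = nrow(e))
      )
    }
  }
  if (!length(out)) {
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      z_nm = numeric(0), type = integer(0)))
  }
  sp <- do.call(rbind, out)
  jit <- rep(cfg$thermalization_nm["default"], nrow(sp))
  jit[sp$type == code("eaq")] <- cfg$thermalization_nm["eaq"]
  sp$x_nm <- sp$x_nm + stats::rnorm(nrow(sp), 0, jit)
  sp$y_nm <- sp$y_nm + stats::rnorm(nrow(sp), 0, jit)
  sp$z_nm <- sp$z_nm + stats::rnorm(nrow(sp), 0, jit)
  rownames(sp) <- NULL
  sp
}

# species-DNA first-order channel rates per ns, ntype x 3 (columns:
# outside/eu/het, 1-indexed class + 1)
dna_rate_matrices <- function(genome, cfg) {
  st <- chem_species_table()
  n <- nrow(st)
  zero <- matrix(0, n, 3)
  if (is.null(genome)) return(list(dr = zero, base = zero, hist = zero))
  # local molarity of deoxyribose per class: 2 per bp
  dens_bp_nm3 <- genome$density_bp_um3 / 1e9      # bp per nm^3
  molar <- function(n_nm3) n_nm3 * 1e24 / 6.02214076e23  # -> mol/L
  c_dr <- molar(2 * dens_bp_nm3)                  # eu, het
  c_base_each <- c_dr / 4                         # 2 bases/bp, 4 kinds
  c_hist <- 2.4 * c_dr
  dt <- dna_reaction_table()
  rate <- function(k_M_s, conc_M) cfg$dna_exposure * k_M_s * conc_M * 1e-9
  dr <- zero; base <- zero; hist <- zero
  for (s in unique(dt$species)) {
    row <- st$code[match(s, st$name)] + 1
    kd <- dt$k_1e9[dt$species == s & dt$target == "deoxyribose"] * 1e9
    kb <- sum(dt$k_1e9[dt$species == s & dt$target != "deoxyribose"]) * 1e9 / 4
    for (cl in 1:2) {
      dr[row, cl + 1] <- rate(kd, c_dr[cl])
      base[row, cl + 1] <- rate(kb * 4, c_base_each[cl])
    }
  }
  for (row in seq_len(n)) {
    for (cl in 1:2) hist[row, cl + 1] <- rate(cfg$histone_k_M_s, c_hist[cl])
  }
  list(dr = dr, base = base, hist = hist)
}

# connected components of species positions under a grid linking length
spur_ids <- function(x, y, z, link_nm) {
  cellk <- paste(floor(x / link_nm), floor(y / link_nm), floor(z / link_nm))
  cells <- unique(cellk)
  idx <- match(cellk, cells)
  nc <- length(cells)
  parent <- seq_len(nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key3 <- do.call(rbind, strsplit(cells, " "))
  cx <- as.integer(key3[, 1]); cy <- as.integer(key3[, 2])
  cz <- as.integer(key3[, 3])
  lut <- new.env(parent = emptyenv(), size = nc * 2)
  for (i in seq_len(nc)) lut[[cells[i]]] <- i
  for (i in seq_len(nc)) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      j <- lut[[paste(cx[i] + dx, cy[i] + dy, cz[i] + dz)]]
      if (!is.null(j) && j > i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(nc), find, integer(1))
  match(comp[idx], unique(comp[idx]))
}

#' Run the chemistry stage for one set of species
#'
#' Splits the species into spatially independent spurs (groups farther
#' apart than several diffusion lengths never interact within the
#' end-time) and simulates each spur's Brownian dynamics with the full
#' reaction network, species-DNA encounter channels governed by the
#' chromatin class at the radical's position, and histone scavenging.
#' Runs to \code{end_time_ns}; encounter records carry their times, so
#' damage can afterwards be scored at any earlier end-time from the same
#' run.
#'
#' @param species data.frame from \code{\link{initialize_species}}.
#' @param genome a \code{genome_model} or NULL (no DNA channels).
#' @param cfg a \code{\link{chemistry_config}}.
#' @param track_id id attached to the outputs.
#' @return list with \code{encounters} (time_ns, species, target, x_nm,
#'   y_nm, z_nm, voxel_id, class, bp_index, strand, break_u, track_id),
#'   \code{reactions} (time_ns, a, b), and \code{n_survivors}.
#' @export
run_chemistry <- function(species, genome = NULL, cfg = chemistry_config(),
                          track_id = 1L) {
  st <- chem_species_table()
  mat <- reaction_matrices()
  dn <- dna_rate_matrices(genome, cfg)
  if (is.null(genome)) {
    lattice <- integer(0); dims <- c(0L, 0L, 0L)
    origin <- c(0, 0, 0); vox_nm <- 1; vclass <- integer(0)
  } else {
    lattice <- genome$lattice; dims <- as.integer(genome$dims)
    origin <- genome$origin_um * 1000; vox_nm <- genome$voxel_um * 1000
    vclass <- ifelse(genome$voxels$class == "euchromatin", 1L, 2L)
  }
  enc <- list(); rx <- list(); nsurv <- 0L
  if (nrow(species)) {
    sid <- spur_ids(species$x_nm, species$y_nm, species$z_nm,
                    cfg$spur_link_nm)
    for (s in unique(sid)) {
      sel <- sid == s
      res <- cpp_chemistry_spur(
        as.matrix(species[sel, c("x_nm", "y_nm", "z_nm")]),
        as.integer(species$type[sel]), mat$D, mat$R, mat$p1, mat$p2, mat$p3,
        dn$dr, dn$base, dn$hist, lattice, dims, origin, vox_nm, vclass,
        cfg$end_time_ns, cfg$dt_min_ns, cfg$dt_max_ns, 0)
      if (nrow(res$encounters)) enc[[length(enc) + 1]] <- res$encounters
      if (nrow(res$reactions)) rx[[length(rx) + 1]] <- res$reactions
      nsurv <- nsurv + nrow(res$survivors)
    }
  }
  enc <- if (length(enc)) do.call(rbind, enc) else matrix(0, 0, 7)
  rx <- if (length(rx)) do.call(rbind, rx) else matrix(0, 0, 3)
  targets <- c("deoxyribose", "base", "histone")
  encounters <- data.frame(
    time_ns = enc[, 1],
    species = st$name[enc[, 2] + 1],
    target = targets[enc[, 3] + 1],
    x_nm = enc[, 4], y_nm = enc[, 5], z_nm = enc[, 6],
    voxel_id = as.integer(enc[, 7])
  )
  if (nrow(encounters)) {
    encounters$class <- genome$voxels$class[encounters$voxel_id]
    encounters$bp_index <- genome_bp_at(genome, encounters$voxel_id,
                                        encounters$x_nm / 1000,
                                        encounters$y_nm / 1000,
                                        encounters$z_nm / 1000)
    encounters$strand <- as.integer(stats::runif(nrow(encounters)) < 0.5)
    encounters$break_u <- stats::runif(nrow(encounters))
  } else {
    encounters$class <- character(0)
    encounters$bp_index <- numeric(0)
    encounters$strand <- integer(0)
    encounters$break_u <- numeric(0)
  }
  encounters$track_id <- rep(as.integer(track_id), nrow(encounters))
  reactions <- data.frame(time_ns = rx[, 1],
                          a = st$name[rx[, 2] + 1], b = st$name[rx[, 3] + 1])
  list(encounters = encounters, reactions = reactions, n_survivors = nsurv)
}

#' Score indirect strand breaks from OH-deoxyribose encounters
#'
#' Each OH-deoxyribose encounter up to the requested end-time breaks the
#' backbone with probability \code{p_break}, inheriting the encounter's
#' bp index and strand.  The per-encounter break draws are attached to
#' the encounters, so scoring at 2.5 ns yields a subset of the breaks
#' scored at 10 ns for the same run.
#'
#' @param encounters encounter table from \code{\link{run_chemistry}}.
#' @param p_break break probability per encounter (default 0.4).
#' @param end_time_ns only encounters up to this time are considered.
#' @return data.frame of breaks: \code{bp_index, strand, origin,
#'   track_id, class}.
#' @export
score_indirect_breaks <- function(encounters, p_break = 0.4,
                                  end_time_ns = Inf) {
  stopifnot(p_break >= 0, p_break <= 1)
  sel <- encounters$species == "OH" & encounters$target == "deoxyribose" &
    encounters$time_ns <= end_time_ns & encounters$break_u < p_break
  br <- encounters[sel, , drop = FALSE]
  data.frame(bp_index = br$bp_index, strand = br$strand,
             origin = rep("indirect", nrow(br)),
             track_id = br$track_id, class = br$class)
}

#' Well-mixed periodic-box chemistry benchmark
#'
#' Runs \code{n} particles of one species in a periodic box at the given
#' concentration for \code{time_ns} and returns the surviving
#' concentration, for comparison with deterministic rate-equation
#' kinetics (e.g. 1/[OH] = 1/[OH]0 + 2kt for the OH self-reaction).
#'
#' @param species species name.
#' @param n particle count.
#' @param conc_M initial concentration (mol/L).
#' @param time_ns simulated time (ns).
#' @param dt_max_ns time-step cap.
#' @return list with \code{conc_M} (final), \code{box_nm}, \code{n_left}.
#' @export
well_mixed_box <- function(species = "OH", n = 200, conc_M = 0.01,
                           time_ns = 5, dt_max_ns = 0.02) {
  st <- chem_species_table()
  mat <- reaction_matrices()
  V_nm3 <- n / (conc_M * 6.02214076e23) * 1e24
  box <- V_nm3^(1 / 3)
  pos <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
  type <- rep(st$code[match(species, st$name)], n)
  zero <- matrix(0, nrow(st), 3)
  res <- cpp_chemistry_spur(pos, as.integer(type), mat$D, mat$R, mat$p1,
                            mat$p2, mat$p3, zero, zero, zero,
                            integer(0), c(0L, 0L, 0L), c(0, 0, 0), 1,
                            integer(0), time_ns, 1e-4, dt_max_ns, box)
  surv <- res$survivors
  n_left <- sum(surv[, 4] == type[1])
  list(conc_M = n_left / V_nm3 * 1e24 / 6.02214076e23, box_nm = box,
       n_left = n_left)
}
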