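# Orchestration: beam -> phase space -> single-nucleus damage chain and
# beam -> microdosimetric population spreads, plus the report tables
# comparing simulated DSB counts with the packaged experimental foci
# constants.

#' Packaged reference tables
#'
#' \code{experimental_foci()} returns the externally measured gamma-H2AX
#' foci counts per nucleus (comparison constants, never recomputed);
#' \code{reference_dsb_yields()} returns the reference full
#' track-structure DSB yields used for the yield-to-per-nucleus
#' arithmetic and RBE cross-checks.
#'
#' @return data.frame.
#' @export
experimental_foci <- function() {
  utils::read.table(system.file("extdata", "experimental_foci_reference.tsv",
                                package = "microdsb", mustWork = TRUE),
                    header = TRUE, sep = "\t", comment.char = "#")
}

#' @rdname experimental_foci
#' @export
reference_dsb_yields <- function() {
  utils::read.table(system.file("extdata", "reference_dsb_yields.tsv",
                                package = "microdsb", mustWork = TRUE),
                    header = TRUE, sep = "\t", comment.char = "#")
}

#' The three study beams
#'
#' Beam definitions used throughout: the two kV tube spectra with their
#' cabinet geometry and the 4 MV linac spectrum with the through-table
#' geometry.
#'
#' @return named list: for each beam, \code{spectrum}, \code{stack} and
#'   the default fine-stage electron count.
#' @export
study_beams <- function() {
  list(
    `40kVp` = list(spectrum = build_kvp_spectrum(40, label = "40kVp"),
                   stack = sarrp_stack(), n_electrons = 10000),
    `220kVp` = list(spectrum = build_kvp_spectrum(220, label = "220kVp"),
                    stack = sarrp_stack(), n_electrons = 10000),
    `4MV` = list(spectrum = mv4_spectrum(), stack = linac_stack(),
                 n_electrons = 50000)
  )
}

#' Sample fine-stage electron sources from a phase space
#'
#' Draws electrons for the single-nucleus damage stage: z and direction
#' come from the phase-space record (z in the layer frame, nucleus
#' centered mid-layer), x-y are resampled uniformly inside the nucleus
#' footprint, matching the restriction of the source to the nucleus
#' dimensions.
#'
#' @param ps phase-space data.frame.
#' @param n number of electrons.
#' @param a_um,b_um nucleus semi-axes (um).
#' @param layer_z_um layer thickness (um).
#' @return data.frame \code{x_nm, y_nm, z_nm, ux, uy, uz, E_keV}.
#' @export
sample_electron_sources <- function(ps, n, a_um = 9.5, b_um = 5.1,
                                    layer_z_um = 5) {
  stopifnot(nrow(ps) > 0)
  idx <- sample.int(nrow(ps), n, replace = TRUE)
  # uniform inside the ellipse by rejection
  xs <- numeric(n); ys <- numeric(n); got <- 0
  while (got < n) {
    m <- (n - got) * 2
    x <- stats::runif(m, -a_um, a_um); y <- stats::runif(m, -b_um, b_um)
    ok <- (x / a_um)^2 + (y / b_um)^2 <= 1
    k <- min(sum(ok), n - got)
    if (k > 0) {
      xs[got + seq_len(k)] <- x[ok][seq_len(k)]
      ys[got + seq_len(k)] <- y[ok][seq_len(k)]
      got <- got + k
    }
  }
  data.frame(
    x_nm = xs * 1000, y_nm = ys * 1000,
    z_nm = (ps$z_um[idx] - layer_z_um / 2) * 1000,
    ux = ps$ux[idx], uy = ps$uy[idx], uz = ps$uz[idx],
    E_keV = ps$E_keV[idx]
  )
}

#' Single-track specific energies without chemistry
#'
#' Transports electrons from the source table and scores the energy each
#' track deposits inside the nucleus (elliptical cylinder at the
#' origin), as specific energy z1 in Gy.  The cheap route to
#' microdosimetric spreads: no genome, no radiolysis.
#'
#' @param sources electron source table from
#'   \code{\link{sample_electron_sources}}.
#' @param a_um,b_um,h_um nucleus semi-axes and height (um).
#' @return numeric vector of z1 (Gy), one per source electron.
#' @export
score_track_doses <- function(sources, a_um = 9.5, b_um = 5.1, h_um = 2.0) {
  mass_kg <- pi * a_um * b_um * h_um * 1e-15
  bbox <- c(-(a_um + 1) * 1000, (a_um + 1) * 1000,
            -(b_um + 1) * 1000, (b_um + 1) * 1000, -2500, 2500)
  vapply(seq_len(nrow(sources)), function(i) {
    tr <- transport_electron(min(sources$E_keV[i], 1000),
                             position_nm = c(sources$x_nm[i],
                                             sources$y_nm[i],
                                             sources$z_nm[i]),
                             direction = c(sources$ux[i], sources$uy[i],
                                           sources$uz[i]),
                             bbox_nm = bbox, track_id = i)
    s <- tr$sites
    inside <- (s$x_nm / (a_um * 1000))^2 + (s$y_nm / (b_um * 1000))^2 <= 1 &
      abs(s$z_nm) <= h_um * 500
    sum(s$energy_eV[inside]) * EV_TO_J / mass_kg
  }, numeric(1))
}

#' Single-nucleus damage chain for one beam
#'
#' Transports electrons sampled from the phase space through the layer
#' water around and inside one nucleus (fine tier, 7.4 eV cut), scores
#' direct backbone breaks (> 17.5 eV cumulated), runs the radiolysis
#' chemistry to the *longest* requested end-time and scores indirect
#' breaks at every requested end-time from the same encounter record
#' (so longer end-times always contain the shorter ones' damage), then
#' clusters breaks into DSBs per track and accumulates yields with
#' 10-batch errors.  Electron energies above the 1 MeV fine-stage bound
#' are clamped to 1 MeV (the stopping power is nearly flat there, so
#' energy deposition over a 2 um nucleus is unaffected).
#'
#' @param sources electron source table from
#'   \code{\link{sample_electron_sources}}.
#' @param genome a \code{genome_model}.
#' @param chem_cfg a \code{\link{chemistry_config}}; its end time is the
#'   longest scoring time.
#' @param end_times_ns end-times at which to score damage (ns).
#' @param n_batches batch count for errors.
#' @param eps_bp DSB clustering radius (bp).
#' @param threshold_eV direct-break threshold (eV).
#' @return object of class \code{damage_run}.
#' @export
run_damage_chain <- function(sources, genome,
                             chem_cfg = chemistry_config(end_time_ns = 10),
                             end_times_ns = c(2.5, 10), n_batches = 10,
                             eps_bp = 10, threshold_eV = 17.5) {
  stopifnot(max(end_times_ns) <= chem_cfg$end_time_ns)
  n <- nrow(sources)
  mass_kg <- pi * genome$a_um * genome$b_um * genome$h_um * 1e-15
  bbox <- c(-(genome$a_um + 1) * 1000, (genome$a_um + 1) * 1000,
            -(genome$b_um + 1) * 1000, (genome$b_um + 1) * 1000,
            -2500, 2500)
  per_track <- vector("list", n)
  breaks_direct <- vector("list", n)
  enc_all <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- transport_electron(min(sources$E_keV[i], 1000),
                             position_nm = c(sources$x_nm[i],
                                             sources$y_nm[i],
                                             sources$z_nm[i]),
                             direction = c(sources$ux[i], sources$uy[i],
                                           sources$uz[i]),
                             bbox_nm = bbox, track_id = i)
    sites <- tr$sites
    vox <- genome_voxel_at(genome, sites$x_nm / 1000, sites$y_nm / 1000,
                           sites$z_nm / 1000)
    in_nuc <- vox > 0
    z1 <- sum(sites$energy_eV[in_nuc]) * EV_TO_J / mass_kg
    per_track[[i]] <- data.frame(track_id = i, E_keV = sources$E_keV[i],
                                 z1_Gy = z1, n_sites = sum(in_nuc))
    nuc_sites <- sites[in_nuc, , drop = FALSE]
    nuc_sites$track_id <- rep(i, nrow(nuc_sites))
    hits <- assign_hits(nuc_sites, genome)
    breaks_direct[[i]] <- score_direct_breaks(hits, threshold_eV)
    sp <- initialize_species(nuc_sites, chem_cfg)
    chem <- run_chemistry(sp, genome, chem_cfg, track_id = i)
    enc_all[[i]] <- chem$encounters
  }
  per_track <- do.call(rbind, per_track)
  encounters <- do.call(rbind, enc_all)
  direct <- do.call(rbind, breaks_direct)
  dose_total <- sum(per_track$z1_Gy)
  batch_of <- ((seq_len(n) - 1) %% n_batches) + 1
  dose_batch <- as.numeric(rowsum(per_track$z1_Gy, batch_of))

  res <- list()
  for (tt in sort(end_times_ns)) {
    indirect <- score_indirect_breaks(encounters, chem_cfg$p_indirect_break,
                                      end_time_ns = tt)
    all_breaks <- merge_breaks(direct, indirect)
    # cluster per track: tracks are independent events in separate cells
    dsb_list <- list(); n_ssb <- 0L
    for (tid in unique(all_breaks$track_id)) {
      cl <- cluster_dsb(all_breaks[all_breaks$track_id == tid, , drop = FALSE],
                        eps_bp)
      if (nrow(cl$dsb)) {
        cl$dsb$track_id <- tid
        dsb_list[[length(dsb_list) + 1]] <- cl$dsb
      }
      n_ssb <- n_ssb + cl$n_ssb
    }
    dsb <- if (length(dsb_list)) do.call(rbind, dsb_list) else
      cluster_dsb(all_breaks[0, ])$dsb
    nb <- if (nrow(dsb)) {
      tabulate(batch_of[dsb$track_id], nbins = n_batches)
    } else rep(0, n_batches)
    pos <- dose_batch > 0   # tiny runs can leave a batch with no deposit
    yld <- compute_yields(nb[pos], dose_batch[pos], genome$total_bp / 1e9,
                          n_simple = sum(dsb$complexity == "simple"),
                          n_complex = sum(dsb$complexity == "complex"))
    res[[as.character(tt)]] <- list(
      dsb = dsb, n_ssb = n_ssb,
      n_breaks = nrow(all_breaks),
      n_direct = nrow(direct),
      n_indirect = nrow(indirect),
      yield = yld,
      chromatin_split = summarize_chromatin_split(dsb, genome)
    )
  }
  structure(list(per_track = per_track, dose_total_Gy = dose_total,
                 dose_batch_Gy = dose_batch, end_times = res,
                 n_electrons = n),
            class = "damage_run")
}

#' @export
print.damage_run <- function(x, ...) {
  cat(sprintf("<damage_run: %d electrons, total dose %.3g Gy>\n",
              x$n_electrons, x$dose_total_Gy))
  for (tt in names(x$end_times)) {
    y <- x$end_times[[tt]]$yield
    cat(sprintf("  %s ns: %.2f +/- %.2f DSB/Gy/Gbp, %d DSBs (%d direct + %d indirect breaks)\n",
                tt, y$dsb_per_gy_per_gbp, y$sd_of_mean,
                nrow(x$end_times[[tt]]$dsb), x$end_times[[tt]]$n_direct,
                x$end_times[[tt]]$n_indirect))
  }
  invisible(x)
}

#' Microdosimetric spread versus dose for a beam
#'
#' Builds the compound-Poisson population for each dose from the
#' single-track specific energies of a damage run (or any z1 sample) and
#' reports the spread; the first dose is also propagated through the
#' pair-cumulation chain as a cross-check.
#'
#' @param z1_samples single-track specific energies (Gy).
#' @param doses_Gy doses (Gy), ascending.
#' @param n_nuclei population size per dose.
#' @return data.frame with \code{dose_Gy, method, mean_z, sigma_z,
#'   sigma_z_rel, n_nuclei}.
#' @export
sigma_zrel_vs_dose <- function(z1_samples, doses_Gy = c(0.25, 0.5, 1, 2),
                               n_nuclei = 4000) {
  z1 <- z1_samples[z1_samples > 0]
  out <- list()
  for (D in doses_Gy) {
    p <- compound_poisson_population(z1, D, n_nuclei)
    out[[length(out) + 1]] <- data.frame(
      dose_Gy = D, method = "compound_poisson", mean_z = p$mean_z,
      sigma_z = p$sigma_z, sigma_z_rel = p$sigma_z_rel,
      n_nuclei = length(p$z_Gy))
  }
  pop <- compound_poisson_population(z1, doses_Gy[1], n_nuclei)
  while (2 * pop$D_Gy <= max(doses_Gy) + 1e-9) {
    pop <- cumulate_pairs(pop)
    out[[length(out) + 1]] <- data.frame(
      dose_Gy = pop$D_Gy, method = "pair_cumulation", mean_z = pop$mean_z,
      sigma_z = pop$sigma_z, sigma_z_rel = pop$sigma_z_rel,
      n_nuclei = length(pop$z_Gy))
  }
  do.call(rbind, out)
}

#' Experiment configuration
#'
#' One structured configuration driving the full chain; serializable to
#' YAML with \code{\link{write_config}} (round-trip stable).
#'
#' @param beams beam names (subset of \code{names(study_beams())}).
#' @param doses_Gy microdosimetry doses.
#' @param n_photons coarse-stage photon count per beam.
#' @param n_electrons fine-stage electron count per beam (named vector or
#'   single number).
#' @param end_times_ns chemistry scoring end-times.
#' @param n_nuclei microdosimetry population size.
#' @param seed root seed (per-stage child streams derive from it).
#' @param out_dir output directory for report files.
#' @return list of class \code{experiment_config}.
#' @export
experiment_config <- function(beams = c("40kVp", "220kVp", "4MV"),
                              doses_Gy = c(0.25, 0.5, 1, 2),
                              n_photons = 2e6,
                              n_electrons = c(`40kVp` = 300, `220kVp` = 300,
                                              `4MV` = 1500),
                              end_times_ns = c(2.5, 10),
                              n_nuclei = 4000, seed = 1,
                              out_dir = "results") {
  stopifnot(all(doses_Gy > 0))
  structure(list(beams = beams, doses_Gy = doses_Gy,
                 n_photons = n_photons, n_electrons = n_electrons,
                 end_times_ns = end_times_ns, n_nuclei = n_nuclei,
                 seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

#' Write / read an experiment configuration (YAML)
#' @param cfg an \code{experiment_config}.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$n_electrons <- as.list(x$n_electrons)   # keep beam names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$n_electrons <- unlist(x$n_electrons)
  do.call(experiment_config, x)
}

#' Run the full pipeline for one configuration
#'
#' For every configured beam: build the spectrum, generate the phase
#' space, run the single-nucleus damage chain at all end-times, compute
#' the microdosimetric spread versus dose, and assemble report tables
#' (interaction partition, yields, per-nucleus counts beside the
#' packaged experimental foci, RBE against the 4 MV reference).
#' Deterministic for a fixed seed.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @param write if TRUE, write CSV tables and a digest under
#'   \code{cfg$out_dir}.
#' @return list with \code{partition}, \code{microdose}, \code{damage},
#'   \code{yields}, \code{foci_comparison}, \code{rbe} tables.
#' @export
run_pipeline <- function(cfg = experiment_config(), write = FALSE) {
  beams <- study_beams()[cfg$beams]
  nele <- cfg$n_electrons
  if (is.null(names(nele))) nele <- stats::setNames(rep(nele[1],
                                                        length(beams)),
                                                    names(beams))
  partition <- list(); micro <- list(); runs <- list()
  for (bn in names(beams)) {
    b <- beams[[bn]]
    pr <- partition_interactions(b$spectrum)
    set.seed(child_seed(cfg$seed, paste0("phase_space_", bn)))
    ps <- generate_phase_space(b$spectrum, b$stack, cfg$n_photons)
    partition[[bn]] <- data.frame(
      beam = bn, mean_photon_keV = b$spectrum$mean_energy,
      pct_pe = 100 * pr$p_photoelectric, pct_ce = 100 * pr$p_compton,
      pct_conv = 100 * pr$p_pair,
      mean_electron_keV = mean(ps$E_keV),
      frac_sub10keV = mean(ps$E_keV <= 10),
      frac_created_inside = mean(ps$origin_flag == "created_inside"))
    set.seed(child_seed(cfg$seed, paste0("damage_", bn)))
    genome <- build_genome()
    src <- sample_electron_sources(ps, nele[[bn]])
    run <- run_damage_chain(src, genome,
                            chemistry_config(end_time_ns =
                                               max(cfg$end_times_ns)),
                            end_times_ns = cfg$end_times_ns)
    runs[[bn]] <- run
    set.seed(child_seed(cfg$seed, paste0("microdose_", bn)))
    ms <- sigma_zrel_vs_dose(run$per_track$z1_Gy, cfg$doses_Gy,
                             cfg$n_nuclei)
    ms$beam <- bn
    micro[[bn]] <- ms
  }
  yields <- do.call(rbind, lapply(names(runs), function(bn) {
    do.call(rbind, lapply(names(runs[[bn]]$end_times), function(tt) {
      y <- runs[[bn]]$end_times[[tt]]$yield
      data.frame(beam = bn, end_time_ns = as.numeric(tt),
                 dsb_per_gy_per_gbp = y$dsb_per_gy_per_gbp,
                 sd = y$sd_of_mean,
                 simple_pct = 100 * y$simple_fraction,
                 complex_pct = 100 * y$complex_fraction,
                 dsb_per_nucleus_1Gy = y$dsb_per_nucleus_1Gy)
    }))
  }))
  foci <- experimental_foci()
  foci1 <- foci[foci$dose_Gy == 1, ]
  foci_cmp <- merge(yields, foci1[, c("beam", "foci_mean", "foci_se")],
                    by = "beam")
  ref <- "4MV"
  rbe <- NULL
  if (ref %in% names(runs)) {
    rbe <- do.call(rbind, lapply(setdiff(names(runs), ref), function(bn) {
      do.call(rbind, lapply(names(runs[[bn]]$end_times), function(tt) {
        r <- compute_rbe(runs[[bn]]$end_times[[tt]]$yield,
                         runs[[ref]]$end_times[[tt]]$yield)
        data.frame(beam = bn, reference = ref,
                   end_time_ns = as.numeric(tt), rbe = r$rbe, sd = r$sd)
      }))
    }))
  }
  out <- list(partition = do.call(rbind, partition),
              microdose = do.call(rbind, micro),
              damage = runs, yields = yields,
              foci_comparison = foci_cmp, rbe = rbe)
  if (write) make_report(out, cfg$out_dir)
  out
}

#' Write report tables and a plain-text digest
#'
#' @param results output of \code{\link{run_pipeline}}.
#' @param out_dir directory (created if absent).
#' @return invisibly, the paths written.
#' @export
make_report <- function(results, out_dir = "results") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$partition, "interaction_partition.csv")
  wr(results$microdose, "microdose_summary.csv")
  wr(results$yields, "dsb_yields.csv")
  wr(results$foci_comparison, "foci_comparison.csv")
  if (!is.null(results$rbe)) wr(results$rbe, "rbe.csv")
  dig <- file.path(out_dir, "digest.txt")
  con <- file(dig, "w")
  writeLines("DSB yield and microdosimetry digest", con)
  for (i in seq_len(nrow(results$yields))) {
    y <- results$yields[i, ]
    writeLines(sprintf(
      "  %s @ %g ns: %.2f +/- %.2f DSB/Gy/Gbp (%.0f%% simple)",
      y$beam, y$end_time_ns, y$dsb_per_gy_per_gbp, y$sd, y$simple_pct), con)
  }
  if (!is.null(results$rbe)) {
    for (i in seq_len(nrow(results$rbe))) {
      r <- results$rbe[i, ]
      writeLines(sprintf("  RBE %s vs %s @ %g ns: %.2f +/- %.2f",
                         r$beam, r$reference, r$end_time_ns, r$rbe, r$sd),
                 con)
    }
  }
  close(con)
  paths <- c(paths, dig)
  invisible(paths)
}
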