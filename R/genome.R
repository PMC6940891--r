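# Statistical chromatin-resolved genome target: a 6 Gbp genome
# partitioned into voxel domains of euchromatin and heterochromatin
# inside one nucleus phantom, mapping energy-deposition sites to
# nucleotide coordinates without atomistic geometry.

#' Build a statistical genome model for one nucleus
#'
#' Voxelizes the nucleus (elliptical cylinder centered at the origin) and
#' labels voxels euchromatin/heterochromatin uniformly at random with
#' volume fractions derived from the genomic class fractions and the
#' compaction (density) ratio.  Genomic coordinates are assigned
#' contiguously in voxel scan order, each class sharing its bp content
#' equally among its voxels, so the domain intervals partition [0, 6e9).
#' Within a voxel, bp positions map locality-preservingly onto a 10 nm
#' sub-lattice so that physically close depositions receive nearby bp
#' indices (10 bp corresponds to a few nm of chromatin).
#'
#' @param a_um,b_um,h_um nucleus semi-axes and height (um).
#' @param eu_fraction,het_fraction genomic class fractions (sum to 1).
#' @param total_bp genome size (bp).
#' @param voxel_um chromatin domain voxel size (um).
#' @param het_eu_density_ratio heterochromatin:euchromatin DNA density
#'   ratio (compaction).
#' @param hit_prob_eu probability that a deposition site in a euchromatin
#'   voxel hits DNA-associated volume; the heterochromatin probability is
#'   this times the density ratio.  Calibrated so that strand-break
#'   yields land in the low-LET literature band (see the calibration
#'   script under analysis/).
#' @param subvolume_fractions named fractions of DNA-associated volume
#'   for \code{deoxyribose}, \code{phosphate}, \code{hydration_shell},
#'   \code{base}, \code{histone}.
#' @return object of class \code{genome_model}.
#' @export
build_genome <- function(a_um = 9.5, b_um = 5.1, h_um = 2.0,
                         eu_fraction = 0.52, het_fraction = 0.48,
                         total_bp = 6e9, voxel_um = 0.25,
                         het_eu_density_ratio = 2,
                         hit_prob_eu = 0.020,
                         subvolume_fractions = c(deoxyribose = 0.30,
                                                 phosphate = 0.30,
                                                 hydration_shell = 0.25,
                                                 base = 0.10,
                                                 histone = 0.05)) {
  stopifnot(abs(eu_fraction + het_fraction - 1) < 1e-9,
            voxel_um > 0, het_eu_density_ratio > 0)
  if (voxel_um > min(a_um, b_um, h_um))
    stop("voxel size larger than nucleus")
  stopifnot(abs(sum(subvolume_fractions) - 1) < 1e-9)
  nx <- ceiling(2 * a_um / voxel_um)
  ny <- ceiling(2 * b_um / voxel_um)
  nz <- ceiling(h_um / voxel_um)
  ox <- -nx * voxel_um / 2; oy <- -ny * voxel_um / 2; oz <- -nz * voxel_um / 2
  gx <- ox + (seq_len(nx) - 0.5) * voxel_um
  gy <- oy + (seq_len(ny) - 0.5) * voxel_um
  gz <- oz + (seq_len(nz) - 0.5) * voxel_um
  grid <- expand.grid(x = gx, y = gy, z = gz)
  inside <- (grid$x / a_um)^2 + (grid$y / b_um)^2 <= 1 &
            abs(grid$z) <= h_um / 2
  vox_idx <- which(inside)
  nvox <- length(vox_idx)
  # volume fractions from genomic fractions and the compaction ratio
  v_eu <- eu_fraction / (eu_fraction + het_fraction / het_eu_density_ratio)
  is_eu <- stats::runif(nvox) < v_eu
  n_eu <- sum(is_eu); n_het <- nvox - n_eu
  if (n_eu == 0 && eu_fraction > 0) is_eu[1] <- TRUE
  bp_per <- ifelse(is_eu, eu_fraction * total_bp / max(n_eu, 1),
                   het_fraction * total_bp / max(n_het, 1))
  bp_end <- cumsum(bp_per)
  bp_start <- c(0, bp_end[-nvox])
  # integer lattice -> voxel row lookup
  lattice <- integer(nx * ny * nz)
  lattice[vox_idx] <- seq_len(nvox)
  voxels <- data.frame(
    id = seq_len(nvox),
    x_um = grid$x[vox_idx], y_um = grid$y[vox_idx], z_um = grid$z[vox_idx],
    class = ifelse(is_eu, "euchromatin", "heterochromatin"),
    bp_start = bp_start, bp_end = bp_end
  )
  nucleus_volume_um3 <- pi * a_um * b_um * h_um
  dens <- c(
    euchromatin = eu_fraction * total_bp / (v_eu * nucleus_volume_um3),
    heterochromatin = het_fraction * total_bp /
      ((1 - v_eu) * nucleus_volume_um3)
  )   # bp/um^3
  structure(list(
    voxels = voxels, lattice = lattice, dims = c(nx, ny, nz),
    origin_um = c(ox, oy, oz), voxel_um = voxel_um,
    a_um = a_um, b_um = b_um, h_um = h_um,
    total_bp = total_bp,
    eu_fraction = eu_fraction, het_fraction = het_fraction,
    density_bp_um3 = dens,
    het_eu_density_ratio = het_eu_density_ratio,
    hit_prob = c(euchromatin = hit_prob_eu,
                 heterochromatin = hit_prob_eu * het_eu_density_ratio),
    subvolume_fractions = subvolume_fractions,
    subcell_nm = 10
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model: %.3g bp in %d voxels (%.0f%% eu / %.0f%% het by bp), voxel %.2f um>\n",
    x$total_bp, nrow(x$voxels), 100 * x$eu_fraction, 100 * x$het_fraction,
    x$voxel_um))
  invisible(x)
}

# voxel row index for positions in the nucleus frame (um); 0 = outside
genome_voxel_at <- function(genome, x_um, y_um, z_um) {
  d <- genome$dims; o <- genome$origin_um; v <- genome$voxel_um
  ix <- floor((x_um - o[1]) / v); iy <- floor((y_um - o[2]) / v)
  iz <- floor((z_um - o[3]) / v)
  ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
  out <- integer(length(x_um))
  lin <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
  out[ok] <- genome$lattice[lin]
  out
}

# locality-preserving bp coordinate for positions inside a voxel:
# positions share a 10 nm sub-cell -> bp indices within ~ one cell's
# bp content of each other
genome_bp_at <- function(genome, vox_row, x_um, y_um, z_um) {
  v <- genome$voxels[vox_row, ]
  sub <- genome$subcell_nm / 1000          # um
  nsub <- max(1L, as.integer(round(genome$voxel_um / sub)))
  lx <- pmin(nsub - 1L, pmax(0L, floor((x_um - (v$x_um - genome$voxel_um / 2)) / sub)))
  ly <- pmin(nsub - 1L, pmax(0L, floor((y_um - (v$y_um - genome$voxel_um / 2)) / sub)))
  lz <- pmin(nsub - 1L, pmax(0L, floor((z_um - (v$z_um - genome$voxel_um / 2)) / sub)))
  cell <- lx + nsub * (ly + nsub * lz)
  ncell <- nsub^3
  bp_cell <- (v$bp_end - v$bp_start) / ncell
  floor(v$bp_start + (cell + stats::runif(length(vox_row))) * bp_cell)
}

#' Map deposition sites to DNA hits
#'
#' Each site inside the nucleus hits DNA-associated volume with the
#' voxel-class hit probability; given a hit, the subvolume is chosen per
#' the configured fractions, the strand is Bernoulli(1/2) and the bp
#' index is drawn locality-preservingly within the voxel's genomic
#' interval.  Sites outside every voxel return no hit.
#'
#' @param sites data.frame with \code{x_nm, y_nm, z_nm, energy_eV} and
#'   optionally \code{track_id} (positions in the nucleus frame).
#' @param genome a \code{\link{build_genome}} model.
#' @param force_hit if TRUE every inside-site hits DNA (diagnostics).
#' @return data.frame of hits: \code{track_id, bp_index, strand,
#'   subvolume, energy_eV, class, voxel_id}.
#' @export
assign_hits <- function(sites, genome, force_hit = FALSE) {
  n <- nrow(sites)
  empty <- data.frame(track_id = integer(0), bp_index = numeric(0),
                      strand = integer(0), subvolume = character(0),
                      energy_eV = numeric(0), class = character(0),
                      voxel_id = integer(0))
  if (n == 0) return(empty)
  x <- sites$x_nm / 1000; y <- sites$y_nm / 1000; z <- sites$z_nm / 1000
  vr <- genome_voxel_at(genome, x, y, z)
  inside <- vr > 0
  if (!any(inside)) return(empty)
  cls <- genome$voxels$class[vr[inside]]
  p <- if (force_hit) rep(1, sum(inside)) else unname(genome$hit_prob[cls])
  hit <- stats::runif(sum(inside)) < p
  if (!any(hit)) return(empty)
  idx <- which(inside)[hit]
  vh <- vr[idx]
  sv <- sample(names(genome$subvolume_fractions), length(idx), replace = TRUE,
               prob = genome$subvolume_fractions)
  data.frame(
    track_id = if ("track_id" %in% names(sites)) sites$track_id[idx] else 1L,
    bp_index = genome_bp_at(genome, vh, x[idx], y[idx], z[idx]),
    strand = as.integer(stats::runif(length(idx)) < 0.5),
    subvolume = sv,
    energy_eV = sites$energy_eV[idx],
    class = genome$voxels$class[vh],
    voxel_id = vh
  )
}

#' Shift all genomic intervals by a constant (mod genome size)
#'
#' Used to verify translation invariance of downstream damage counts.
#'
#' @param genome a \code{genome_model}.
#' @param offset_bp shift in bp.
#' @return shifted \code{genome_model}.
#' @export
genome_shift <- function(genome, offset_bp) {
  g <- genome
  g$voxels$bp_start <- (g$voxels$bp_start + offset_bp) %% g$total_bp
  g$voxels$bp_end <- g$voxels$bp_start +
    (genome$voxels$bp_end - genome$voxels$bp_start)
  g
}

#' Chromatin class at genomic coordinates
#' @param genome a \code{genome_model}.
#' @param bp_index bp coordinates.
#' @return character vector of classes (NA outside all intervals).
#' @export
genome_class_at_bp <- function(genome, bp_index) {
  v <- genome$voxels[order(genome$voxels$bp_start), ]
  i <- findInterval(bp_index, v$bp_start)
  cls <- rep(NA_character_, length(bp_index))
  ok <- i >= 1 & bp_index < v$bp_end[pmax(i, 1)]
  cls[ok] <- v$class[i[ok]]
  cls
}
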