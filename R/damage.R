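# Strand-break scoring and DSB clustering: direct breaks from cumulated
# backbone energy above 17.5 eV, indirect breaks from OH attack, a
# density-based scan (eps < 10 bp, minimum 2 breaks) with the
# opposite-strand rule, complexity classification, yields per Gy per
# Gbp, per-nucleus counts and RBE with batch statistics.

#' Score direct strand breaks from DNA hits
#'
#' Energies deposited in the 2-deoxyribose, phosphate and hydration-shell
#' subvolumes of the same nucleotide (bp index and strand) are summed; a
#' break registers when the cumulated energy exceeds the threshold
#' (strictly greater than 17.5 eV by default).  Base and histone hits
#' never contribute.
#'
#' @param hits data.frame from \code{\link{assign_hits}}.
#' @param threshold_eV energy threshold (eV).
#' @return data.frame of breaks: \code{bp_index, strand, origin,
#'   track_id, class}.
#' @export
score_direct_breaks <- function(hits, threshold_eV = 17.5) {
  empty <- data.frame(bp_index = numeric(0), strand = integer(0),
                      origin = character(0), track_id = integer(0),
                      class = character(0))
  if (nrow(hits) == 0) return(empty)
  if (any(hits$energy_eV < 0)) stop("negative hit energy")
  bb <- hits[hits$subvolume %in%
               c("deoxyribose", "phosphate", "hydration_shell"), ,
             drop = FALSE]
  if (nrow(bb) == 0) return(empty)
  key <- paste(bb$bp_index, bb$strand, sep = "_")
  tot <- rowsum(bb$energy_eV, key)
  broken <- rownames(tot)[tot[, 1] > threshold_eV]
  if (!length(broken)) return(empty)
  first <- bb[match(broken, key), ]
  data.frame(bp_index = first$bp_index, strand = first$strand,
             origin = rep("direct", length(broken)),
             track_id = first$track_id, class = first$class)
}

#' Merge direct and indirect strand breaks
#'
#' A nucleotide site is either broken or not: duplicate breaks at one
#' (bp, strand) merge into one, keeping the first origin encountered
#' (direct before indirect).
#'
#' @param ... break data.frames.
#' @return deduplicated break data.frame.
#' @export
merge_breaks <- function(...) {
  br <- do.call(rbind, Filter(Negate(is.null), list(...)))
  if (is.null(br) || nrow(br) == 0) {
    return(data.frame(bp_index = numeric(0), strand = integer(0),
                      origin = character(0), track_id = integer(0),
                      class = character(0)))
  }
  br <- br[!duplicated(paste(br$bp_index, br$strand)), , drop = FALSE]
  rownames(br) <- NULL
  br
}

#' Cluster strand breaks into double-strand breaks
#'
#' Density-based scan over bp coordinates with neighborhood
#' \code{|delta bp| < eps_bp} and a minimum of two breaks: in one genomic
#' dimension this is transitive chaining of breaks whose consecutive
#' gaps are below eps.  Clusters whose members all lie on one strand are
#' not DSBs (they remain single-strand breaks and are reported
#' separately); clusters with both strands are DSBs, simple when they
#' contain exactly two breaks and complex when three or more.
#'
#' @param breaks deduplicated break data.frame.
#' @param eps_bp neighborhood radius in bp (strict \code{<}, default 10).
#' @return list with \code{dsb} (data.frame: cluster_id, start_bp,
#'   end_bp, centroid_bp, n_breaks, complexity), \code{n_ssb} (breaks
#'   not in any DSB), and \code{members} (per-DSB break rows).
#' @export
cluster_dsb <- function(breaks, eps_bp = 10) {
  if (nrow(breaks) == 0) {
    return(list(dsb = data.frame(cluster_id = integer(0),
                                 start_bp = numeric(0), end_bp = numeric(0),
                                 centroid_bp = numeric(0),
                                 n_breaks = integer(0),
                                 complexity = character(0)),
                n_ssb = 0L, members = list()))
  }
  o <- order(breaks$bp_index, breaks$strand)
  b <- breaks[o, , drop = FALSE]
  gap_new <- c(TRUE, diff(b$bp_index) >= eps_bp)
  comp <- cumsum(gap_new)
  dsb_rows <- list(); members <- list()
  n_ssb <- 0L
  cid <- 0L
  for (g in unique(comp)) {
    rows <- b[comp == g, , drop = FALSE]
    if (nrow(rows) >= 2 && length(unique(rows$strand)) == 2) {
      cid <- cid + 1L
      dsb_rows[[cid]] <- data.frame(
        cluster_id = cid, start_bp = min(rows$bp_index),
        end_bp = max(rows$bp_index),
        centroid_bp = mean(rows$bp_index),
        n_breaks = nrow(rows),
        complexity = classify_complexity(nrow(rows))
      )
      members[[cid]] <- rows
    } else {
      n_ssb <- n_ssb + nrow(rows)
    }
  }
  dsb <- if (cid) do.call(rbind, dsb_rows) else
    data.frame(cluster_id = integer(0), start_bp = numeric(0),
               end_bp = numeric(0), centroid_bp = numeric(0),
               n_breaks = integer(0), complexity = character(0))
  list(dsb = dsb, n_ssb = n_ssb, members = members)
}

#' DSB complexity class
#'
#' Simple DSBs contain exactly two strand breaks; complex DSBs contain
#' three or more.
#'
#' @param n_breaks number of member breaks (>= 2).
#' @return \code{"simple"} or \code{"complex"}.
#' @export
classify_complexity <- function(n_breaks) {
  if (any(n_breaks < 2)) stop("a DSB cluster has at least two breaks")
  ifelse(n_breaks == 2, "simple", "complex")
}

#' DSB damage yields with batch statistics
#'
#' Yield = N_DSB / (dose * genome size in Gbp).  Tracks are partitioned
#' into batches by track id; the spread is the standard deviation of the
#' mean over batches.
#'
#' @param n_dsb_per_batch DSB counts per batch.
#' @param dose_per_batch dose (Gy) per batch.
#' @param genome_gbp genome size in Gbp (default 6).
#' @param n_simple,n_complex totals for the complexity split.
#' @return object of class \code{damage_yield} with fields
#'   \code{dsb_per_gy_per_gbp}, \code{sd_of_mean},
#'   \code{simple_fraction}, \code{complex_fraction},
#'   \code{dsb_per_nucleus_1Gy}.
#' @export
compute_yields <- function(n_dsb_per_batch, dose_per_batch, genome_gbp = 6,
                           n_simple = NA, n_complex = NA) {
  stopifnot(length(n_dsb_per_batch) == length(dose_per_batch))
  if (any(dose_per_batch <= 0)) stop("zero or negative batch dose")
  per_batch <- n_dsb_per_batch / (dose_per_batch * genome_gbp)
  y <- sum(n_dsb_per_batch) / (sum(dose_per_batch) * genome_gbp)
  sdm <- if (length(per_batch) > 1) {
    stats::sd(per_batch) / sqrt(length(per_batch))
  } else NA_real_
  ntot <- n_simple + n_complex
  structure(list(
    dsb_per_gy_per_gbp = y,
    sd_of_mean = sdm,
    per_batch = per_batch,
    simple_fraction = if (!is.na(ntot) && ntot > 0) n_simple / ntot else NA,
    complex_fraction = if (!is.na(ntot) && ntot > 0) n_complex / ntot else NA,
    dsb_per_nucleus_1Gy = dsb_per_nucleus(y, 1, genome_gbp)
  ), class = "damage_yield")
}

#' @export
print.damage_yield <- function(x, ...) {
  cat(sprintf(
    "<damage_yield: %.2f +/- %.2f DSB/Gy/Gbp (%.0f%% simple), %.1f DSB/nucleus at 1 Gy>\n",
    x$dsb_per_gy_per_gbp, x$sd_of_mean,
    100 * ifelse(is.na(x$simple_fraction), NA, x$simple_fraction),
    x$dsb_per_nucleus_1Gy))
  invisible(x)
}

#' Per-nucleus DSB count from a yield
#'
#' @param dsb_per_gy_per_gbp yield.
#' @param dose_Gy dose (Gy).
#' @param genome_gbp genome size (Gbp).
#' @return expected DSB count per nucleus.
#' @export
dsb_per_nucleus <- function(dsb_per_gy_per_gbp, dose_Gy = 1,
                            genome_gbp = 6) {
  dsb_per_gy_per_gbp * dose_Gy * genome_gbp
}

#' Relative biological effectiveness between two yields
#'
#' Ratio of DSB yields (test over reference) with the batch
#' uncertainties propagated in quadrature.
#'
#' @param yield_test,yield_reference \code{damage_yield} objects or bare
#'   yield numbers.
#' @param sd_test,sd_reference uncertainties when bare numbers are given.
#' @return list with \code{rbe} and \code{sd}.
#' @export
compute_rbe <- function(yield_test, yield_reference,
                        sd_test = NA, sd_reference = NA) {
  yt <- if (inherits(yield_test, "damage_yield"))
    yield_test$dsb_per_gy_per_gbp else yield_test
  yr <- if (inherits(yield_reference, "damage_yield"))
    yield_reference$dsb_per_gy_per_gbp else yield_reference
  st <- if (inherits(yield_test, "damage_yield"))
    yield_test$sd_of_mean else sd_test
  sr <- if (inherits(yield_reference, "damage_yield"))
    yield_reference$sd_of_mean else sd_reference
  if (yr <= 0) stop("reference yield must be positive")
  r <- yt / yr
  s <- if (!is.na(st) && !is.na(sr)) r * sqrt((st / yt)^2 + (sr / yr)^2)
  else NA_real_
  list(rbe = r, sd = s)
}

#' Euchromatin/heterochromatin split of DSBs
#'
#' Fraction of DSB cluster centroids falling in each chromatin class of
#' the genome model.
#'
#' @param dsb DSB table from \code{\link{cluster_dsb}}.
#' @param genome a \code{genome_model}.
#' @return named vector \code{c(euchromatin = ..., heterochromatin =
#'   ...)} summing to 1 (NaN when there are no DSBs).
#' @export
summarize_chromatin_split <- function(dsb, genome) {
  cls <- genome_class_at_bp(genome, dsb$centroid_bp)
  c(euchromatin = mean(cls == "euchromatin", na.rm = TRUE),
    heterochromatin = mean(cls == "heterochromatin", na.rm = TRUE))
}
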