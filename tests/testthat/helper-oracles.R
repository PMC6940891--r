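# Brute-force transitive-closure clustering oracle: link any two breaks
# with |delta bp| < eps, take connected components, keep components with
# >= 2 members and both strands.
bf_cluster <- function(breaks, eps_bp = 10) {
  n <- nrow(breaks)
  if (n == 0) return(list(sizes = integer(0), assignment = integer(0)))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(breaks$bp_index[i] - breaks$bp_index[j]) < eps_bp &&
            comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keep <- vapply(unique(comp), function(g) {
    m <- breaks[comp == g, , drop = FALSE]
    nrow(m) >= 2 && length(unique(m$strand)) == 2
  }, logical(1))
  dsb_comps <- unique(comp)[keep]
  sizes <- sort(vapply(dsb_comps, function(g) sum(comp == g), integer(1)))
  assignment <- ifelse(comp %in% dsb_comps, comp, NA_integer_)
  list(sizes = sizes, assignment = assignment)
}

random_breaks <- function(n, bp_range = 200) {
  b <- data.frame(bp_index = sample.int(bp_range, n, replace = TRUE),
                  strand = sample(0:1, n, replace = TRUE),
                  origin = "direct", track_id = 1L, class = "euchromatin")
  b[!duplicated(paste(b$bp_index, b$strand)), , drop = FALSE]
}

# canonical partition signature of a DSB clustering, for equality of
# partitions rather than just counts
partition_signature <- function(breaks, members) {
  sig <- lapply(members, function(m) {
    sort(paste(m$bp_index, m$strand, sep = "/"))
  })
  sort(vapply(sig, paste, character(1), collapse = ";"))
}
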