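# Deterministic child-seed derivation: one root seed in a config fans out
# into per-stage streams so stages can be rerun independently.

#' Derive a child seed from a root seed and a stage tag
#'
#' Uses a small multiplicative string hash so that every (root, tag) pair
#' maps reproducibly to a seed in [1, 2^31 - 2].
#'
#' @param root_seed integer root seed.
#' @param tag character stage tag, e.g. "phase_space".
#' @return an integer seed.
#' @export
child_seed <- function(root_seed, tag) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  h <- as.double(root_seed %% 2147483647)
  for (ch in utf8ToInt(tag)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
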