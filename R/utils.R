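# Counter-based child seeds: every stochastic operation takes one integer
# seed derived from the master seed plus a label path, so any cell of a large
# experiment can be reproduced in isolation.

MERSENNE31 <- 2147483647

#' Derive a reproducible child seed
#'
#' Folds a master seed and an arbitrary sequence of labels (strings or
#' numbers) into a single integer seed in `[1, 2^31 - 2]`. The map is
#' deterministic, so the same `(seed, labels)` path always yields the same
#' child seed, and distinct paths almost surely yield distinct seeds.
#'
#' @param seed Integer master seed.
#' @param ... Labels (character or numeric scalars/vectors) identifying the
#'   stochastic operation, e.g. `child_seed(1, "scenario", "5pct", 12)`.
#' @return A single integer usable with [set.seed()].
#' @export
#' @examples
#' child_seed(1, "draw", 10)
child_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  parts <- unlist(lapply(list(...), function(v) {
    if (is.character(v)) utf8ToInt(paste(v, collapse = "/")) else as.numeric(v)
  }), use.names = FALSE)
  h <- abs(as.numeric(seed)) %% MERSENNE31
  for (v in parts) {
    if (!is.finite(v)) abort("child_seed() labels must be finite")
    h <- (h * 48271 + (abs(v) %% MERSENNE31) + 1) %% MERSENNE31
  }
  as.integer(h %% (MERSENNE31 - 2) + 1)
}

# Evaluate `expr` under a fixed RNG seed without touching the caller's RNG
# stream; NULL seed means "use the current stream".
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# kg per tree summed over a 400 m2 plot -> t/ha: divide by plot_area_m2 / 10
kg_to_tha <- function(kg, plot_area_m2) (kg / 1000) / (plot_area_m2 / 10000)
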