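#' Specify a sampling design for two occasions
#'
#' Plot types follow the two-occasion typology: `n_t1_only` plots measured
#' only at occasion 1, `n_permanent` plots remeasured at both occasions, and
#' `n_t2_only` new plots measured only at occasion 2. A temporary-plot
#' design has no permanent plots; CFI has only permanent plots.
#'
#' @param design One of `"temporary"`, `"cfi"`, `"spr"`.
#' @param n_t1_only,n_permanent,n_t2_only Plot-type counts.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(design = c("temporary", "cfi", "spr"),
                        n_t1_only = 0, n_permanent = 0, n_t2_only = 0) {
  design <- match.arg(design)
  d <- list(design = design, n_t1_only = as.integer(n_t1_only),
            n_permanent = as.integer(n_permanent),
            n_t2_only = as.integer(n_t2_only))
  if (any(unlist(d[-1]) < 0)) abort("plot-type counts must be >= 0")
  if (design == "temporary" && d$n_permanent != 0) {
    abort("a temporary-plot design has no permanent plots")
  }
  if (design == "cfi" && (d$n_t1_only != 0 || d$n_t2_only != 0)) {
    abort("a CFI design uses permanent plots only")
  }
  if (design == "temporary" && (d$n_t1_only < 2 || d$n_t2_only < 2)) {
    abort("temporary design needs at least 2 plots per occasion")
  }
  if (design == "cfi" && d$n_permanent < 3) {
    abort("CFI design needs at least 3 permanent plots")
  }
  if (design == "spr" && (d$n_permanent < 3 || d$n_t2_only < 2)) {
    abort("SPR design needs >= 3 permanent and >= 2 new occasion-2 plots")
  }
  structure(d, class = "design_spec")
}

#' The packaged sample-size configuration
#'
#' 375 plots measured per occasion for every design: SPR as 250 permanent
#' plus 125 occasion-specific temporary plots; CFI as 375 permanent; the
#' temporary design as two independent 375-plot samples.
#'
#' @return Named list of [design_spec()] objects.
#' @export
default_designs <- function() {
  list(
    spr = design_spec("spr", n_t1_only = 125, n_permanent = 250, n_t2_only = 125),
    cfi = design_spec("cfi", n_permanent = 375),
    temporary = design_spec("temporary", n_t1_only = 375, n_t2_only = 375)
  )
}

#' Draw sample plot roles for a design
#'
#' All draws are simple random sampling without replacement. CFI draws
#' `n_permanent` plots used at both occasions. The temporary design draws the
#' two occasions independently; chance overlaps stay unmatched. SPR draws
#' `n_permanent + n_t1_only` occasion-1 plots, randomly designates
#' `n_permanent` of them permanent, and draws the `n_t2_only` new occasion-2
#' plots from the plots not sampled at occasion 1.
#'
#' @param n_plots Population size.
#' @param design A [design_spec()].
#' @param seed Integer seed (`NULL` = current RNG stream).
#' @return List with integer id vectors `t1_ids` (all occasion-1 plots),
#'   `permanent_ids` (subset of `t1_ids`), `t2_new_ids`.
#' @export
draw_samples <- function(n_plots, design, seed = NULL) {
  stopifnot(inherits(design, "design_spec"))
  d <- design
  n_t1 <- d$n_t1_only + d$n_permanent
  if (n_t1 > n_plots || d$n_t2_only > n_plots) {
    abort("requested sample sizes exceed the population")
  }
  with_seed_or_not(seed, {
    if (d$design == "cfi") {
      perm <- sample.int(n_plots, d$n_permanent)
      list(t1_ids = perm, permanent_ids = perm, t2_new_ids = integer())
    } else if (d$design == "temporary") {
      list(t1_ids = sample.int(n_plots, d$n_t1_only),
           permanent_ids = integer(),
           t2_new_ids = sample.int(n_plots, d$n_t2_only))
    } else {
      t1 <- sample.int(n_plots, n_t1)
      perm <- sample(t1, d$n_permanent)
      rest <- setdiff(seq_len(n_plots), t1)
      if (d$n_t2_only > length(rest)) {
        abort("not enough unsampled plots for the new occasion-2 sample")
      }
      list(t1_ids = t1, permanent_ids = perm,
           t2_new_ids = rest[sample.int(length(rest), d$n_t2_only)])
    }
  })
}
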