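#' Parameters of the synthetic two-occasion forest population
#'
#' The generator emulates the 750-subplot lowland tropical forest panel used
#' as the study population: an inverse-J (shifted exponential) diameter
#' distribution above a 15 cm calliper threshold, uniform tree mortality
#' between occasions, and positively skewed diameter increments whose mean is
#' modulated by a per-plot multiplicative growth effect. The defaults are
#' calibrated so that a 750-plot population reproduces the published
#' occasion means (120.3 and 132.5 t/ha), tree counts (8650 and 8191) and
#' between-occasion plot correlation (0.804).
#'
#' @param n_plots Number of fixed-area plots.
#' @param plot_area_m2 Plot area, m2.
#' @param trees_per_plot_mean Mean of the per-plot Poisson tree count.
#' @param dbh_min Calliper threshold, cm; no tree below it enters the panel.
#' @param dbh_scale Scale (cm) of the exponential diameter distribution above
#'   `dbh_min`; mean dbh is `dbh_min + dbh_scale`.
#' @param mortality_prob Per-tree probability of dying between occasions.
#' @param growth_mean Mean diameter increment of survivors, cm, at the
#'   population level (the per-plot effect averages to one).
#' @param growth_sd Tree-level SD of the increment, cm.
#' @param plot_growth_sd SD of the per-plot multiplicative growth effect
#'   (gamma with mean 1). This is the knob that lowers the between-occasion
#'   plot correlation; 0 disables it.
#' @return A list of class `population_params`.
#' @export
population_params <- function(n_plots = 750,
                              plot_area_m2 = 400,
                              trees_per_plot_mean = 8650 / 750,
                              dbh_min = 15,
                              dbh_scale = 15.147,
                              mortality_prob = 1 - 8191 / 8650,
                              growth_mean = 2.40,
                              growth_sd = 1.5,
                              plot_growth_sd = 1.90) {
  p <- list(
    n_plots = as.integer(n_plots), plot_area_m2 = plot_area_m2,
    trees_per_plot_mean = trees_per_plot_mean, dbh_min = dbh_min,
    dbh_scale = dbh_scale, mortality_prob = mortality_prob,
    growth_mean = growth_mean, growth_sd = growth_sd,
    plot_growth_sd = plot_growth_sd
  )
  validate_population_params(p)
  structure(p, class = "population_params")
}

validate_population_params <- function(p) {
  if (p$n_plots < 0) abort("`n_plots` must be >= 0")
  for (f in c("plot_area_m2", "trees_per_plot_mean", "dbh_min", "dbh_scale",
              "growth_mean", "growth_sd")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
      abort(paste0("`", f, "` must be a positive number"))
    }
  }
  if (p$mortality_prob < 0 || p$mortality_prob > 1) {
    abort("`mortality_prob` must lie in [0, 1]")
  }
  if (p$plot_growth_sd < 0) abort("`plot_growth_sd` must be >= 0")
  invisible(p)
}

#' Generate a synthetic two-occasion tree population
#'
#' Draws a complete tree list for `n_plots` fixed-area plots at two
#' measurement occasions. Per plot, the tree count is Poisson; occasion-1
#' diameters are `dbh_min + Exponential(dbh_scale)`; each tree survives to
#' occasion 2 with probability `1 - mortality_prob`; survivors grow by a
#' gamma increment with mean `growth_mean * g_p` and tree-level SD
#' `growth_sd`, where `g_p` is the plot's gamma growth effect (mean 1, SD
#' `plot_growth_sd`). Dead trees carry `NA` for `dbh_t2`.
#'
#' @param params A [population_params()] list.
#' @param seed Integer seed; the draw is fully reproducible given
#'   `(params, seed)`. `NULL` uses the current RNG stream.
#' @return A tibble of class `tree_population` with columns `plot_id`,
#'   `tree_id`, `dbh_t1`, `alive_t2`, `dbh_t2` and attributes `n_plots`,
#'   `plot_area_m2`.
#' @export
#' @examples
#' pop <- generate_population(population_params(n_plots = 10), seed = 1)
#' dplyr::count(pop, plot_id)
generate_population <- function(params = population_params(), seed = NULL) {
  validate_population_params(params)
  p <- params
  with_seed_or_not(seed, {
    n_trees <- rpois(p$n_plots, p$trees_per_plot_mean)
    plot_id <- rep(seq_len(p$n_plots), n_trees)
    n <- length(plot_id)
    dbh_t1 <- p$dbh_min + rexp(n, rate = 1 / p$dbh_scale)
    alive_t2 <- runif(n) >= p$mortality_prob
    g_p <- if (p$plot_growth_sd > 0) {
      rgamma(p$n_plots, shape = 1 / p$plot_growth_sd^2,
             scale = p$plot_growth_sd^2)
    } else {
      rep(1, p$n_plots)
    }
    m <- p$growth_mean * g_p[plot_id]
    inc <- numeric(n)
    pos <- m > 0
    if (any(pos)) {
      inc[pos] <- rgamma(sum(pos), shape = (m[pos] / p$growth_sd)^2,
                         scale = p$growth_sd^2 / m[pos])
    }
    dbh_t2 <- ifelse(alive_t2, dbh_t1 + inc, NA_real_)
    trees <- tibble(
      plot_id = plot_id,
      tree_id = if (n > 0) stats::ave(plot_id, plot_id, FUN = seq_along) else integer(),
      dbh_t1 = dbh_t1, alive_t2 = alive_t2, dbh_t2 = dbh_t2
    )
    new_tree_population(trees, p$n_plots, p$plot_area_m2)
  })
}

new_tree_population <- function(trees, n_plots, plot_area_m2) {
  structure(as_tibble(trees),
            n_plots = as.integer(n_plots), plot_area_m2 = plot_area_m2,
            class = c("tree_population", class(as_tibble(trees))))
}

#' Validate and label a tree table as a population
#'
#' @param trees Tibble with columns `plot_id`, `tree_id`, `dbh_t1`,
#'   `alive_t2`, `dbh_t2` (`NA` when dead).
#' @param n_plots Number of plots in the population (ids must lie in
#'   `1..n_plots`); defaults to the largest `plot_id` present.
#' @param plot_area_m2 Plot area, m2.
#' @param dbh_min Calliper threshold used for validation, cm.
#' @return The validated `tree_population` tibble.
#' @export
as_tree_population <- function(trees, n_plots = NULL, plot_area_m2 = 400,
                               dbh_min = 15) {
  trees <- as_tibble(trees)
  need <- c("plot_id", "tree_id", "dbh_t1", "alive_t2", "dbh_t2")
  miss <- setdiff(need, names(trees))
  if (length(miss)) {
    abort(paste("tree table is missing columns:", paste(miss, collapse = ", ")))
  }
  if (is.null(n_plots)) n_plots <- if (nrow(trees)) max(trees$plot_id) else 0L
  if (plot_area_m2 <= 0) abort("`plot_area_m2` must be > 0")
  bad <- which(trees$dbh_t1 < dbh_min | !is.finite(trees$dbh_t1))
  if (length(bad)) {
    abort(paste0("dbh_t1 below the ", dbh_min, " cm threshold (or non-finite) at row ",
                 bad[1]))
  }
  bad <- which(trees$alive_t2 & (is.na(trees$dbh_t2) | trees$dbh_t2 < trees$dbh_t1))
  if (length(bad)) {
    abort(paste0("surviving tree with missing or shrinking dbh_t2 at row ", bad[1]))
  }
  bad <- which(!trees$alive_t2 & !is.na(trees$dbh_t2))
  if (length(bad)) {
    abort(paste0("dead tree carries a dbh_t2 value at row ", bad[1]))
  }
  if (nrow(trees) && (min(trees$plot_id) < 1 || max(trees$plot_id) > n_plots)) {
    abort("`plot_id` values must lie in 1..n_plots")
  }
  if (anyDuplicated(trees[c("plot_id", "tree_id")])) {
    abort(paste0("duplicate (plot_id, tree_id) at row ",
                 anyDuplicated(trees[c("plot_id", "tree_id")])))
  }
  new_tree_population(trees, n_plots, plot_area_m2)
}

n_plots <- function(pop) attr(pop, "n_plots")
plot_area <- function(pop) attr(pop, "plot_area_m2")

# Sum a per-tree kg vector into a full-length per-plot t/ha vector.
plot_totals_tha <- function(pop, kg) {
  np <- n_plots(pop)
  tot <- numeric(np)
  if (nrow(pop)) {
    s <- rowsum(kg, group = pop$plot_id, reorder = FALSE)
    tot[as.integer(rownames(s))] <- s[, 1]
  }
  kg_to_tha(tot, plot_area(pop))
}

#' Per-plot aboveground biomass at one occasion
#'
#' Sums tree biomass ([agb_from_dbh()]) within each plot and expresses it per
#' hectare. Dead trees contribute zero at occasion 2; plots without trees
#' yield 0 t/ha.
#'
#' @param pop A `tree_population`.
#' @param occasion 1 or 2.
#' @return Tibble with `plot_id` and `agb_tha` for every plot.
#' @export
plot_biomass <- function(pop, occasion) {
  stopifnot(inherits(pop, "tree_population"))
  if (!occasion %in% c(1, 2)) abort("`occasion` must be 1 or 2")
  kg <- numeric(nrow(pop))
  if (nrow(pop)) {
    if (occasion == 1) {
      kg <- agb_from_dbh(pop$dbh_t1)
    } else {
      kg[pop$alive_t2] <- agb_from_dbh(pop$dbh_t2[pop$alive_t2])
    }
  }
  tibble(plot_id = seq_len(n_plots(pop)), agb_tha = plot_totals_tha(pop, kg))
}

#' Summary statistics of a two-occasion plot panel
#'
#' Per-occasion count, min, max, mean, median and SD of plot biomass, plus
#' the Pearson correlation between occasion-1 values and the requested
#' occasion-2 variant — the panel analogue of a published plot-statistics
#' table.
#'
#' @param panel A plot panel tibble (see [apply_scenario()]) with columns
#'   `x_t1`, `y_t2_undisturbed`, `y_t2_disturbed`.
#' @param occasion2 Which occasion-2 column to summarise: `"disturbed"`
#'   (default) or `"undisturbed"`.
#' @return Tibble with one row per occasion and a shared `correlation`
#'   column.
#' @export
summarize_panel <- function(panel, occasion2 = c("disturbed", "undisturbed")) {
  occasion2 <- match.arg(occasion2)
  if (nrow(panel) < 2) abort("panel must contain at least 2 plots")
  y <- if (occasion2 == "disturbed") panel$y_t2_disturbed else panel$y_t2_undisturbed
  x <- panel$x_t1
  r <- cor(x, y)
  stats_row <- function(occ, v) {
    tibble(occasion = occ, n = length(v), min = min(v), max = max(v),
           mean = mean(v), median = median(v), sd = sd(v))
  }
  bind_rows(stats_row(1L, x), stats_row(2L, y)) %>%
    mutate(correlation = r)
}
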