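# Monte Carlo comparison of the three designs under disturbance scenarios.
#
# Treatment bias is simulated at its conceivable endpoint: when the bias
# flag is on, every sampled permanent plot observes the undisturbed
# occasion-2 value (no disturbance takes place on plots known to be
# remeasured), while new temporary plots always observe the disturbed
# landscape. True change always refers to the disturbed population.

# Fast inner kernel on cached per-plot scenario values.
iterate_cell <- function(pv, is_aff, design, bias, seed, spr_mode) {
  y_dist <- ifelse(is_aff, pv$y_rule, pv$y_undist)
  roles <- draw_samples(nrow(pv), design, seed = seed)
  y_perm_obs <- if (bias) pv$y_undist else y_dist
  est <- switch(design$design,
    temporary = estimate_temporary(pv$x_t1[roles$t1_ids], y_dist[roles$t2_new_ids]),
    cfi = estimate_cfi(pv$x_t1[roles$permanent_ids],
                       y_perm_obs[roles$permanent_ids]),
    spr = estimate_spr(pv$x_t1[roles$t1_ids],
                       pv$x_t1[roles$permanent_ids],
                       y_perm_obs[roles$permanent_ids],
                       y_dist[roles$t2_new_ids],
                       mode = spr_mode)
  )
  est
}

#' Run one Monte Carlo iteration
#'
#' Draws the affected plots, applies the scenario, draws the sample roles,
#' observes occasion-2 values (undisturbed on sampled permanent plots when
#' `bias` is on), and runs the design's estimator. The affected-plot draw is
#' controlled by `seed_scenario` so that all designs and bias variants of an
#' iteration share the identical true change.
#'
#' @param pop A `tree_population`.
#' @param scenario A [scenario_spec()].
#' @param design A [design_spec()].
#' @param bias Logical; simulate treatment bias on permanent plots.
#' @param seed_scenario Seed for the affected-plot draw.
#' @param seed_sample Seed for the sample-role draw.
#' @param spr_mode SPR change-variance mode, see [spr_change()].
#' @return One-row tibble with the estimate and the true change.
#' @export
run_iteration <- function(pop, scenario, design, bias = FALSE,
                          seed_scenario = NULL, seed_sample = NULL,
                          spr_mode = "corrected") {
  pv <- scenario_plot_values(pop, scenario)
  aff <- select_affected_plots(nrow(pv), scenario$fraction, seed = seed_scenario)
  is_aff <- pv$plot_id %in% aff
  est <- iterate_cell(pv, is_aff, design, bias, seed_sample, spr_mode)
  truth <- mean(ifelse(is_aff, pv$y_rule, pv$y_undist)) - mean(pv$x_t1)
  tibble(scenario = scenario$name, design = design$design, bias = bias,
         change = est$change, variance = est$variance, se = est$se,
         true_change = truth, n_t1 = est$n_t1, n_t2 = est$n_t2)
}

#' Run the full Monte Carlo experiment
#'
#' For every scenario, iteration, design and bias variant: redraw the
#' affected plots (per scenario and iteration, shared across designs), draw
#' the sample, estimate the change. All randomness derives from
#' `master_seed` through labelled child seeds, so any cell is independently
#' reproducible and the run is deterministic end to end.
#'
#' @param pop A `tree_population` (e.g. [generate_population()]).
#' @param scenarios List of [scenario_spec()]; default [default_scenarios()].
#' @param designs List of [design_spec()]; default [default_designs()].
#' @param bias_variants Logical vector, default `c(FALSE, TRUE)`.
#' @param iterations Iterations per combination (the reference experiment
#'   uses 1000).
#' @param master_seed Integer master seed.
#' @param spr_mode SPR change-variance mode.
#' @param fresh_scenario_draw Redraw affected plots every iteration
#'   (default); `FALSE` freezes one disturbed population per scenario.
#' @param progress Emit a message per scenario.
#' @return Tibble of iteration-level results (class `mc_results`), one row
#'   per scenario x iteration x design x bias.
#' @export
run_experiment <- function(pop,
                           scenarios = default_scenarios(),
                           designs = default_designs(),
                           bias_variants = c(FALSE, TRUE),
                           iterations = 1000,
                           master_seed = 1,
                           spr_mode = "corrected",
                           fresh_scenario_draw = TRUE,
                           progress = FALSE) {
  stopifnot(iterations >= 1)
  cells <- length(scenarios) * iterations * length(designs) * length(bias_variants)
  out <- list(
    scenario = character(cells), design = character(cells),
    bias = logical(cells), iteration = integer(cells),
    change = numeric(cells), variance = numeric(cells), se = numeric(cells),
    true_change = numeric(cells)
  )
  k <- 0L
  for (sc in scenarios) {
    if (progress) inform(paste("scenario:", sc$name))
    pv <- scenario_plot_values(pop, sc)
    np <- nrow(pv)
    for (it in seq_len(iterations)) {
      aff_seed <- if (fresh_scenario_draw) {
        child_seed(master_seed, "affected", sc$name, it)
      } else {
        child_seed(master_seed, "affected", sc$name, 1)
      }
      aff <- select_affected_plots(np, sc$fraction, seed = aff_seed)
      is_aff <- pv$plot_id %in% aff
      truth <- mean(ifelse(is_aff, pv$y_rule, pv$y_undist)) - mean(pv$x_t1)
      for (d in designs) {
        for (b in bias_variants) {
          est <- iterate_cell(pv, is_aff, d, b,
                              child_seed(master_seed, "sample", sc$name,
                                         d$design, it),
                              spr_mode)
          k <- k + 1L
          out$scenario[k] <- sc$name
          out$design[k] <- d$design
          out$bias[k] <- b
          out$iteration[k] <- it
          out$change[k] <- est$change
          out$variance[k] <- est$variance
          out$se[k] <- est$se
          out$true_change[k] <- truth
        }
      }
    }
  }
  res <- as_tibble(out)
  class(res) <- c("mc_results", class(res))
  res
}

#' Summarise a Monte Carlo experiment
#'
#' Aggregates iteration-level results into the four reported surfaces per
#' scenario x design x bias cell: mean estimated change, mean (signed and
#' absolute) deviation from the true change, the mean estimate as percent of
#' the true change, and the percent standard error. The percent surfaces use
#' the cell's mean true change as reference magnitude (stable when single
#' estimates cross zero) and are `NA` where the true change is numerically
#' zero.
#'
#' @param results An `mc_results` tibble from [run_experiment()].
#' @return Tibble of class `mc_summary`.
#' @export
summarize_experiment <- function(results) {
  if (min(table(results$scenario, results$design, results$bias)) < 2) {
    abort("need at least 2 iterations per cell to summarise")
  }
  s <- results %>%
    group_by(.data$scenario, .data$design, .data$bias) %>%
    summarise(
      n_iter = dplyr::n(),
      mean_change = mean(.data$change),
      mean_true_change = mean(.data$true_change),
      mean_diff = mean(.data$change - .data$true_change),
      mean_abs_diff = mean(abs(.data$change - .data$true_change)),
      pct_of_true = ifelse(abs(mean(.data$true_change)) > 1e-9,
                           100 * mean(.data$change) / mean(.data$true_change),
                           NA_real_),
      mean_se = mean(.data$se),
      pct_se = ifelse(abs(mean(.data$true_change)) > 1e-9,
                      100 * mean(.data$se) / abs(mean(.data$true_change)),
                      NA_real_),
      empirical_sd = sd(.data$change),
      .groups = "drop"
    )
  class(s) <- c("mc_summary", class(s))
  s
}
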