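#' Define a deforestation or degradation scenario
#'
#' A scenario removes occasion-2 biomass on a randomly chosen fraction of
#' plots according to a diameter rule: `remove_below` zeroes trees with
#' occasion-2 dbh strictly below the threshold (fuelwood harvesting of small
#' stems), `remove_above` zeroes trees strictly above it (selective timber
#' harvesting), `remove_all` clears the plot (deforestation), and `none`
#' leaves the panel untouched. Occasion-1 values are never modified.
#'
#' @param name Label for the scenario.
#' @param fraction Fraction of plots affected, in `[0, 1]`.
#' @param rule One of `"none"`, `"remove_below"`, `"remove_above"`,
#'   `"remove_all"`.
#' @param threshold Diameter threshold, cm; required for the threshold rules.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, fraction = 0, rule = "none", threshold = NULL) {
  rule <- match.arg(rule, c("none", "remove_below", "remove_above", "remove_all"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    abort("`fraction` must lie in [0, 1]")
  }
  if (rule %in% c("remove_below", "remove_above")) {
    if (is.null(threshold) || !is.numeric(threshold) || threshold <= 0) {
      abort(paste0("rule `", rule, "` requires a positive `threshold` (cm)"))
    }
  }
  structure(list(name = name, fraction = fraction, rule = rule,
                 threshold = threshold),
            class = "scenario_spec")
}

#' The six packaged disturbance scenarios
#'
#' No intervention; 10% and 20% degradation removing trees with dbh < 35 cm;
#' 10% and 20% degradation removing trees with dbh > 45 cm; and 5%
#' deforestation clearing whole plots.
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  specs <- list(
    scenario_spec("no_intervention", 0, "none"),
    scenario_spec("deg10_below35", 0.10, "remove_below", 35),
    scenario_spec("deg10_above45", 0.10, "remove_above", 45),
    scenario_spec("deg20_below35", 0.20, "remove_below", 35),
    scenario_spec("deg20_above45", 0.20, "remove_above", 45),
    scenario_spec("defor5", 0.05, "remove_all")
  )
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Draw the plots affected by a disturbance
#'
#' Simple random sampling without replacement of `floor(fraction * n_plots)`
#' plot ids; the disturbance fractions refer to the whole population, not to
#' any sample.
#'
#' @param n_plots Number of plots in the population.
#' @param fraction Fraction affected, in `[0, 1]`.
#' @param seed Integer seed (`NULL` = current RNG stream).
#' @return Sorted integer vector of affected plot ids.
#' @export
#' @examples
#' length(select_affected_plots(750, 0.05, seed = 1)) # 37
select_affected_plots <- function(n_plots, fraction, seed = NULL) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    abort("`fraction` must lie in [0, 1]")
  }
  k <- floor(fraction * n_plots)
  with_seed_or_not(seed, sort(sample.int(n_plots, k)))
}

# Per-tree kept-kg at occasion 2 under a rule (dead trees already 0).
rule_kept_kg <- function(pop, rule, threshold) {
  kg2 <- numeric(nrow(pop))
  kg2[pop$alive_t2] <- agb_from_dbh(pop$dbh_t2[pop$alive_t2])
  keep <- switch(rule,
    none = rep(TRUE, nrow(pop)),
    remove_all = rep(FALSE, nrow(pop)),
    remove_below = !pop$alive_t2 | pop$dbh_t2 >= threshold,
    remove_above = !pop$alive_t2 | pop$dbh_t2 <= threshold
  )
  kg2 * as.numeric(keep)
}

# Plot-level biomass columns needed to realise a scenario: occasion-1,
# undisturbed occasion-2, and occasion-2 after applying the rule. Computing
# these once makes repeated Monte-Carlo draws pure vector arithmetic.
scenario_plot_values <- function(pop, spec) {
  stopifnot(inherits(pop, "tree_population"), inherits(spec, "scenario_spec"))
  kg1 <- if (nrow(pop)) agb_from_dbh(pop$dbh_t1) else numeric()
  kg2 <- numeric(nrow(pop))
  kg2[pop$alive_t2] <- agb_from_dbh(pop$dbh_t2[pop$alive_t2])
  tibble(
    plot_id = seq_len(n_plots(pop)),
    x_t1 = plot_totals_tha(pop, kg1),
    y_undist = plot_totals_tha(pop, kg2),
    y_rule = plot_totals_tha(pop, rule_kept_kg(pop, spec$rule, spec$threshold))
  )
}

#' Apply a disturbance scenario to a population
#'
#' Builds the two-occasion plot panel: occasion-1 biomass, undisturbed
#' occasion-2 biomass, and disturbed occasion-2 biomass in which trees
#' matching the scenario rule contribute zero on affected plots. The
#' threshold test uses occasion-2 diameters by default (removal happens at
#' occasion 2); strict inequalities are used, so trees exactly at the
#' threshold are retained.
#'
#' @param pop A `tree_population`.
#' @param spec A [scenario_spec()].
#' @param affected Integer vector of affected plot ids; drawn via
#'   [select_affected_plots()] with `seed` when `NULL`.
#' @param seed Seed for the affected-plot draw when `affected` is `NULL`.
#' @return Plot panel tibble: `plot_id`, `x_t1`, `y_t2_undisturbed`,
#'   `y_t2_disturbed`, `affected`, `scenario`.
#' @export
apply_scenario <- function(pop, spec, affected = NULL, seed = NULL) {
  if (is.null(affected)) {
    affected <- select_affected_plots(n_plots(pop), spec$fraction, seed = seed)
  }
  if (length(affected) && (min(affected) < 1 || max(affected) > n_plots(pop))) {
    abort("`affected` contains plot ids outside the population")
  }
  pv <- scenario_plot_values(pop, spec)
  is_aff <- pv$plot_id %in% affected
  tibble(
    plot_id = pv$plot_id,
    x_t1 = pv$x_t1,
    y_t2_undisturbed = pv$y_undist,
    y_t2_disturbed = ifelse(is_aff, pv$y_rule, pv$y_undist),
    affected = is_aff,
    scenario = spec$name
  )
}

#' True population change of a plot panel
#'
#' Population (not sample) means over all plots, using the disturbed
#' occasion-2 values.
#'
#' @param panel A plot panel tibble from [apply_scenario()].
#' @return One-row tibble with `mean_t1`, `mean_t2`, `change` (t/ha).
#' @export
true_change <- function(panel) {
  tibble(
    mean_t1 = mean(panel$x_t1),
    mean_t2 = mean(panel$y_t2_disturbed),
    change = mean(panel$y_t2_disturbed) - mean(panel$x_t1)
  )
}
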