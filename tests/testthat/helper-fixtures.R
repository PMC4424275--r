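# Small hand-built populations used across test files.

# One plot, two surviving trees with chosen occasion-2 diameters.
two_tree_plot <- function(dbh_t2 = c(30, 50)) {
  as_tree_population(
    tibble::tibble(
      plot_id = c(1L, 1L), tree_id = c(1L, 2L),
      dbh_t1 = pmax(15, dbh_t2 - 2), alive_t2 = TRUE, dbh_t2 = dbh_t2
    ),
    n_plots = 1, plot_area_m2 = 400
  )
}

small_pop <- function(n_plots = 40, seed = 11) {
  generate_population(population_params(n_plots = n_plots), seed = seed)
}
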