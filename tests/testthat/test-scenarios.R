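test_that("affected-plot counts follow floor(fraction * n) exactly", {
  expect_length(select_affected_plots(750, 0.05, seed = 1), 37)
  expect_length(select_affected_plots(750, 0.10, seed = 1), 75)
  expect_length(select_affected_plots(750, 0.20, seed = 1), 150)
  expect_length(select_affected_plots(500, 0, seed = 1), 0)
  for (n in c(10, 101, 750)) {
    for (f in c(0, 0.033, 0.5, 0.999, 1)) {
      ids <- select_affected_plots(n, f, seed = n)
      expect_length(ids, floor(f * n))
      expect_false(anyDuplicated(ids) > 0)
      expect_true(all(ids %in% seq_len(n)))
    }
  }
  expect_error(select_affected_plots(100, 1.2), "\\[0, 1\\]")
})

test_that("scenario rules remove the right trees with strict thresholds", {
  pop <- two_tree_plot(dbh_t2 = c(30, 50))
  a <- agb_from_dbh(30) / 40
  b <- agb_from_dbh(50) / 40
  below <- apply_scenario(pop, scenario_spec("s", 1, "remove_below", 35),
                          affected = 1)
  above <- apply_scenario(pop, scenario_spec("s", 1, "remove_above", 45),
                          affected = 1)
  all_rm <- apply_scenario(pop, scenario_spec("s", 1, "remove_all"),
                           affected = 1)
  expect_equal(below$y_t2_disturbed, b, tolerance = 1e-12)
  expect_equal(above$y_t2_disturbed, a, tolerance = 1e-12)
  expect_equal(all_rm$y_t2_disturbed, 0)
  # trees exactly at the threshold are retained (strict comparison)
  at <- two_tree_plot(dbh_t2 = c(35, 50))
  kept <- apply_scenario(at, scenario_spec("s", 1, "remove_below", 35),
                         affected = 1)
  expect_equal(kept$y_t2_disturbed, kept$y_t2_undisturbed)
  # unaffected plots are untouched
  none <- apply_scenario(pop, scenario_spec("s", 1, "remove_below", 35),
                         affected = integer())
  expect_equal(none$y_t2_disturbed, none$y_t2_undisturbed)
  expect_error(scenario_spec("s", 0.1, "remove_below"), "threshold")
})

test_that("occasion-1 biomass is never altered and removal rules partition biomass", {
  pop <- small_pop(n_plots = 30, seed = 21)
  base <- apply_scenario(pop, scenario_spec("none", 0, "none"), affected = integer())
  aff <- 1:30
  below <- apply_scenario(pop, scenario_spec("b", 1, "remove_below", 40), affected = aff)
  above <- apply_scenario(pop, scenario_spec("a", 1, "remove_above", 40), affected = aff)
  expect_identical(below$x_t1, base$x_t1)
  expect_identical(above$x_t1, base$x_t1)
  # no tree sits exactly at 40 cm (continuous diameters), so kept biomass
  # under the two complementary rules adds back to the undisturbed value
  expect_equal(below$y_t2_disturbed + above$y_t2_disturbed,
               base$y_t2_undisturbed, tolerance = 1e-10)
})

test_that("larger affected sets never increase disturbed biomass", {
  pop <- small_pop(n_plots = 50, seed = 8)
  spec <- scenario_spec("d", 0.5, "remove_above", 45)
  small <- sort(select_affected_plots(50, 0.2, seed = 2))
  big <- sort(union(small, select_affected_plots(50, 0.5, seed = 3)))
  p_small <- apply_scenario(pop, spec, affected = small)
  p_big <- apply_scenario(pop, spec, affected = big)
  expect_true(all(p_big$y_t2_disturbed <= p_small$y_t2_disturbed + 1e-12))
})

test_that("true change uses population means of the disturbed panel", {
  pop <- small_pop(n_plots = 40, seed = 14)
  grown <- apply_scenario(pop, scenario_spec("none", 0, "none"), affected = integer())
  tc <- true_change(grown)
  expect_gt(tc$change, 0) # growth only
  cleared <- apply_scenario(pop, scenario_spec("all", 1, "remove_all"),
                            affected = 1:40)
  tc2 <- true_change(cleared)
  expect_equal(tc2$change, -mean(grown$x_t1))
  expect_equal(tc$change, tc$mean_t2 - tc$mean_t1)
})
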