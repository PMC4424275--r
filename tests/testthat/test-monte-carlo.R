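mc_pop <- generate_population(population_params(), seed = 2024)

test_that("experiments are deterministic and truth is shared within an iteration", {
  scen <- default_scenarios()[c("no_intervention", "defor5")]
  a <- run_experiment(mc_pop, scenarios = scen, iterations = 5, master_seed = 12)
  b <- run_experiment(mc_pop, scenarios = scen, iterations = 5, master_seed = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  shared <- a %>%
    dplyr::group_by(scenario, iteration) %>%
    dplyr::summarise(n_truths = dplyr::n_distinct(true_change), .groups = "drop")
  expect_true(all(shared$n_truths == 1))
  # different master seed, different draws
  c_ <- run_experiment(mc_pop, scenarios = scen, iterations = 5, master_seed = 13)
  expect_false(identical(a$change, c_$change))
})

test_that("without disturbance the bias flag cannot alter any estimate", {
  res <- run_experiment(mc_pop,
                        scenarios = default_scenarios()["no_intervention"],
                        iterations = 8, master_seed = 5)
  wide <- tidyr::pivot_wider(res[, c("design", "bias", "iteration", "change")],
                             names_from = bias, values_from = change)
  expect_equal(wide$`TRUE`, wide$`FALSE`)
})

test_that("run_iteration mirrors one cell of the experiment", {
  sc <- default_scenarios()$deg10_below35
  row <- run_iteration(mc_pop, sc, default_designs()$cfi, bias = TRUE,
                       seed_scenario = 3, seed_sample = 4)
  expect_equal(nrow(row), 1)
  expect_equal(row$design, "cfi")
  expect_equal(row$n_t1, 375)
  # truth depends only on the scenario seed
  row2 <- run_iteration(mc_pop, sc, default_designs()$spr, bias = FALSE,
                        seed_scenario = 3, seed_sample = 99)
  expect_equal(row$true_change, row2$true_change)
})

test_that("all designs are unbiased without treatment bias", {
  res <- run_experiment(mc_pop,
                        scenarios = default_scenarios()[c("defor5", "deg20_below35")],
                        bias_variants = FALSE,
                        iterations = 120, master_seed = 31)
  s <- summarize_experiment(res)
  expect_true(all(abs(s$mean_diff) <=
                    3 * s$empirical_sd / sqrt(s$n_iter)))
})

test_that("treatment bias inflates permanent-plot change estimates most", {
  res <- run_experiment(mc_pop,
                        scenarios = default_scenarios()["deg20_above45"],
                        iterations = 80, master_seed = 77)
  s <- summarize_experiment(res)
  over <- with(s[s$bias, ], setNames(mean_diff, design))
  expect_gt(over[["cfi"]], over[["spr"]])
  expect_gt(over[["spr"]], over[["temporary"]] + 1)
})

test_that("summaries compute the four surfaces from iteration rows", {
  fake <- tibble::tibble(
    scenario = "s", design = rep(c("cfi", "spr"), each = 3), bias = FALSE,
    iteration = rep(1:3, 2),
    change = c(10, 10, 10, 8, 12, 10), variance = 4, se = 2,
    true_change = 10
  )
  class(fake) <- c("mc_results", class(fake))
  s <- summarize_experiment(fake)
  expect_equal(s$pct_of_true, c(100, 100))
  expect_equal(s$empirical_sd, c(0, 2))
  expect_equal(s$pct_se, c(20, 20))
  expect_equal(s$mean_abs_diff, c(0, 4 / 3))
  zero <- dplyr::mutate(fake, true_change = 0)
  expect_true(all(is.na(summarize_experiment(zero)$pct_of_true)))
  expect_error(summarize_experiment(fake[c(1, 4), ]), "at least 2")
})

test_that("summary plots build without error", {
  res <- run_experiment(mc_pop, scenarios = default_scenarios()["defor5"],
                        iterations = 4, master_seed = 3)
  s <- summarize_experiment(res)
  p <- autoplot(s, metric = "pct_se")
  expect_s3_class(p, "ggplot")
  panel <- apply_scenario(mc_pop, default_scenarios()$defor5, seed = 2)
  expect_s3_class(plot_panel(panel), "ggplot")
})
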