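test_that("temporary-plot estimator matches hand-computed values", {
  e <- estimate_temporary(c(10, 20, 30), c(12, 24, 30))
  expect_equal(e$change, 2)
  expect_equal(e$variance, 61 + 1 / 3, tolerance = 1e-12)
  cst <- estimate_temporary(rep(7, 4), rep(7, 5))
  expect_equal(cst$change, 0)
  expect_equal(cst$variance, 0)
  expect_error(estimate_temporary(1, c(1, 2)), "at least 2")
})

test_that("CFI estimator matches hand-computed values and collapses for identical panels", {
  e <- estimate_cfi(c(10, 20, 30), c(12, 24, 30))
  expect_equal(e$change, 2)
  expect_equal(e$variance, 4 / 3, tolerance = 1e-6)
  same <- estimate_cfi(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$change, 0)
  expect_equal(same$variance, 0)
  shift <- estimate_cfi(c(1, 2, 3), c(6, 7, 8))
  expect_equal(shift$change, 5)
  expect_equal(shift$variance, 0)
  expect_error(estimate_cfi(1:4, 1:3), "paired")
  expect_error(estimate_cfi(1:2, 2:3), "at least 3")
  expect_warning(estimate_cfi(rep(2, 3), c(1, 2, 3)), "zero variance")
})

test_that("SPR worked example reproduces every stage of the estimation chain", {
  comp <- spr_fit(c(10, 20, 30, 40), c(10, 20, 30), c(12, 24, 30), c(20, 30))
  expect_equal(comp$beta_yx, 0.9)
  expect_equal(comp$r, 0.981980506062, tolerance = 1e-10)
  expect_equal(comp$s2_yx, 6)
  expect_equal(comp$y_I, 26.5)
  expect_equal(comp$v_I, 22.25)
  expect_equal(comp$y_II, 25)
  expect_equal(comp$v_II, 25)
  cur <- spr_current(comp)
  expect_equal(cur$mean, 25.7936507937, tolerance = 1e-10)
  expect_equal(cur$variance, 29.3714003989, tolerance = 1e-10)
  est <- spr_change(comp)
  expect_equal(est$change, 0.793650793651, tolerance = 1e-10)
  expect_equal(est$variance, 13.7566137566, tolerance = 1e-10)
  printed <- suppressWarnings(spr_change(comp, mode = "as_printed"))
  expect_equal(printed$variance, -105.291005291, tolerance = 1e-10)
  expect_true(printed$negative_variance)
})

test_that("SPR collapses to the remeasured mean when no unmatched occasion-1 plots exist", {
  comp <- spr_fit(c(10, 20, 30), c(10, 20, 30), c(12, 24, 30), c(20, 30))
  expect_equal(comp$y_I, mean(c(12, 24, 30)))
})

test_that("SPR design preconditions are enforced", {
  expect_error(spr_fit(1:4, 1:2, 1:2, 1:3), "at least 3 remeasured")
  expect_error(spr_fit(1:4, 1:3, 1:3, 1), "at least 2 new")
  expect_error(spr_fit(1:2, 1:3, 1:3, 1:3), "all occasion-1")
  expect_error(spr_fit(c(5, 5, 5, 6), rep(5, 3), 1:3, 1:3), "constant")
})

test_that("all SPR, CFI and temporary quantities match the brute-force oracle", {
  withr::with_seed(101, {
    for (i in 1:300) {
      inst <- random_spr_instance()
      comp <- spr_fit(inst$x1_all, inst$x12, inst$y12, inst$y_new)
      orc <- oracle_spr(inst$x1_all, inst$x12, inst$y12, inst$y_new)
      for (f in c("xbar1", "xbar12", "ybar12", "ybar_minus2", "s_xy", "s2_x12",
                  "s2_y12", "s2_yx", "r", "beta_yx", "y_I", "y_II", "v_I",
                  "v_II", "w_I", "w_II", "w", "s2_x1")) {
        expect_equal(comp[[f]], orc[[f]], tolerance = 1e-10)
      }
      cur <- spr_current(comp)
      expect_equal(cur$mean, orc$current_mean, tolerance = 1e-10)
      expect_equal(cur$variance, orc$current_variance, tolerance = 1e-10)
      est <- spr_change(comp)
      expect_equal(est$change, orc$change, tolerance = 1e-10)
      if (orc$change_variance >= 0) {
        expect_equal(est$variance, orc$change_variance, tolerance = 1e-10)
      }
      ecfi <- estimate_cfi(inst$x12, inst$y12)
      ocfi <- oracle_cfi(inst$x12, inst$y12)
      expect_equal(ecfi$change, ocfi$change, tolerance = 1e-10)
      expect_equal(ecfi$variance, max(ocfi$variance, 0), tolerance = 1e-10)
      etmp <- estimate_temporary(inst$x1_all, inst$y_new)
      otmp <- oracle_temporary(inst$x1_all, inst$y_new)
      expect_equal(etmp$change, otmp$change, tolerance = 1e-10)
      expect_equal(etmp$variance, otmp$variance, tolerance = 1e-10)
    }
  })
})

test_that("estimators are location and scale equivariant", {
  withr::with_seed(33, {
    x <- runif(8, 80, 160)
    y <- x * 1.1 + rnorm(8, 0, 12)
    yn <- runif(5, 80, 180)
    for (shift in c(-4, 25)) {
      a <- estimate_cfi(x, y)
      b <- estimate_cfi(x, y + shift)
      expect_equal(b$change, a$change + shift, tolerance = 1e-10)
      expect_equal(b$variance, a$variance, tolerance = 1e-10)
      a <- estimate_spr(x, x[1:6], y[1:6], yn)
      b <- estimate_spr(x, x[1:6], y[1:6] + shift, yn + shift)
      expect_equal(b$change, a$change + shift, tolerance = 1e-8)
      expect_equal(b$variance, a$variance, tolerance = 1e-8)
    }
    k <- 2.5
    a <- estimate_temporary(x, yn)
    b <- estimate_temporary(k * x, k * yn)
    expect_equal(b$change, k * a$change, tolerance = 1e-10)
    expect_equal(b$variance, k^2 * a$variance, tolerance = 1e-10)
    a <- estimate_spr(x, x[1:6], y[1:6], yn)
    b <- estimate_spr(k * x, k * x[1:6], k * y[1:6], k * yn)
    expect_equal(b$change, k * a$change, tolerance = 1e-8)
    expect_equal(b$variance, k^2 * a$variance, tolerance = 1e-8)
  })
})

test_that("positive pairing correlation makes CFI beat temporary plots", {
  withr::with_seed(55, {
    for (i in 1:40) {
      x <- runif(12, 80, 200)
      y <- x + rnorm(12, 5, 10)
      if (cor(x, y) <= 0) next
      expect_lt(estimate_cfi(x, y)$variance,
                estimate_temporary(x, y)$variance)
    }
  })
})

test_that("SPR current mean is a convex combination of its two components", {
  withr::with_seed(77, {
    for (i in 1:50) {
      inst <- random_spr_instance()
      comp <- spr_fit(inst$x1_all, inst$x12, inst$y12, inst$y_new)
      cur <- spr_current(comp)
      expect_gte(cur$mean, min(comp$y_I, comp$y_II) - 1e-10)
      expect_lte(cur$mean, max(comp$y_I, comp$y_II) + 1e-10)
    }
  })
})

test_that("percent standard error follows the requested convention", {
  e <- estimate_temporary(c(10, 20, 30), c(12, 24, 30))
  expect_equal(percent_standard_error(e),
               100 * sqrt(61 + 1 / 3) / 2, tolerance = 1e-10)
  cfi <- estimate_cfi(c(10, 20, 30), c(12, 24, 30))
  expect_equal(percent_standard_error(cfi), 57.735, tolerance = 1e-3)
  expect_equal(percent_standard_error(cfi, "current_mean", ref = 22),
               100 * cfi$se / 22, tolerance = 1e-10)
  zero <- estimate_temporary(c(1, 2, 3), c(1, 2, 3))
  expect_warning(out <- percent_standard_error(zero), "zero")
  expect_true(is.na(out))
  expect_equal(percent_standard_error(e, ref = 4), 100 * e$se / 4)
})

test_that("tidiers expose the estimate and the component audit trail", {
  est <- estimate_spr(c(10, 20, 30, 40), c(10, 20, 30), c(12, 24, 30), c(20, 30))
  td <- tidy(est)
  expect_named(td, c("design", "change", "variance", "se", "pct_se",
                     "n_t1", "n_t2"))
  expect_equal(td$design, "spr")
  expect_equal(glance(est), td)
  comps <- tidy(est$components)
  expect_true(all(c("beta_yx", "w_I", "s2_yx") %in% comps$term))
})
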