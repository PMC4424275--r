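# Independent brute-force recomputation of every estimator quantity from
# first principles: explicit loops and sums only, no code shared with the
# package implementation.

oracle_mean <- function(v) {
  s <- 0
  for (vi in v) s <- s + vi
  s / length(v)
}

oracle_mean_var <- function(v) {
  m <- oracle_mean(v)
  s <- 0
  for (vi in v) s <- s + (vi - m)^2
  s / (length(v) * (length(v) - 1))
}

oracle_temporary <- function(x, y) {
  list(change = oracle_mean(y) - oracle_mean(x),
       variance = oracle_mean_var(y) + oracle_mean_var(x))
}

oracle_cfi <- function(x, y) {
  n <- length(x)
  mx <- oracle_mean(x); my <- oracle_mean(y)
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  r <- sxy / sqrt(sxx * syy)
  vx <- sxx / (n * (n - 1)); vy <- syy / (n * (n - 1))
  list(change = my - mx, variance = vy + vx - 2 * r * sqrt(vy) * sqrt(vx))
}

oracle_spr <- function(x1_all, x12, y12, y_new, mode = "corrected") {
  n1 <- length(x1_all); n12 <- length(x12); nm2 <- length(y_new)
  xbar1 <- oracle_mean(x1_all); xbar12 <- oracle_mean(x12)
  ybar12 <- oracle_mean(y12); ybarm2 <- oracle_mean(y_new)
  ssx <- 0; ssy <- 0; sxy <- 0
  for (j in seq_len(n12)) {
    ssx <- ssx + (x12[j] - xbar12)^2
    ssy <- ssy + (y12[j] - ybar12)^2
    sxy <- sxy + (x12[j] - xbar12) * (y12[j] - ybar12)
  }
  s_xy <- sxy / (n12 - 1)
  s2_x12 <- ssx / (n12 - 1)
  s2_y12 <- ssy / (n12 - 1)
  beta <- s_xy / s2_x12
  r <- s_xy / (sqrt(s2_x12) * sqrt(s2_y12))
  s2_yx <- (1 - r^2) * ssy / (n12 - 2)
  y_I <- ybar12 + beta * (xbar1 - xbar12)
  v_I <- s2_yx * (1 / n12 + (xbar1 - xbar12)^2 / ssx) + (s2_y12 - s2_yx) / n1
  v_II <- 0
  for (j in seq_len(nm2)) v_II <- v_II + (y_new[j] - ybarm2)^2
  v_II <- v_II / (nm2 * (nm2 - 1))
  w_I <- 1 / v_I; w_II <- 1 / v_II; w <- w_I + w_II
  ybar <- (w_I * y_I + w_II * ybarm2) / w
  v_ybar <- (1 + 4 * w_I * w_II * (1 / (n12 - 1) + 1 / (nm2 - 1)) / w^2) / w
  ssx1 <- 0
  for (i in seq_len(n1)) ssx1 <- ssx1 + (x1_all[i] - xbar1)^2
  s2_x1 <- ssx1 / (n1 - 1)
  change <- ybar - xbar1
  v_change <- if (mode == "as_printed") {
    1 / w + s2_x1 / n1 - 2 * (w_I / w) * beta * ssx1 / (n1 - 1)
  } else {
    1 / w + s2_x1 / n1 - 2 * (w_I / w) * beta * s2_x1 / n1
  }
  list(n1 = n1, n12 = n12, n_minus2 = nm2,
       xbar1 = xbar1, xbar12 = xbar12, ybar12 = ybar12, ybar_minus2 = ybarm2,
       s_xy = s_xy, s2_x12 = s2_x12, s2_y12 = s2_y12, s2_yx = s2_yx,
       r = r, beta_yx = beta, y_I = y_I, y_II = ybarm2, v_I = v_I, v_II = v_II,
       w_I = w_I, w_II = w_II, w = w, s2_x1 = s2_x1,
       current_mean = ybar, current_variance = v_ybar,
       change = change, change_variance = v_change)
}

# Random small SPR/CFI instances for oracle-equivalence sweeps.
random_spr_instance <- function() {
  n12 <- sample(3:10, 1)
  nm2 <- sample(2:10, 1)
  n1only <- sample(0:10, 1)
  x12 <- round(runif(n12, 50, 200), 3)
  y12 <- round(x12 * runif(1, 0.8, 1.3) + rnorm(n12, 0, 20), 3)
  list(x1_all = c(x12, round(runif(n1only, 50, 200), 3)),
       x12 = x12, y12 = y12,
       y_new = round(runif(nm2, 40, 220), 3))
}
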