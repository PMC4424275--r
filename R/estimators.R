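# Change estimators for sampling on successive occasions.
#
# All three designs estimate the mean biomass change C = Ybar - Xbar. They
# differ in how the occasion-2 plots relate to the occasion-1 plots:
# temporary plots are unmatched, CFI plots are fully matched, and SPR mixes
# a matched (remeasured) subsample with new temporary plots, combining a
# regression-updated mean with the new-plot mean by inverse-variance
# weighting. Estimators consume plain numeric vectors and never see plot
# roles or bias flags.

mean_var <- function(v) sum((v - mean(v))^2) / (length(v) * (length(v) - 1))

new_change_estimate <- function(design, change, variance, n_t1, n_t2,
                                components = NULL, negative_variance = FALSE) {
  structure(
    list(design = design, change = change,
         variance = variance, se = sqrt(max(variance, 0)),
         n_t1 = as.integer(n_t1), n_t2 = as.integer(n_t2),
         components = components, negative_variance = negative_variance),
    class = "change_estimate"
  )
}

#' Change estimate from temporary (unmatched) plots
#'
#' Occasion samples are independent, so the variance of the change is the
#' sum of the two mean variances — no covariance reduction is available.
#'
#' @param x Occasion-1 plot values, t/ha (n >= 2).
#' @param y Occasion-2 plot values, t/ha (n >= 2); need not match `x` in
#'   length.
#' @return A `change_estimate` object; see [tidy.change_estimate()].
#' @export
#' @examples
#' tidy(estimate_temporary(c(10, 20, 30), c(12, 24, 30)))
estimate_temporary <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("both samples need at least 2 plots")
  }
  new_change_estimate("temporary",
                      change = mean(y) - mean(x),
                      variance = mean_var(y) + mean_var(x),
                      n_t1 = length(x), n_t2 = length(y))
}

#' Change estimate from permanent plots (continuous forest inventory)
#'
#' Plots are remeasured, so `x` and `y` are paired and the change variance
#' is reduced by twice the covariance term,
#' `V(Ybar) + V(Xbar) - 2 r sqrt(V(Ybar)) sqrt(V(Xbar))`, with `r` the
#' paired Pearson correlation.
#'
#' @param x,y Paired plot values, t/ha; equal length >= 3.
#' @return A `change_estimate` object.
#' @export
#' @examples
#' tidy(estimate_cfi(c(10, 20, 30), c(12, 24, 30)))
estimate_cfi <- function(x, y) {
  if (length(x) != length(y)) abort("CFI requires paired samples of equal length")
  if (length(x) < 3) abort("CFI requires at least 3 paired plots")
  vx <- mean_var(x)
  vy <- mean_var(y)
  if (vx == 0 || vy == 0) {
    warn("zero variance at one occasion: correlation undefined, using the unmatched-variance form")
    v <- vx + vy
  } else {
    r <- cor(x, y)
    v <- max(vy + vx - 2 * r * sqrt(vy) * sqrt(vx), 0)
  }
  new_change_estimate("cfi", change = mean(y) - mean(x), variance = v,
                      n_t1 = length(x), n_t2 = length(y))
}

#' Fit the sampling-with-partial-replacement components
#'
#' Computes every intermediate quantity of the two-occasion SPR estimator:
#' the regression of remeasured occasion-2 values on their occasion-1 values
#' (slope `beta_yx`, correlation `r`, residual variance `s2_yx`), the
#' regression-updated mean `y_I` with variance `v_I`, and the new-plot mean
#' `y_II` with variance `v_II`, together with their inverse-variance weights.
#'
#' @param x1_all All occasion-1 plot values (matched and unmatched),
#'   length `n1`.
#' @param x12,y12 Paired values on the `n12` remeasured (permanent) plots;
#'   `n12 >= 3` and `x12` must not be constant.
#' @param y_new Values on the `n_minus2` new occasion-2 temporary plots
#'   (`n >= 2`).
#' @return A list of class `spr_components`; see [tidy.spr_components()].
#' @export
#' @examples
#' comp <- spr_fit(c(10, 20, 30, 40), c(10, 20, 30), c(12, 24, 30), c(20, 30))
#' comp$y_I
spr_fit <- function(x1_all, x12, y12, y_new) {
  n1 <- length(x1_all)
  n12 <- length(x12)
  nm2 <- length(y_new)
  if (length(y12) != n12) abort("`x12` and `y12` must be paired")
  if (n12 < 3) abort("SPR needs at least 3 remeasured plots (regression degrees of freedom)")
  if (nm2 < 2) abort("SPR needs at least 2 new occasion-2 plots")
  if (n1 < n12) abort("`x1_all` must contain all occasion-1 plots, including the remeasured ones")
  xbar1 <- mean(x1_all)
  xbar12 <- mean(x12)
  ybar12 <- mean(y12)
  ybar_m2 <- mean(y_new)
  ssx12 <- sum((x12 - xbar12)^2)
  if (ssx12 == 0) abort("`x12` is constant: the update regression is degenerate")
  s_xy <- sum((y12 - ybar12) * (x12 - xbar12)) / (n12 - 1)
  s2_x12 <- ssx12 / (n12 - 1)
  s2_y12 <- sum((y12 - ybar12)^2) / (n12 - 1)
  beta <- s_xy / s2_x12
  r <- if (s2_y12 > 0) s_xy / sqrt(s2_x12 * s2_y12) else 0
  s2_yx <- (1 - r^2) * sum((y12 - ybar12)^2) / (n12 - 2)
  y_I <- ybar12 + beta * (xbar1 - xbar12)
  v_I <- s2_yx * (1 / n12 + (xbar1 - xbar12)^2 / ssx12) + (s2_y12 - s2_yx) / n1
  y_II <- ybar_m2
  v_II <- sum((y_new - ybar_m2)^2) / (nm2 * (nm2 - 1))
  s2_x1 <- sum((x1_all - xbar1)^2) / (n1 - 1)
  structure(
    list(n1 = n1, n12 = n12, n_minus2 = nm2,
         xbar1 = xbar1, xbar12 = xbar12, ybar12 = ybar12, ybar_minus2 = ybar_m2,
         s_xy = s_xy, s2_x12 = s2_x12, s2_y12 = s2_y12, s2_yx = s2_yx,
         r = r, beta_yx = beta,
         y_I = y_I, y_II = y_II, v_I = v_I, v_II = v_II,
         w_I = 1 / v_I, w_II = 1 / v_II, w = 1 / v_I + 1 / v_II,
         s2_x1 = s2_x1),
    class = "spr_components"
  )
}

#' Combined SPR estimate of the current mean
#'
#' Weights the regression-updated mean and the new-plot mean by their
#' inverse variances; the variance of the combination carries a small-sample
#' inflation term `4 w_I w_II (1/(n12-1) + 1/(n_minus2-1)) / w^2`.
#'
#' @param comp An [spr_fit()] result.
#' @return One-row tibble with `mean` and `variance`.
#' @export
spr_current <- function(comp) {
  stopifnot(inherits(comp, "spr_components"))
  if (comp$v_I == 0 || comp$v_II == 0) {
    warn("zero component variance: returning that component's mean with variance 0")
    m <- if (comp$v_I == 0) comp$y_I else comp$y_II
    return(tibble(mean = m, variance = 0))
  }
  m <- (comp$w_I * comp$y_I + comp$w_II * comp$y_II) / comp$w
  infl <- 4 * comp$w_I * comp$w_II *
    (1 / (comp$n12 - 1) + 1 / (comp$n_minus2 - 1)) / comp$w^2
  tibble(mean = m, variance = (1 + infl) / comp$w)
}

#' SPR change estimate and variance
#'
#' Change is the combined current mean minus the all-plot occasion-1 mean.
#' Its approximate variance is `1/w + s2_x1/n1 - 2 (w_I/w) beta s2_x1/n1`
#' in the default `corrected` mode. The published form of the covariance
#' term lacks the `1/n1` divisor; that form is dimensionally inconsistent
#' (it is O(s^2) while the other terms are O(s^2/n)) and goes far negative
#' on realistic inputs, but is retained as `as_printed` for fidelity
#' checking, reported unclamped with a warning flag.
#'
#' @param comp An [spr_fit()] result.
#' @param mode `"corrected"` (default) or `"as_printed"`.
#' @return A `change_estimate` object carrying `comp` in `$components`.
#' @export
#' @examples
#' comp <- spr_fit(c(10, 20, 30, 40), c(10, 20, 30), c(12, 24, 30), c(20, 30))
#' tidy(spr_change(comp))
spr_change <- function(comp, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  cur <- spr_current(comp)
  change <- cur$mean - comp$xbar1
  cov_term <- 2 * (comp$w_I / comp$w) * comp$beta_yx * comp$s2_x1 / comp$n1
  if (mode == "as_printed") {
    v <- 1 / comp$w + comp$s2_x1 / comp$n1 - cov_term * comp$n1
    neg <- v < 0
    if (neg) warn("as-printed SPR change variance is negative; reported unclamped")
    return(new_change_estimate("spr", change, v, comp$n1, comp$n12 + comp$n_minus2,
                               components = comp, negative_variance = neg))
  }
  v <- 1 / comp$w + comp$s2_x1 / comp$n1 - cov_term
  neg <- v < 0
  if (neg) {
    warn("corrected SPR change variance was negative; clamped to 0")
    v <- 0
  }
  new_change_estimate("spr", change, v, comp$n1, comp$n12 + comp$n_minus2,
                      components = comp, negative_variance = neg)
}

#' One-call SPR change estimate
#'
#' Convenience wrapper: [spr_fit()] followed by [spr_change()].
#'
#' @inheritParams spr_fit
#' @inheritParams spr_change
#' @return A `change_estimate` object.
#' @export
estimate_spr <- function(x1_all, x12, y12, y_new,
                         mode = c("corrected", "as_printed")) {
  spr_change(spr_fit(x1_all, x12, y12, y_new), mode = match.arg(mode))
}

#' Percent standard error of a change estimate
#'
#' `100 * se / |ref|`, where the reference magnitude is the absolute change
#' estimate (default) or a supplied current-mean estimate. Which convention
#' a report uses should be stated; both are available.
#'
#' @param e A `change_estimate`.
#' @param denominator `"abs_change"` or `"current_mean"`.
#' @param ref Reference value when `denominator = "current_mean"`, or an
#'   override for the change.
#' @return Percent standard error; `NA` (with a warning) when the reference
#'   is zero.
#' @export
percent_standard_error <- function(e, denominator = c("abs_change", "current_mean"),
                                   ref = NULL) {
  denominator <- match.arg(denominator)
  if (is.null(ref)) {
    if (denominator == "current_mean") {
      abort("`ref` must be supplied for the current-mean convention")
    }
    ref <- e$change
  }
  if (ref == 0) {
    warn("reference magnitude is zero: percent standard error undefined")
    return(NA_real_)
  }
  100 * e$se / abs(ref)
}

#' @export
print.change_estimate <- function(x, ...) {
  cat(sprintf("<change_estimate: %s>\n  change %.3f t/ha, SE %.3f (n1 = %d, n2 = %d)\n",
              x$design, x$change, x$se, x$n_t1, x$n_t2))
  invisible(x)
}

#' Tidy a change estimate
#'
#' @param x A `change_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `design`, `change`, `variance`, `se`, `pct_se`,
#'   `n_t1`, `n_t2`.
#' @method tidy change_estimate
#' @export
tidy.change_estimate <- function(x, ...) {
  tibble(design = x$design, change = x$change, variance = x$variance,
         se = x$se,
         pct_se = if (x$change != 0) 100 * x$se / abs(x$change) else NA_real_,
         n_t1 = x$n_t1, n_t2 = x$n_t2)
}

#' @rdname tidy.change_estimate
#' @method glance change_estimate
#' @export
glance.change_estimate <- function(x, ...) tidy(x)

#' Tidy the SPR component quantities
#'
#' @param x An `spr_components` list.
#' @param ... Unused.
#' @return Long tibble of `term`, `value` for every intermediate quantity,
#'   for audit of the estimation chain.
#' @method tidy spr_components
#' @export
tidy.spr_components <- function(x, ...) {
  tibble(term = names(unclass(x)),
         value = vapply(unclass(x), as.numeric, numeric(1)))
}
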