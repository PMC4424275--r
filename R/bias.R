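#' Treatment-bias check: permanent versus temporary plots
#'
#' If permanent plots are managed differently from the surrounding forest,
#' their current-occasion biomass drifts away from that of freshly placed
#' temporary plots, which cannot be treated preferentially. The check runs
#' an unequal-variance (Welch) comparison of the two means together with a
#' two-one-sided (TOST) equivalence test against a margin:
#' a significant difference is evidence of treatment bias; demonstrated
#' equivalence within the margin is evidence of its absence; otherwise the
#' data are inconclusive.
#'
#' @param y_perm Current-occasion biomass on remeasured permanent plots,
#'   t/ha (n >= 2).
#' @param y_temp Current-occasion biomass on new temporary plots, t/ha
#'   (n >= 2).
#' @param alpha Test level for both tests.
#' @param margin Equivalence margin, t/ha; default 10% of the
#'   temporary-plot mean.
#' @return One-row tibble of class `bias_check`: `mean_diff`
#'   (permanent - temporary), `se`, `statistic`, `df`, `p_value` (difference
#'   test), `p_tost` (equivalence test), `margin`, `alpha`, `verdict`.
#' @export
#' @examples
#' set.seed(1)
#' compare_permanent_temporary(rnorm(125, 130, 60), rnorm(125, 130, 60))
compare_permanent_temporary <- function(y_perm, y_temp, alpha = 0.05,
                                        margin = NULL) {
  if (length(y_perm) < 2 || length(y_temp) < 2) {
    abort("both samples need at least 2 plots")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (is.null(margin)) margin <- 0.1 * abs(mean(y_temp))
  if (margin < 0) abort("`margin` must be >= 0")
  n1 <- length(y_perm)
  n2 <- length(y_temp)
  v1 <- stats::var(y_perm) / n1
  v2 <- stats::var(y_temp) / n2
  diff <- mean(y_perm) - mean(y_temp)
  se <- sqrt(v1 + v2)
  if (se == 0) {
    p_value <- if (diff == 0) 1 else 0
    p_tost <- if (abs(diff) < margin) 0 else 1
    stat <- if (diff == 0) 0 else Inf * sign(diff)
    df <- n1 + n2 - 2
  } else {
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    stat <- diff / se
    p_value <- 2 * pt(-abs(stat), df)
    p_lower <- pt((diff + margin) / se, df, lower.tail = FALSE)
    p_upper <- pt((diff - margin) / se, df)
    p_tost <- max(p_lower, p_upper)
  }
  # an exactly zero mean difference lies inside any positive margin, so it
  # counts as demonstrated equivalence even when the TOST is underpowered
  verdict <- if (p_value < alpha) {
    "evidence_of_bias"
  } else if (margin > 0 && (diff == 0 || p_tost < alpha)) {
    "no_evidence_of_bias"
  } else {
    "inconclusive"
  }
  out <- tibble(mean_diff = diff, se = se, statistic = stat, df = df,
                p_value = p_value, p_tost = p_tost,
                margin = margin, alpha = alpha, verdict = verdict)
  class(out) <- c("bias_check", class(out))
  out
}
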