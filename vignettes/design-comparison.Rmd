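---
title: "Comparing inventory designs for biomass-change estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing inventory designs for biomass-change estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
set.seed(NULL)
```

```{r setup}
library(sprforest)
```

## The scientific problem

Carbon-accounting schemes for avoided deforestation and forest degradation
(REDD+) pay for *verified changes* in forest carbon stocks, which makes the
standard error of the estimated aboveground-biomass (AGB) change between two
inventory occasions as important as the change itself. Three classical
designs compete for this job:

* **Temporary plots** — independent samples at each occasion. The change
  estimate is a difference of two independent means; its variance is the sum
  of the two mean variances, with no benefit from between-occasion
  correlation.
* **Continuous forest inventory (CFI)** — one set of permanent plots
  measured on both occasions. Pairing exploits the (typically high)
  correlation between successive measurements of the same plot and shrinks
  the change variance dramatically.
* **Sampling with partial replacement (SPR)** — a compromise: part of the
  first-occasion sample is remeasured (matched plots), part is replaced by
  new plots. The current mean is a composite of a regression-updated
  estimate from the matched plots and the plain mean of the new plots,
  combined with inverse-variance weights.

Permanent plots carry a hidden risk. Once field crews, land owners, or
concession holders know where the plots are, those plots can be treated
differently from the surrounding forest — spared from logging, for example.
Estimates from permanent plots then describe an unrepresentative,
undisturbed subset while the landscape degrades around them. This
*treatment bias* inflates the estimated biomass change exactly where REDD+
accounting needs it to be honest. The package provides a desk-scale
laboratory for quantifying this trade-off: a calibrated synthetic
two-occasion forest, disturbance scenarios with and without treatment bias,
the three change estimators with their textbook variance formulas, a Monte
Carlo engine, and an equivalence-based diagnostic for detecting treatment
bias from data.

## The synthetic forest

The population is a set of `n_plots` square subplots (default 750 subplots
of 400 m^2, the equivalent of thirty 1-ha plots divided into 25 subplots
each). Within each plot:

* The tree count is Poisson with mean `trees_per_plot_mean`
  (default 8650/750 ≈ 11.53), so the expected population holds 8650 trees
  at the first occasion.
* First-occasion diameters follow a shifted exponential:
  `dbh = dbh_min + Exp(scale = dbh_scale)` with `dbh_min = 15` cm (the
  calliper threshold) and `dbh_scale = 15.147` cm. The exponential gives
  the inverse-J-shaped stand structure typical of uneven-aged tropical
  forest.
* Each tree dies before the second occasion with probability
  `mortality_prob` (default 1 − 8191/8650 ≈ 0.0531), independently. There
  is no ingrowth: the drop in tree count between occasions is modelled as
  mortality only, because no decomposition into mortality and recruitment
  is available for calibration.
* Survivors grow by a nonnegative gamma increment with per-tree standard
  deviation `growth_sd` (1.5 cm) around a plot-level mean
  `growth_mean × g_p` (default `growth_mean` = 2.40 cm over the period),
  where `g_p` is a plot-level gamma multiplier with mean 1 and standard
  deviation `plot_growth_sd` (1.90). The multiplier induces between-plot
  heterogeneity in growth and is the knob that controls the correlation
  between the two occasions' plot biomasses.

Tree AGB comes from a power-law allometry,
`AGB = exp(-1.562 + 2.148 · ln(dbh))` in kg with dbh in cm; plot biomass is
the tree sum divided by 40 (kg per 400 m^2 → t/ha).

### Calibration

`calibrate()` moment-matches the generator to published-style panel
statistics: plot-biomass means of 120.3 and 132.5 t/ha on the two
occasions, a between-occasion plot correlation of 0.804, and tree counts of
8650 and 8191. Counts fix the Poisson mean and mortality in closed form;
`dbh_scale` is solved from the exact expectation of tree AGB under the
shifted-exponential diameter law; `growth_mean` and `plot_growth_sd` are
root-found on short common-random-number simulations, alternating to absorb
their interaction. The shipped defaults in
`inst/extdata/default_params.yaml` are the result of this calibration.

```{r calibration-check}
params <- read_population_params(system.file("extdata",
  "default_params.yaml", package = "sprforest"))
pop <- generate_population(params, seed = 101)
panel <- apply_scenario(pop, default_scenarios()$no_intervention, seed = 1)
summarize_panel(panel)
```

### What the generator does and does not emulate

The generator reproduces the *first-moment panel structure*: occasion
means, tree counts, the correlation, and the qualitative stand structure
(inverse-J diameters, minimum tree AGB ≈ 70 kg at the 15 cm threshold).
It does **not** reproduce every second moment simultaneously. In
particular, once the between-occasion correlation is pinned at 0.804, the
occasion-2 plot standard deviation overshoots its nominal target
(≈ 75–80 t/ha rather than ≈ 65 t/ha): with survival-driven covariance,
`Cov(X, Y) ≥ (1 − mortality) · Var(X)` up to growth noise, and a
correlation of 0.804 then forces `SD(Y)` above the target. A generator
matching `SD(Y)` instead would miss the correlation that the variance
formulas feed on. We chose to match the correlation, because it is the
quantity that drives the CFI and SPR variance advantage under study; the
overshoot is a known, documented distortion, and relative comparisons
between designs are unaffected since all designs sample the same
population.

Other simplifications: mortality is independent of size, growth is
independent of size, and plots are spatially independent (no
autocorrelation, no edge effects).

## Disturbance scenarios

A scenario is a plot fraction plus a tree-removal rule applied to the
second-occasion diameters of affected plots (`scenario_spec()`):

```{r scenarios}
purrr::map_dfr(default_scenarios(), function(s) tibble::tibble(
  name = s$name, fraction = s$fraction, rule = s$rule,
  threshold = if (is.null(s$threshold)) NA_real_ else s$threshold))
```

`floor(fraction × n_plots)` plots are drawn without replacement, so the
default fractions affect exactly 37, 75, and 150 of the 750 plots.
Deforestation (`remove_all`) zeroes the plot; degradation removes the trees
below or above a diameter threshold (strict comparison on the
second-occasion dbh). `apply_scenario()` returns a plot panel carrying
*both* the undisturbed and the disturbed occasion-2 biomass, which is what
makes treatment bias expressible: a biased permanent plot reports the
undisturbed column while the landscape truth is the disturbed one.

Because growth adds roughly 12 t/ha between occasions, most scenarios still
show a positive net change; only heavy degradation of large trees (20% of
plots, dbh > 45 cm removed) turns the landscape change negative — large
trees hold the majority of the biomass under a power-law allometry.

## Estimators

All three estimators operate on plot-level t/ha values and return a
`change_estimate` with the change, its variance, and the standard error.

* `estimate_temporary(x, y)`: difference of independent means; variance is
  the sum of the two squared standard errors of the means.
* `estimate_cfi(x, y)`: same difference on paired plots; the variance
  subtracts the covariance term `2 r s_x s_y / n`, equivalently the
  variance of the paired differences. When the covariance term would make
  the expression degenerate (zero variances) the estimator falls back to
  the independent form with a warning.
* `estimate_spr(x1_all, x12, y12, y_new)`: regression of occasion-2 on
  occasion-1 biomass over the matched plots updates the matched-plot mean
  with the full first-occasion sample (`y_I`); the new plots contribute
  their plain mean (`y_II`). The two are combined with inverse-variance
  weights, and the combined variance carries an inflation term accounting
  for the estimated weights. The change subtracts the full first-occasion
  mean, and its variance adds the first-occasion mean variance and a
  covariance correction.

### The `spr_variance_mode` switch

A widely circulated closed-form variance for the SPR *change* contains a
final covariance-correction term that, taken literally, is not scaled by
the occasion-1 sample size. On realistic inputs the literal expression can
go (strongly) negative — a variance cannot. Dimensional analysis of the
surrounding terms shows the term is a plot-level variance where a variance
of a *mean* is required. The package therefore defaults to a `"corrected"`
mode that divides this final term by the occasion-1 sample size, which
restores positivity on realistic inputs and agrees with the paired-design
intuition that more matched plots cannot hurt. The literal form is kept as
`mode = "as_printed"` for fidelity and comparison; it never clamps, and the
estimate flags negativity instead.

```{r spr-modes}
x1 <- c(10, 20, 30, 40); x12 <- c(10, 20, 30); y12 <- c(12, 24, 30)
y2 <- c(20, 30)
estimate_spr(x1, x12, y12, y2, mode = "corrected")$variance
suppressWarnings(estimate_spr(x1, x12, y12, y2, mode = "as_printed")$variance)
```

## The Monte Carlo experiment

`run_experiment()` crosses scenarios × designs × bias variants over a fixed
population. Each iteration draws a fresh set of affected plots and a fresh
sample; within an iteration, all designs and bias variants see the *same*
disturbed landscape, so differences between cells are attributable to the
design, not to scenario noise. The default sample-size configuration
measures 375 plots per occasion in every design: SPR splits them into 125
occasion-1-only, 250 permanent, 125 new; CFI uses 375 permanent plots;
temporary sampling draws 375 independent plots per occasion.

Under *treatment bias*, sampled permanent plots report their undisturbed
occasion-2 biomass; the truth against which all estimates are judged is
always the disturbed population mean. Temporary plots are immune by
construction — new plots cannot have been treated preferentially.

```{r experiment}
res <- suppressWarnings(
  run_experiment(pop, iterations = 100, master_seed = 42))
s <- summarize_experiment(res)
dplyr::filter(s, scenario == "deg20_above45") |>
  dplyr::select(design, bias, mean_change, mean_true_change, mean_diff, pct_se)
```

The pattern above is the core result this laboratory reproduces: without
bias all designs are unbiased and CFI is the most precise, followed by SPR,
then temporary plots; with treatment bias the precision ranking inverts
into a *bias* ranking — CFI overstates the change the most, SPR less
(its new plots see the degraded landscape), and temporary plots stay
unbiased.

```{r plot, fig.alt = "Overestimation of the biomass change by design and bias"}
autoplot(s, metric = "mean_diff")
```

### Seeding design

All randomness descends from one master seed through a labelled child-seed
hash (`child_seed(master, "sample", scenario, design, iteration)` and the
like), so every cell of the experiment is individually reproducible and
cells are statistically independent. Two deliberate choices:

* The affected-plot draw is keyed by scenario and iteration only, so all
  designs and bias variants within an iteration share the same truth.
* The *bias flag is excluded* from the sample-draw seed. With it included,
  toggling bias would also change which plots are drawn, and the flag could
  alter estimates even when no plot is disturbed. Excluding it guarantees
  the invariant that under `no_intervention` the bias flag cannot change
  any estimate — bias effects in the output are bias effects, not seed
  effects.

### Numerical scale

The shipped problem sizes are small by design: a 750-plot population
generates in well under a second, a 200-iteration full experiment
(6 scenarios × 3 designs × 2 bias variants) runs in seconds on one core,
and the variance-validity checks in the test suite use 2000 superpopulation
replicates in under a minute. Monte Carlo summaries at 200 iterations carry
a relative standard error of roughly 7% on empirical dispersions; ordering
claims in the tests are therefore made at scenario level, not pooled across
unrelated cells.

Note that the variance formulas estimate the superpopulation (infinite
population) sampling variance; they carry no finite-population correction.
The test suite therefore validates them against replicates that redraw the
population each time, not against repeated sampling from one fixed
population.

## The treatment-bias diagnostic

`compare_permanent_temporary()` asks whether permanent plots have drifted
away from freshly placed temporary plots, which is the observable signature
of treatment bias. It combines a Welch two-sample test (difference) with a
two-one-sided (TOST) equivalence test against a margin (default 10% of the
temporary-plot mean): a significant difference is `evidence_of_bias`,
demonstrated equivalence is `no_evidence_of_bias`, and otherwise the data
are `inconclusive` — absence of evidence is not evidence of absence.

```{r bias-check}
roles <- draw_samples(750, default_designs()$spr, seed = 7)
panel_deg <- apply_scenario(pop, default_scenarios()$deg20_above45, seed = 3)
compare_permanent_temporary(
  panel_deg$y_t2_undisturbed[roles$permanent_ids],  # treated plots
  panel_deg$y_t2_disturbed[roles$t2_new_ids]        # honest new plots
)
```

## Limitations

* The population is synthetic; absolute variance levels depend on the
  generator's (documented) second-moment distortions, so conclusions should
  be read as *relative* comparisons between designs.
* Mortality and growth are independent of tree size, and there is no
  ingrowth, spatial autocorrelation, or measurement error.
* Disturbance is binary at plot level (a plot is affected or not) and the
  removal rules are sharp diameter thresholds.
* The SPR estimator is the classical two-occasion form; multi-occasion
  updating and optimal matching fractions are out of scope.
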