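# sprforest

Design-based comparison of forest-inventory sampling designs for estimating
aboveground-biomass (AGB) change between two occasions: **temporary plots**,
**continuous forest inventory** (CFI, permanent plots), and **sampling with
partial replacement** (SPR).

## The problem

Carbon-accounting schemes for avoided deforestation and degradation (REDD+)
pay for verified *changes* in forest carbon, so the standard error of the
estimated AGB change matters as much as the change itself. Permanent plots
make change estimation precise — pairing exploits the high correlation
between successive measurements of the same plot — but they carry a hidden
risk: once their locations are known, permanent plots may be treated
differently from the surrounding forest (spared from logging, for example).
Estimates from such plots then track an undisturbed subset while the
landscape degrades around them, overstating the biomass change exactly
where accounting needs honesty. This package is a desk-scale laboratory for
quantifying that trade-off.

It provides:

* a calibrated synthetic two-occasion tropical-forest population
  (750 plots of 400 m², power-law allometry, inverse-J diameter structure,
  plot-correlated growth, mortality);
* deforestation and degradation scenarios (fraction of plots affected ×
  tree-removal rule), each carrying both the disturbed and undisturbed
  occasion-2 biomass so *treatment bias* is expressible;
* the three classical change estimators with their variance formulas. In
  field notation, with plot biomasses `x` (occasion 1) and `y` (occasion 2):
  * temporary: `Δ = ȳ − x̄`, `V = s²_x/n₁ + s²_y/n₂` (independent samples);
  * CFI: same `Δ` on paired plots, `V = (s²_x + s²_y − 2 r s_x s_y)/n`;
  * SPR: a regression-updated mean from the matched plots and the plain
    mean of the new plots, combined with inverse-variance weights, minus
    the full occasion-1 mean — including the variance-inflation term for
    estimated weights and a corrected covariance term (see
    `?spr_change`, argument `mode`);
* a Monte Carlo engine crossing scenarios × designs × bias variants with a
  fully reproducible labelled child-seed scheme;
* an equivalence-based diagnostic (`Welch + TOST`) that tests permanent
  against temporary plots for the observable signature of treatment bias.

## Worked example

```r
library(sprforest)

pop <- generate_population(population_params(), seed = 101)
panel <- apply_scenario(pop, default_scenarios()$deg20_above45, seed = 1)
summarize_panel(panel)
#> # A tibble: 2 × 8
#>   occasion     n   min   max  mean median    sd correlation
#>      <int> <int> <dbl> <dbl> <dbl>  <dbl> <dbl>       <dbl>
#> 1        1   750  14.7  413.  123.   111.  61.4       0.729
#> 2        2   750  17.8  853.  122.   106.  79.4       0.729

true_change(panel)
#> # A tibble: 1 × 3
#>   mean_t1 mean_t2 change
#>     <dbl>   <dbl>  <dbl>
#> 1    123.    122.  -1.17
```

Heavy degradation of large trees (20% of plots, dbh > 45 cm removed) is the
one default scenario where growth no longer compensates the loss: the true
landscape change is negative. An honest SPR estimate from one sample:

```r
roles <- draw_samples(750, default_designs()$spr, seed = 2)
est <- estimate_spr(panel$x_t1[roles$t1_ids],
                    panel$x_t1[roles$permanent_ids],
                    panel$y_t2_disturbed[roles$permanent_ids],
                    panel$y_t2_disturbed[roles$t2_new_ids])
est
#> <change_estimate: spr>
#>   change -1.779 t/ha, SE 3.434 (n1 = 375, n2 = 375)
```

The Monte Carlo comparison over 200 iterations (same population; each
iteration draws fresh affected plots and fresh samples; under treatment
bias, sampled permanent plots report their undisturbed biomass while the
truth stays the disturbed landscape mean):

```r
res <- suppressWarnings(run_experiment(pop, iterations = 200, master_seed = 42))
s <- summarize_experiment(res)
dplyr::filter(s, scenario == "deg20_above45") |>
  dplyr::select(design, bias, mean_change, mean_true_change, mean_diff, pct_se)
#> # A tibble: 6 × 6
#>   design    bias  mean_change mean_true_change mean_diff pct_se
#>   <chr>     <lgl>       <dbl>            <dbl>     <dbl>  <dbl>
#> 1 cfi       FALSE      -0.964           -0.922   -0.0419   308.
#> 2 cfi       TRUE       13.9             -0.922   14.8      239.
#> 3 spr       FALSE      -1.61            -0.922   -0.693    360.
#> 4 spr       TRUE        8.94            -0.922    9.86     299.
#> 5 temporary FALSE      -1.22            -0.922   -0.296    561.
#> 6 temporary TRUE       -1.22            -0.922   -0.296    561.
```

This is the core result: without bias, all designs are unbiased and CFI is
the most precise, followed by SPR, then temporary plots (the `pct_se`
values are huge here only because the true change is near zero). With
treatment bias the ranking inverts into a bias ranking — CFI turns a true
−0.9 t/ha into +14 t/ha, SPR into +9 (its new plots see the degraded
landscape), while temporary plots stay unbiased.

The drift is detectable from data:

```r
compare_permanent_temporary(panel$y_t2_undisturbed[roles$permanent_ids],
                            panel$y_t2_disturbed[roles$t2_new_ids])
#> # A tibble: 1 × 9
#>   mean_diff    se statistic    df p_value p_tost margin alpha verdict
#>       <dbl> <dbl>     <dbl> <dbl>   <dbl>  <dbl>  <dbl> <dbl> <chr>
#> 1      18.3  7.87      2.32  351.  0.0209  0.796   11.7  0.05 evidence_of_bias
```

## Command line

An executable `sprforest` script is installed under `exec/`:

```sh
sprforest gen-pop --out trees.csv --seed 3
sprforest apply-scenario --trees trees.csv --scenario defor5 --seed 2 --out panel.csv
sprforest run-mc --config experiment.yaml --out results/
sprforest bias-check --permanent perm.csv --temporary temp.csv
```

Default parameter, scenario, design, and experiment files ship in
`inst/extdata/`.

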