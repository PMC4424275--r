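Package: sprforest
Title: Sampling with Partial Replacement for Forest Biomass Change Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based comparison of forest-inventory sampling designs for
    estimating aboveground-biomass change on successive occasions: temporary
    plots, continuous forest inventory (CFI) with permanent plots, and sampling
    with partial replacement (SPR). Provides a calibrated two-occasion synthetic
    tropical-forest population, deforestation and degradation scenario
    simulators including treatment-bias variants, the classical change
    estimators with their variance formulas, a Monte Carlo experiment engine,
    and an equivalence-based diagnostic for treatment bias on permanent plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
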