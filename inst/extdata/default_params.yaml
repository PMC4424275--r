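# Calibrated defaults of the synthetic two-occasion forest population.
# A 750-plot draw reproduces occasion plot-biomass means of about
# 120.3 / 132.5 t/ha, tree counts of about 8650 / 8191 and a
# between-occasion plot correlation near 0.80.
n_plots: 750
plot_area_m2: 400.0
trees_per_plot_mean: 11.533333
dbh_min: 15.0
dbh_scale: 15.147
mortality_prob: 0.053064
growth_mean: 2.40
growth_sd: 1.5
plot_growth_sd: 1.90
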