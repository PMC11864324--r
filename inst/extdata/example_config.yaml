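# Example run configuration for forestcl::read_run_config().
# Paths are relative to the working directory at run time.
out_dir: results/example_run
trees_csv: results/demo/trees.csv
plot_covariates_csv: results/demo/plot_covariates.csv
traits_csv: results/demo/traits.csv
seed: 1
# fitting
iterations: 20000
restarts: 3
min_trees: 500
delta_aic: 4.0
ns_corr_threshold: 0.7
# critical-load reduction fractions
f_growth: 0.05
f_survival: 0.01
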