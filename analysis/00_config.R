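# Shared configuration for the analysis scripts. Source this first.
#
# The demonstration scenario: 6 species across 4 ecoregion Divisions
# (cool/wet 21, warm/high-deposition 22, prairie 25, dry interior 34),
# 700 trees per species x Division, with generating models chosen to
# realize every response shape on the vulnerability scale. All
# randomness flows from DEMO_SEED.

library(forestcl)

DEMO_SEED <- 20260926L
OUT_DIR <- file.path("results", "demo")

demo_run_config <- function(seed = DEMO_SEED, out_dir = OUT_DIR,
                            iterations = 3000L) {
  species <- c("ACRU", "PIPO", "QUAL", "TSCA", "PSME", "LITU")
  divisions <- c("21", "22", "25", "34")
  grad <- division_gradients()
  shapes_cycle <- list(
    list(has_N = TRUE, s_form = "sigmoid", n1_factor = 1.0),   # unimodal N
    list(has_N = TRUE, s_form = "lognormal", n1_factor = 2.5), # increasing N
    list(has_N = FALSE, s_form = "sigmoid"),                   # flat N
    list(has_N = TRUE, s_form = "none", n1_factor = 0.3),      # decreasing N
    list(has_N = TRUE, s_form = "sigmoid", n1_factor = 1.2))
  tp <- list()
  i <- 0L
  for (sp in species) for (dv in divisions) {
    i <- i + 1L
    sc <- shapes_cycle[[1L + (i - 1L) %% length(shapes_cycle)]]
    row <- grad[grad$division == dv, ]
    for (ep in c("growth", "survival")) {
      tp[[paste(sp, dv, ep, sep = "|")]] <- list(
        has_N = sc$has_N, s_form = sc$s_form,
        params = default_true_params(ep, row, has_N = sc$has_N,
                                     s_form = sc$s_form,
                                     n1_factor = if (is.null(sc$n1_factor)) 1
                                                 else sc$n1_factor))
    }
  }
  scen <- scenario_config(species = species, divisions = divisions,
                          n_trees_per_unit = 700L, true_params = tp,
                          ns_rho = 0.35, n_excluded_per_unit = 3L,
                          seed = seed)
  run_config(out_dir = out_dir,
             fit = fit_config(iterations = iterations, restarts = 2L,
                              min_trees = 500L),
             scenario = scen,
             tree_newick = file.path(out_dir, "species_phylogeny.nwk"),
             stage2_scope = shape ~ Ndep + Sdep + soil_pH + leaf_habit,
             seed = seed)
}
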