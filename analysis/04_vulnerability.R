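# Stage 4: model the ordered vulnerability of the response shapes
# against Division-level covariates and traits with proportional-odds
# regressions (stepwise AIC from the hypothesis scope), run the Fisher
# and ANOVA/Tukey supporting tests, and check phylogenetic signal in the
# species-level residuals. Writes ordinal_results.json, tests.csv and
# phylo_signal.json.

source(file.path("analysis", "00_config.R"))

config <- demo_run_config()
shapes <- read.csv(file.path(config$out_dir, "shapes.csv"),
                   stringsAsFactors = FALSE,
                   colClasses = c(division = "character"))
plot_cov <- read.csv(file.path(config$out_dir, "plot_covariates.csv"),
                     stringsAsFactors = FALSE,
                     colClasses = c(division = "character"))
traits <- read.csv(file.path(config$out_dir, "traits.csv"),
                   stringsAsFactors = FALSE)
phylo <- ape::read.tree(config$tree_newick)

reg <- stage_regress(config, shapes, plot_cov, traits, phylo = phylo)

for (key in names(reg$ordinal)) {
  m <- reg$ordinal[[key]]
  if (m$status != "ok") {
    cat(key, ": ordinal fit not available (", m$message, ")\n")
    next
  }
  cat(key, ": n =", m$n, " AICc =", round(m$AICc, 1),
      " Nagelkerke R2 =", round(m$nagelkerke_r2, 3), "\n")
  if (!is.null(m$odds_ratios) && nrow(m$odds_ratios)) {
    or <- m$odds_ratios
    cat("  odds ratios:",
        paste(sprintf("%s %.2f [%.2f, %.2f]", or$term, or$odds_ratio,
                      or$lo, or$hi), collapse = "; "), "\n")
  }
}
cat("\nSupporting tests:\n")
print(reg$tests, digits = 3)
if (length(reg$phylo_signal)) {
  cat("\nBlomberg K on species-level ordinal residuals:\n")
  for (key in names(reg$phylo_signal)) {
    ps <- reg$phylo_signal[[key]]
    cat(" ", key, ": K =", round(ps$K, 3), " p =", round(ps$p_value, 3),
        "(", ps$n_species, "species )\n")
  }
}
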