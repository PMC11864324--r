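# Stage 5: reconcile counts across stages and write a run report.

source(file.path("analysis", "00_config.R"))

config <- demo_run_config()
sel <- read.csv(file.path(config$out_dir, "selection.csv"),
                stringsAsFactors = FALSE)
shapes <- read.csv(file.path(config$out_dir, "shapes.csv"),
                   stringsAsFactors = FALSE,
                   colClasses = c(division = "character"))
cl <- read.csv(file.path(config$out_dir, "cl.csv"),
               stringsAsFactors = FALSE)
trees <- read.csv(file.path(config$out_dir, "trees.csv"),
                  stringsAsFactors = FALSE)

stopifnot(nrow(shapes) == 2 * nrow(sel))    # two pollutants per unit

report <- list(
  seed = config$seed,
  iterations = config$fit$iterations,
  n_tree_records = nrow(trees),
  n_units_attempted = nrow(sel),
  n_selected = sum(sel$status == "selected"),
  n_excluded_ns = sum(sel$status == "excluded_ns_collinearity"),
  n_insufficient = sum(sel$status == "insufficient_data"),
  shape_distribution = as.data.frame(table(shapes$shape)),
  cl_quantiles = as.list(round(quantile(
    cl$cl_kg_ha_yr, c(0.05, 0.5, 0.95), na.rm = TRUE), 2)),
  package_version = as.character(packageVersion("forestcl")))
jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("Units:", report$n_units_attempted, "attempted;",
    report$n_selected, "selected;",
    report$n_excluded_ns, "excluded (N-S collinearity);",
    report$n_insufficient, "insufficient data\n")
cat("Shapes across endpoints and pollutants:\n")
print(table(shapes$shape))
cat("Critical-load quantiles (kg ha-1 yr-1):\n")
print(unlist(report$cl_quantiles))
cat("Report written to", file.path(config$out_dir, "report.json"), "\n")
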