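# Stage 3: classify every selected unit's N and S response shape on the
# vulnerability scale and compute critical loads (n1 / s1 directly;
# sigmoid S by inversion at f = 5% for growth, 1% for survival). Writes
# shapes.csv and cl.csv, and checks shape recovery against the truth
# manifest.

source(file.path("analysis", "00_config.R"))

config <- demo_run_config()
ingested <- ingest_trees(file.path(config$out_dir, "trees.csv"),
                         min_trees = config$fit$min_trees)
selections <- read_selections(config$out_dir, config$fit)
cls <- stage_classify(config, selections, ingested)

cat("Shape distribution (growth, N):\n")
sub <- cls$shapes[cls$shapes$endpoint == "growth" &
                    cls$shapes$pollutant == "N", ]
print(table(sub$division, sub$shape))

manifest <- jsonlite::read_json(file.path(config$out_dir,
                                          "truth_manifest.json"))
hits <- 0L; tot <- 0L
for (i in seq_len(nrow(sub))) {
  tr <- manifest[[paste(sub$species[i], sub$division[i], sep = "|")]]
  if (is.null(tr) || sub$shape[i] == "not_applicable") next
  tot <- tot + 1L
  if (sub$shape[i] == tr$growth$expected_n_shape) hits <- hits + 1L
}
cat("Growth N-shape recovery vs. truth manifest:", hits, "/", tot, "\n")

cl <- cls$cl
defined <- cl[!is.na(cl$cl_kg_ha_yr), ]
cat("Critical loads (kg ha-1 yr-1) by pollutant:\n")
print(aggregate(cl_kg_ha_yr ~ pollutant + endpoint, defined,
                function(x) round(quantile(x, c(0.25, 0.5, 0.75)), 1)))
out_of_range <- defined$cl_kg_ha_yr > defined$dep_max |
  defined$cl_kg_ha_yr < defined$dep_min
cat(sum(out_of_range), "of", nrow(defined),
    "critical loads fall outside the unit's observed deposition range\n")
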