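## Orchestration: ingest/validation, the simulate -> fit -> classify ->
## regress -> report flow, and CSV/JSON serialization of every
## intermediate so runs are inspectable and resumable.

#' Run configuration
#'
#' @param out_dir Output directory (created if needed); every stage
#'   writes its tables there.
#' @param fit A [fit_config()]; its `seed` is ignored in favour of
#'   `seed` here.
#' @param f_growth,f_survival Reduction fractions for sigmoid S critical
#'   loads, by endpoint.
#' @param endpoints Endpoints to analyse.
#' @param scenario Optional [scenario_config()]; when present the
#'   simulate stage generates the inputs, otherwise `trees_csv`,
#'   `plot_covariates_csv` and `traits_csv` must point at existing files.
#' @param trees_csv,plot_covariates_csv,traits_csv,tree_newick Input
#'   paths used when no scenario is given (the Newick phylogeny is
#'   optional).
#' @param stage2_scope Formula for the stage-2 stepwise scope (default
#'   [stage2_scope()]).
#' @param fisher_B Monte-Carlo draws for R x C Fisher tests.
#' @param seed Master seed; all per-stage seeds derive from it.
#' @return A `forestcl_run_config` list.
#' @export
run_config <- function(out_dir, fit = fit_config(), f_growth = 0.05,
                       f_survival = 0.01,
                       endpoints = c("growth", "survival"),
                       scenario = NULL, trees_csv = NULL,
                       plot_covariates_csv = NULL, traits_csv = NULL,
                       tree_newick = NULL, stage2_scope = NULL,
                       fisher_B = 2000L, seed = 1L) {
  stopifnot(f_growth > 0, f_growth < 1, f_survival > 0, f_survival < 1)
  fit$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, fit = fit, f_growth = f_growth,
                 f_survival = f_survival, endpoints = endpoints,
                 scenario = scenario, trees_csv = trees_csv,
                 plot_covariates_csv = plot_covariates_csv,
                 traits_csv = traits_csv, tree_newick = tree_newick,
                 stage2_scope = stage2_scope, fisher_B = as.integer(fisher_B),
                 seed = as.integer(seed)),
            class = "forestcl_run_config")
}

#' Read a YAML run-configuration file
#'
#' Convenience reader mapping a flat YAML document onto [run_config()]
#' and [fit_config()] fields.
#' @param path YAML file.
#' @param out_dir Output directory (overrides the file's `out_dir`).
#' @return A `forestcl_run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_run_config requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  fit_args <- y[intersect(names(y), names(formals(fit_config)))]
  run_args <- y[intersect(names(y), names(formals(run_config)))]
  run_args$fit <- do.call(fit_config, fit_args)
  if (!is.null(out_dir)) run_args$out_dir <- out_dir
  do.call(run_config, run_args)
}

#' Ingest and validate a tree-record table
#'
#' Checks the canonical schema ([tree_record_columns()]), rejects rows
#' with non-finite covariates, non-positive size/interval/basal area or
#' `BAL > BA` (hard failure when more than `max_invalid_frac` of rows are
#' invalid), and builds the survival analysis set by dropping records
#' flagged harvested or dead at both censuses (a `status` column, when
#' present).
#'
#' @param trees Data frame or path to a CSV in the canonical schema.
#' @param min_trees Unit-size cutoff used to flag small units.
#' @param max_invalid_frac Hard-failure threshold on the invalid-row
#'   fraction.
#' @return List: `trees` (validated growth set), `survival_trees`,
#'   `report` (row counts, drop reasons, flagged small units).
#' @export
ingest_trees <- function(trees, min_trees = 500L, max_invalid_frac = 0.01) {
  if (is.character(trees)) {
    trees <- utils::read.csv(trees, stringsAsFactors = FALSE,
                             colClasses = c(division = "character"))
  }
  missing_cols <- setdiff(tree_record_columns(), names(trees))
  if (length(missing_cols)) {
    stop("ingest_trees: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- c("size_kgC", "growth_kgC_yr", "dt_yr", "ba_m2ha", "bal_m2ha",
                "temp_K", "precip_dm", "ndep_kgN_ha_yr", "sdep_kgS_ha_yr")
  for (cl in num_cols) {
    if (!is.numeric(trees[[cl]])) {
      stop("ingest_trees: column '", cl, "' is not numeric")
    }
  }
  n0 <- nrow(trees)
  bad <- !is.finite(trees$size_kgC) | trees$size_kgC <= 0 |
    !is.finite(trees$dt_yr) | trees$dt_yr <= 0 |
    !is.finite(trees$ba_m2ha) | trees$ba_m2ha <= 0 |
    !is.finite(trees$bal_m2ha) | trees$bal_m2ha < 0 |
    trees$bal_m2ha > trees$ba_m2ha |
    !is.finite(trees$temp_K) | trees$temp_K <= 0 |
    !is.finite(trees$precip_dm) | trees$precip_dm <= 0 |
    !is.finite(trees$ndep_kgN_ha_yr) | trees$ndep_kgN_ha_yr < 0 |
    !is.finite(trees$sdep_kgS_ha_yr) | trees$sdep_kgS_ha_yr < 0
  if (mean(bad) > max_invalid_frac) {
    stop("ingest_trees: ", sum(bad), " of ", n0, " rows invalid (",
         round(100 * mean(bad), 1), "% > ",
         100 * max_invalid_frac, "% allowed)")
  }
  valid <- trees[!bad, , drop = FALSE]
  n_status_dropped <- 0L
  surv <- valid
  if ("status" %in% names(valid)) {
    keep <- !(valid$status %in% c("harvested", "dead_both"))
    n_status_dropped <- sum(!keep)
    surv <- valid[keep, , drop = FALSE]
  }
  unit_n <- table(paste(valid$species, valid$division, sep = "|"))
  small_units <- names(unit_n)[unit_n < min_trees]
  list(trees = valid, survival_trees = surv,
       report = list(n_input = n0, n_invalid = sum(bad),
                     n_status_dropped = n_status_dropped,
                     small_units = small_units, min_trees = min_trees))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

fits_to_df <- function(selections) {
  rows <- list()
  for (sel in selections) {
    for (f in sel$all_fits) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sel$species, division = sel$division,
        endpoint = sel$endpoint, spec = f$spec$label, k = f$spec$k,
        logLik = f$logLik, AIC = f$AIC, n_obs = f$n_obs,
        converged = f$converged, seed = f$seed,
        params = as.character(jsonlite::toJSON(as.list(f$params),
                                               auto_unbox = TRUE,
                                               digits = NA)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

selection_to_df <- function(selections) {
  do.call(rbind, lapply(selections, function(sel) data.frame(
    species = sel$species, division = sel$division,
    endpoint = sel$endpoint, status = sel$status,
    selected_spec = if (is.null(sel$selected_fit)) NA_character_ else
      sel$selected_fit$spec$label,
    n_candidates = length(sel$candidate_set),
    ns_correlation = sel$ns_correlation, stringsAsFactors = FALSE)))
}

#' Reconstruct per-unit selections from serialized fit tables
#'
#' Reads `fits.csv` and `selection.csv` from a run directory, rebuilds the
#' fitted-model objects (parameters are stored as JSON in the table), and
#' re-applies the selection rule, so downstream stages can resume from a
#' previous run's intermediates.
#'
#' @param out_dir Run directory holding `fits.csv` and `selection.csv`.
#' @param config A [fit_config()] with the selection thresholds to apply.
#' @return Named list of `forestcl_selection` objects keyed
#'   `endpoint|species|division`.
#' @export
read_selections <- function(out_dir, config = fit_config()) {
  fits_df <- utils::read.csv(file.path(out_dir, "fits.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(division = "character"))
  sel_df <- utils::read.csv(file.path(out_dir, "selection.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(division = "character"))
  all_specs <- c(enumerate_models("growth"), enumerate_models("survival"))
  spec_by_label <- stats::setNames(all_specs, vapply(all_specs, `[[`,
                                                     character(1), "label"))
  out <- list()
  for (i in seq_len(nrow(sel_df))) {
    row <- sel_df[i, ]
    sub <- fits_df[fits_df$species == row$species &
                     fits_df$division == row$division &
                     fits_df$endpoint == row$endpoint, , drop = FALSE]
    fits <- lapply(seq_len(nrow(sub)), function(j) {
      structure(list(
        spec = spec_by_label[[sub$spec[j]]],
        params = unlist(jsonlite::fromJSON(sub$params[j])),
        logLik = sub$logLik[j], AIC = sub$AIC[j], n_obs = sub$n_obs[j],
        converged = sub$converged[j], seed = sub$seed[j]),
        class = "forestcl_fit")
    })
    sel <- if (row$status == "insufficient_data" && !length(fits)) {
      structure(list(species = row$species, division = row$division,
                     endpoint = row$endpoint, status = "insufficient_data",
                     selected_fit = NULL, candidate_set = list(),
                     ns_correlation = row$ns_correlation),
                class = "forestcl_selection")
    } else {
      select_model(fits, row$ns_correlation, config,
                   species = row$species, division = row$division,
                   endpoint = row$endpoint)
    }
    sel$all_fits <- fits
    out[[paste(row$endpoint, row$species, row$division, sep = "|")]] <- sel
  }
  out
}

## ---- stages ----------------------------------------------------------------

#' Pipeline stages
#'
#' The four computation stages behind [run_pipeline()], exposed so an
#' analysis can be driven (and resumed) stage by stage: `stage_simulate`
#' generates and writes the synthetic inputs; `stage_fit` fits and
#' selects candidate models per unit (writing `fits.csv`,
#' `selection.csv`); `stage_classify` writes `shapes.csv` and `cl.csv`;
#' `stage_regress` runs the ordinal vulnerability models and supporting
#' tests (`ordinal_results.json`, `tests.csv`, `phylo_signal.json`).
#'
#' @param config A [run_config()].
#' @param ingested Output of [ingest_trees()].
#' @param selections List of `forestcl_selection` (from [stage_fit()] or
#'   [read_selections()]).
#' @param shapes,plot_covariates,traits Data frames as written by the
#'   earlier stages.
#' @param phylo Optional `ape::phylo` for the phylogenetic-signal check.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  gen <- generate_trees(config$scenario, f_growth = config$f_growth,
                        f_survival = config$f_survival)
  utils::write.csv(gen$trees, file.path(config$out_dir, "trees.csv"),
                   row.names = FALSE)
  utils::write.csv(gen$plot_covariates,
                   file.path(config$out_dir, "plot_covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(gen$traits, file.path(config$out_dir, "traits.csv"),
                   row.names = FALSE)
  write_json_out(gen$manifest,
                 file.path(config$out_dir, "truth_manifest.json"))
  gen
}

#' @rdname pipeline_stages
#' @export
stage_fit <- function(config, ingested) {
  selections <- list()
  for (endpoint in config$endpoints) {
    dat <- if (endpoint == "survival") ingested$survival_trees else
      ingested$trees
    units <- unique(dat[c("species", "division")])
    units <- units[order(units$species, units$division), , drop = FALSE]
    for (i in seq_len(nrow(units))) {
      sp <- units$species[i]; dv <- units$division[i]
      rec <- dat[dat$species == sp & dat$division == dv, , drop = FALSE]
      cfg <- config$fit
      cfg$seed <- derive_seed(config$seed,
                              match(endpoint, c("growth", "survival")), i)
      selections[[paste(endpoint, sp, dv, sep = "|")]] <-
        fit_unit(rec, endpoint, cfg, species = sp, division = dv)
    }
  }
  utils::write.csv(fits_to_df(selections),
                   file.path(config$out_dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(selection_to_df(selections),
                   file.path(config$out_dir, "selection.csv"),
                   row.names = FALSE)
  selections
}

#' @rdname pipeline_stages
#' @export
stage_classify <- function(config, selections, ingested) {
  shapes <- list(); cls <- list()
  for (sel in selections) {
    dat <- if (sel$endpoint == "survival") ingested$survival_trees else
      ingested$trees
    rec <- dat[dat$species == sel$species & dat$division == sel$division, ]
    n_rng <- range(rec$ndep_kgN_ha_yr)
    s_rng <- range(rec$sdep_kgS_ha_yr)
    n_shape <- classify_n_shape(sel, n_rng)
    s_shape <- classify_s_shape(sel)
    shapes[[length(shapes) + 1L]] <- data.frame(
      species = sel$species, division = sel$division,
      endpoint = sel$endpoint,
      pollutant = c("N", "S"), shape = c(n_shape, s_shape),
      stringsAsFactors = FALSE)
    if (sel$status == "selected") {
      cl <- unit_critical_loads(sel, config$f_growth, config$f_survival)
      cls[[length(cls) + 1L]] <- data.frame(
        species = sel$species, division = sel$division,
        endpoint = sel$endpoint, pollutant = c("N", "S"),
        basis = c(cl$N$basis, cl$S$basis),
        f = c(cl$N$f, cl$S$f),
        cl_kg_ha_yr = c(cl$N$value, cl$S$value),
        dep_min = c(n_rng[1], s_rng[1]), dep_max = c(n_rng[2], s_rng[2]),
        stringsAsFactors = FALSE)
    }
  }
  shapes <- do.call(rbind, shapes)
  cls <- if (length(cls)) do.call(rbind, cls) else data.frame()
  utils::write.csv(shapes, file.path(config$out_dir, "shapes.csv"),
                   row.names = FALSE)
  utils::write.csv(cls, file.path(config$out_dir, "cl.csv"),
                   row.names = FALSE)
  list(shapes = shapes, cl = cls)
}

# Mean observed-minus-expected vulnerability rank per species: the
# numeric residual fed to the phylogenetic-signal test.
ordinal_species_residuals <- function(ordfit, table) {
  pr <- stats::predict(ordfit$fit, newdata = table, type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = nrow(table), byrow = TRUE)
  expected <- drop(pr %*% seq_len(ncol(pr)))
  res <- as.integer(table$shape) - expected
  tapply(res, table$species, mean)
}

#' @rdname pipeline_stages
#' @export
stage_regress <- function(config, shapes, plot_covariates, traits,
                          phylo = NULL) {
  results <- list(); tests <- list(); phylo_signal <- list()
  scope <- config$stage2_scope %||% stage2_scope()
  for (endpoint in config$endpoints) {
    for (pol in c("N", "S")) {
      key <- paste(endpoint, pol, sep = "_")
      sub <- shapes[shapes$endpoint == endpoint & shapes$pollutant == pol, ]
      tab <- build_covariate_table(sub, plot_covariates, traits)
      fit <- tryCatch(suppressWarnings(stepwise_aic(tab, scope)),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        results[[key]] <- list(status = "failed",
                               message = conditionMessage(fit),
                               n = nrow(tab))
      } else {
        results[[key]] <- list(
          status = "ok", n = fit$n,
          formula = deparse(fit$formula),
          coefficients = as.list(fit$coefficients),
          thresholds = as.list(fit$thresholds),
          logLik = fit$logLik, AIC = fit$AIC, AICc = fit$AICc,
          nagelkerke_r2 = fit$nagelkerke_r2,
          odds_ratios = fit$odds_ratios,
          step_trace = data.frame(step = as.character(fit$step_trace$Step),
                                  AIC = fit$step_trace$AIC))
        if (!is.null(phylo)) {
          res <- ordinal_species_residuals(fit, tab)
          common <- intersect(phylo$tip.label, names(res))
          if (length(common) >= 3) {
            pruned <- ape::keep.tip(phylo, common)
            ks <- blomberg_k(pruned, res[common], n_perm = 999L,
                             seed = derive_seed(config$seed, 91,
                                                nchar(key)))
            phylo_signal[[key]] <- list(K = ks$K, p_value = ks$p_value,
                                        n_species = length(common))
          }
        }
      }
      ct <- table(tab$shape, tab$division)
      ct <- ct[rowSums(ct) > 0, colSums(ct) > 0, drop = FALSE]
      fp <- if (all(dim(ct) >= 2)) {
        fisher_exact_shapes(ct, B = config$fisher_B,
                            seed = derive_seed(config$seed, 7,
                                               nchar(key)))$p_value
      } else NA_real_
      tests[[length(tests) + 1L]] <- data.frame(
        test = "fisher_shapes_by_division", endpoint = endpoint,
        pollutant = pol, statistic = NA_real_, p_value = fp,
        stringsAsFactors = FALSE)
    }
  }
  # Division-level differences in each continuous covariate
  cov_tab <- unique(build_covariate_table(
    shapes[shapes$pollutant == "N", ], plot_covariates, traits)[
      c("species", "division", "MAT", "MAP", "soil_pH", "Ndep", "Sdep")])
  for (v in c("MAT", "MAP", "soil_pH", "Ndep", "Sdep")) {
    av <- tryCatch(anova_tukey(cov_tab[[v]], cov_tab$division),
                   error = function(e) NULL)
    if (!is.null(av)) {
      tests[[length(tests) + 1L]] <- data.frame(
        test = paste0("anova_", v), endpoint = "both", pollutant = "both",
        statistic = av$F, p_value = av$p_value, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  write_json_out(results, file.path(config$out_dir, "ordinal_results.json"))
  utils::write.csv(tests, file.path(config$out_dir, "tests.csv"),
                   row.names = FALSE)
  if (length(phylo_signal)) {
    write_json_out(phylo_signal,
                   file.path(config$out_dir, "phylo_signal.json"))
  }
  list(ordinal = results, tests = tests, phylo_signal = phylo_signal)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (when the config carries a scenario) or
#' read inputs; ingest/validate; fit and select candidate models per
#' species x Division x endpoint; classify response shapes and compute
#' critical loads; stage-2 ordinal regressions and supporting tests;
#' report. Every stage writes its tables (CSV/JSON) under the config's
#' output directory, and the whole run is reproducible from the single
#' seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage outputs and the run report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "forestcl_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$scenario)) {
    gen <- stage_simulate(config)
    trees <- gen$trees; plot_cov <- gen$plot_covariates; traits <- gen$traits
  } else {
    trees <- utils::read.csv(config$trees_csv, stringsAsFactors = FALSE,
                             colClasses = c(division = "character"))
    plot_cov <- utils::read.csv(config$plot_covariates_csv,
                                stringsAsFactors = FALSE,
                                colClasses = c(division = "character"))
    traits <- utils::read.csv(config$traits_csv, stringsAsFactors = FALSE)
  }
  phylo <- if (!is.null(config$tree_newick)) {
    ape::read.tree(config$tree_newick)
  }
  ingested <- ingest_trees(trees, min_trees = config$fit$min_trees)
  selections <- stage_fit(config, ingested)
  classified <- stage_classify(config, selections, ingested)
  regressed <- stage_regress(config, classified$shapes, plot_cov, traits,
                             phylo = phylo)
  statuses <- vapply(selections, `[[`, character(1), "status")
  shape_dist <- as.data.frame(table(classified$shapes$division,
                                    classified$shapes$shape))
  names(shape_dist) <- c("division", "shape", "count")
  cl_vals <- classified$cl$cl_kg_ha_yr
  report <- list(
    seed = config$seed,
    iterations = config$fit$iterations,
    n_trees_ingested = nrow(ingested$trees),
    n_survival_trees = nrow(ingested$survival_trees),
    ingest = ingested$report,
    n_units_attempted = length(selections),
    n_selected = sum(statuses == "selected"),
    n_excluded_ns = sum(statuses == "excluded_ns_collinearity"),
    n_insufficient = sum(statuses == "insufficient_data"),
    shape_distribution = shape_dist,
    cl_quantiles = if (length(cl_vals)) as.list(stats::quantile(
      cl_vals, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE)) else NULL,
    package_version = as.character(utils::packageVersion("forestcl")))
  write_json_out(report, file.path(config$out_dir, "report.json"))
  invisible(list(ingested = ingested, selections = selections,
                 shapes = classified$shapes, cl = classified$cl,
                 stage2 = regressed, report = report))
}

#' Bundled small demonstration scenario
#'
#' Four species crossed with three Divisions, 600 trees per unit, with
#' generating models chosen to realize a mix of response shapes
#' (increasing, flat, unimodal and decreasing N responses; sigmoid,
#' lognormal and absent S terms). Sized to run end to end in minutes on
#' one CPU with a reduced annealing budget.
#'
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Master seed.
#' @param iterations Total annealing budget per fit.
#' @param n_trees_per_unit Trees per unit.
#' @return A `forestcl_run_config`.
#' @export
small_run_config <- function(out_dir, seed = 1L, iterations = 4000L,
                             n_trees_per_unit = 600L) {
  species <- c("ACRU", "PIPO", "QUAL", "TSCA")
  divisions <- c("21", "25", "31")
  tp <- list()
  grad <- division_gradients()
  shapes_cycle <- list(
    list(has_N = TRUE, s_form = "sigmoid", n1_factor = 1.0),   # unimodal
    list(has_N = TRUE, s_form = "lognormal", n1_factor = 2.5), # increase
    list(has_N = FALSE, s_form = "sigmoid"),                   # flat N
    list(has_N = TRUE, s_form = "none", n1_factor = 0.3))      # decrease
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
                                     n1_factor = sc$n1_factor %||% 1))
    }
  }
  scen <- scenario_config(species = species, divisions = divisions,
                          n_trees_per_unit = n_trees_per_unit,
                          true_params = tp, ns_rho = 0.3,
                          n_excluded_per_unit = 2L, seed = seed)
  run_config(out_dir = out_dir,
             fit = fit_config(iterations = iterations, restarts = 2L,
                              min_trees = 500L),
             scenario = scen,
             stage2_scope = shape ~ Ndep + Sdep + leaf_habit,
             seed = seed)
}
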