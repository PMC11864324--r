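## Synthetic forest-inventory data: tree records drawn from the package's
## own growth/survival equations with known parameters, Division-level
## covariate gradients, trait tables, ordinal shape datasets from a known
## proportional-odds model, and Yule phylogenies with Brownian traits.
## Every generated dataset carries a truth manifest so recovery is testable.

#' Default Division-level covariate gradients
#'
#' Means and SDs of the plot-level covariates for the 11 conterminous-US
#' ecoregion Divisions. The qualitative pattern mimics the real gradients
#' (wetter east and northwest, higher N and S deposition in the east,
#' higher soil pH in the interior) but the numbers are generator
#' parameters, not data.
#'
#' @return Data frame: division, temp_K, temp_sd, precip_dm, precip_sd,
#'   ndep, ndep_sd, sdep, sdep_sd, soil_pH, pH_sd.
#' @export
division_gradients <- function() {
  g <- data.frame(
    division = c("21", "22", "23", "24", "25", "26",
                 "31", "32", "33", "34", "41"),
    temp_K   = c(279, 284, 291, 283, 285, 288, 290, 292, 281, 282, 297),
    precip_dm = c(10, 10.5, 13, 18, 8, 7, 5, 3, 4.5, 3, 13.5),
    ndep = c(10, 12, 11, 4, 11, 6, 5, 4, 6, 3, 8),
    sdep = c(7, 9, 8, 2.5, 6, 2, 2.5, 2, 3, 1.5, 5),
    soil_pH = c(5.0, 5.3, 5.3, 5.5, 6.2, 6.0, 7.6, 7.7, 6.8, 7.2, 5.8),
    stringsAsFactors = FALSE)
  g$temp_sd <- 2
  g$precip_sd <- 0.15 * g$precip_dm
  g$ndep_sd <- 0.25 * g$ndep
  g$sdep_sd <- 0.25 * g$sdep
  g$pH_sd <- 0.3
  g
}

#' Default generating parameters for a unit
#'
#' Growth and survival parameter vectors anchored at a Division's
#' covariate means, used by [generate_trees()] when the scenario does not
#' override them. The N peak `n1` and sigmoid S midpoint `s1` are placed
#' relative to the Division's deposition mean so that units realize
#' interesting (unimodal / sigmoid) shapes by default.
#'
#' @param endpoint `"growth"` or `"survival"`.
#' @param div_row One row of [division_gradients()].
#' @param has_N,s_form Structure of the generating model.
#' @param n1_factor Multiple of the Division N mean at which the N
#'   modifier peaks.
#' @return Named parameter vector (see [param_names()]).
#' @export
default_true_params <- function(endpoint, div_row, has_N = TRUE,
                                s_form = "sigmoid", n1_factor = 1.1) {
  shared <- c(t1 = div_row$temp_K, t2 = 6,
              p1 = div_row$precip_dm, p2 = 4)
  if (has_N) shared <- c(shared, n1 = n1_factor * div_row$ndep, n2 = 0.6)
  if (s_form == "sigmoid") {
    shared <- c(shared, s1 = 1.2 * div_row$sdep, s2 = 3, s3 = 0.3)
  } else if (s_form == "lognormal") {
    shared <- c(shared, s1 = max(0.3 * div_row$sdep, 0.3), s2 = 2)
  }
  if (endpoint == "growth") {
    c(a = 2.5, z = 0.35, a2 = -0.01, a3 = -0.05, shared, sigma = 1.5)
  } else {
    c(a = 0.995, z1 = 80, z2 = 4, ba1 = 25, ba2 = 5, bl1 = 10, bl2 = 5,
      shared)
  }
}

#' Scenario configuration for the tree-record generator
#'
#' @param species Character vector of species codes.
#' @param divisions Division codes (default: all 11).
#' @param occupancy Optional data frame (species, division) giving which
#'   units exist; default: full cross.
#' @param n_trees_per_unit Trees generated per species x Division.
#' @param true_params Optional named list of overrides keyed
#'   `"species|division|endpoint"`, each a list(has_N, s_form, params).
#' @param gradients Covariate gradients (default [division_gradients()]).
#' @param ns_rho Within-unit correlation between plot N and S deposition.
#' @param trees_per_plot Trees per synthetic plot.
#' @param dt_mean,dt_sd,dt_range Census-interval distribution, years:
#'   normal mean 8.2, SD 2.9, truncated to [5, 10] like typical
#'   inventory remeasurement cycles.
#' @param trait_probs `c(AM = , deciduous = )` species trait
#'   probabilities.
#' @param n_excluded_per_unit Harvested / dead-at-both-census records
#'   injected per unit (to exercise the ingest filter).
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `forestcl_scenario` list.
#' @export
scenario_config <- function(species, divisions = division_gradients()$division,
                            occupancy = NULL, n_trees_per_unit = 600L,
                            true_params = NULL,
                            gradients = division_gradients(),
                            ns_rho = 0.4, trees_per_plot = 5L,
                            dt_mean = 8.2, dt_sd = 2.9, dt_range = c(5, 10),
                            trait_probs = c(AM = 0.4, deciduous = 0.6),
                            n_excluded_per_unit = 0L, seed = 1L) {
  stopifnot(n_trees_per_unit >= 1, abs(ns_rho) < 1,
            all(divisions %in% gradients$division))
  if (is.null(occupancy)) {
    occupancy <- expand.grid(species = species, division = divisions,
                             stringsAsFactors = FALSE)
  }
  stopifnot(nrow(occupancy) > 0)
  structure(list(species = species, divisions = divisions,
                 occupancy = occupancy,
                 n_trees_per_unit = as.integer(n_trees_per_unit),
                 true_params = true_params, gradients = gradients,
                 ns_rho = ns_rho, trees_per_plot = as.integer(trees_per_plot),
                 dt_mean = dt_mean, dt_sd = dt_sd, dt_range = dt_range,
                 trait_probs = trait_probs,
                 n_excluded_per_unit = as.integer(n_excluded_per_unit),
                 seed = as.integer(seed)),
            class = "forestcl_scenario")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

unit_truth <- function(config, sp, dv, endpoint) {
  key <- paste(sp, dv, endpoint, sep = "|")
  ov <- config$true_params[[key]]
  div_row <- config$gradients[config$gradients$division == dv, ]
  if (is.null(ov)) {
    list(has_N = TRUE, s_form = "sigmoid",
         params = default_true_params(endpoint, div_row))
  } else {
    params <- ov$params
    if (is.null(params)) {
      params <- default_true_params(endpoint, div_row,
                                    has_N = isTRUE(ov$has_N),
                                    s_form = ov$s_form %||% "sigmoid")
    }
    list(has_N = isTRUE(ov$has_N %||% TRUE),
         s_form = ov$s_form %||% "sigmoid", params = params)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

truth_spec <- function(endpoint, has_N, s_form) {
  if (endpoint == "growth") {
    new_model_spec("growth", has_N, s_form)
  } else {
    new_model_spec("survival", has_N, s_form, competition_form = "B")
  }
}

#' Generate synthetic tree records with a truth manifest
#'
#' For every occupied species x Division unit, draws plot covariates from
#' the Division gradient (N and S jointly with correlation `ns_rho`),
#' tree sizes and competition, then generates growth as the model mean
#' plus Gaussian noise and survival as a Bernoulli draw of the annual
#' bracket raised to the census interval. Both outcomes are filled on
#' every record. The manifest records each unit's generating spec and
#' parameters, its expected response shapes on the realized deposition
#' range, and the true critical loads.
#'
#' @param config A [scenario_config()].
#' @param f_growth,f_survival Reduction fractions used for the
#'   manifest's true sigmoid S critical loads.
#' @return List: `trees` (data frame in the canonical schema, plus a
#'   `status` column when exclusions are injected), `plot_covariates`
#'   (for stage 2), `traits`, and `manifest` (per-unit truth).
#' @export
generate_trees <- function(config, f_growth = 0.05, f_survival = 0.01) {
  stopifnot(inherits(config, "forestcl_scenario"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  trees <- list(); plots <- list(); manifest <- list()
  set.seed(derive_seed(config$seed, 777))
  traits <- data.frame(
    species = config$species,
    mycorrhiza = ifelse(stats::runif(length(config$species)) <
                          config$trait_probs[["AM"]], "AM", "EcM"),
    leaf_habit = ifelse(stats::runif(length(config$species)) <
                          config$trait_probs[["deciduous"]],
                        "deciduous", "evergreen"),
    stringsAsFactors = FALSE)
  for (u in seq_len(nrow(config$occupancy))) {
    sp <- config$occupancy$species[u]
    dv <- as.character(config$occupancy$division[u])
    set.seed(derive_seed(config$seed, u))
    g <- config$gradients[config$gradients$division == dv, ]
    n <- config$n_trees_per_unit
    n_plots <- max(1L, ceiling(n / config$trees_per_plot))
    plot_id <- paste0(sp, "_", dv, "_p", seq_len(n_plots))
    z1 <- stats::rnorm(n_plots); z2 <- stats::rnorm(n_plots)
    pl <- data.frame(
      species = sp, division = dv, plot_id = plot_id,
      temp_K = stats::rnorm(n_plots, g$temp_K, g$temp_sd),
      precip_dm = pmax(stats::rnorm(n_plots, g$precip_dm, g$precip_sd), 0.5),
      ndep = pmax(g$ndep + g$ndep_sd * z1, 0.3),
      sdep = pmax(g$sdep + g$sdep_sd *
                    (config$ns_rho * z1 +
                       sqrt(1 - config$ns_rho^2) * z2), 0.1),
      soil_pH = stats::rnorm(n_plots, g$soil_pH, g$pH_sd),
      ba = stats::rlnorm(n_plots, log(25), 0.4),
      stringsAsFactors = FALSE)
    idx <- rep(seq_len(n_plots), length.out = n)
    rec <- data.frame(
      tree_id = paste0(sp, "_", dv, "_t", seq_len(n)),
      species = sp, division = dv, plot_id = pl$plot_id[idx],
      size_kgC = stats::rlnorm(n, log(60), 0.9),
      growth_kgC_yr = NA_real_, survived = NA_integer_,
      dt_yr = rtrunc_norm(n, config$dt_mean, config$dt_sd,
                          config$dt_range[1], config$dt_range[2]),
      ba_m2ha = pl$ba[idx], bal_m2ha = NA_real_,
      temp_K = pl$temp_K[idx], precip_dm = pl$precip_dm[idx],
      ndep_kgN_ha_yr = pl$ndep[idx], sdep_kgS_ha_yr = pl$sdep[idx],
      stringsAsFactors = FALSE)
    rec$bal_m2ha <- stats::rbeta(n, 2, 2) * rec$ba_m2ha

    tg <- unit_truth(config, sp, dv, "growth")
    ts <- unit_truth(config, sp, dv, "survival")
    spec_g <- truth_spec("growth", tg$has_N, tg$s_form)
    spec_s <- truth_spec("survival", ts$has_N, ts$s_form)
    mu <- growth_mean(rec, spec_g, tg$params)
    rec$growth_kgC_yr <- mu + stats::rnorm(n, 0, tg$params[["sigma"]])
    br <- survival_bracket(rec, spec_s, ts$params)
    if (any(br <= 0) || any(br > 1)) {
      stop("generate_trees: survival parameters for unit ", sp, " x ", dv,
           " give an annual bracket outside (0, 1]")
    }
    rec$survived <- stats::rbinom(n, 1L, br^rec$dt_yr)

    n_rng <- range(rec$ndep_kgN_ha_yr)
    manifest[[paste(sp, dv, sep = "|")]] <- list(
      species = sp, division = dv,
      growth = truth_summary(spec_g, tg$params, n_rng, f_growth),
      survival = truth_summary(spec_s, ts$params, n_rng, f_survival))

    if (config$n_excluded_per_unit > 0) {
      ex <- rec[seq_len(min(config$n_excluded_per_unit, n)), ]
      ex$tree_id <- paste0(ex$tree_id, "_x")
      ex$status <- rep_len(c("harvested", "dead_both"), nrow(ex))
      rec$status <- "measured"
      rec <- rbind(rec, ex)
    }
    trees[[u]] <- rec
    plots[[u]] <- pl
  }
  trees <- do.call(rbind, trees)
  rownames(trees) <- NULL
  plots <- do.call(rbind, plots)
  plot_covariates <- data.frame(
    species = plots$species, division = plots$division,
    plot_id = plots$plot_id, MAT_C = plots$temp_K - 273.15,
    MAP_mm = plots$precip_dm * 100, soil_pH = plots$soil_pH,
    ndep_kgN_ha_yr = plots$ndep, sdep_kgS_ha_yr = plots$sdep,
    stringsAsFactors = FALSE)
  list(trees = trees, plot_covariates = plot_covariates, traits = traits,
       manifest = manifest)
}

truth_summary <- function(spec, params, n_rng, f) {
  sel <- structure(list(status = "selected",
                        selected_fit = list(spec = spec, params = params)),
                   class = "forestcl_selection")
  expected_n <- classify_n_shape(sel, n_rng)
  expected_s <- classify_s_shape(sel)
  cl_n <- if (spec$has_N) params[["n1"]] else NA_real_
  cl_s <- if (spec$s_form == "sigmoid") {
    critical_load_sigmoid(params[["s1"]], params[["s2"]], params[["s3"]],
                          f)$value
  } else if (spec$s_form == "lognormal") params[["s1"]] else NA_real_
  list(spec = spec$label, params = as.list(params),
       expected_n_shape = expected_n, expected_s_shape = expected_s,
       true_cl_n = cl_n, true_cl_s = cl_s, n_range = n_rng)
}

#' Generate an ordinal shape dataset from a known proportional-odds model
#'
#' Covariate rows are drawn from plausible stage-2 distributions and the
#' ordered shape outcome from P(Y <= j) = logistic(alpha_j - x'beta) at
#' the supplied coefficients, so [fit_proportional_odds()] can be checked
#' for recovery and coverage.
#'
#' @param n_units Number of species x Division rows.
#' @param beta Named coefficients over any of MAT, MAP, soil_pH, Ndep,
#'   Sdep, mycoEcM, leaf_habitevergreen.
#' @param thresholds Strictly increasing cumulative-logit cutpoints
#'   (J - 1 of them).
#' @param seed Integer seed.
#' @return List: `table` (covariate rows with ordered `shape`), `beta`,
#'   `thresholds`.
#' @export
generate_shape_dataset <- function(n_units = 268L,
                                   beta = c(leaf_habitevergreen = log(2.3)),
                                   thresholds = c(-1.5, 0.5, 2.5),
                                   seed = 1L) {
  if (any(diff(thresholds) <= 0)) {
    stop("generate_shape_dataset: thresholds must be strictly increasing")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  tab <- data.frame(
    species = paste0("sp", seq_len(n_units)),
    division = sample(division_gradients()$division, n_units, replace = TRUE),
    MAT = stats::rnorm(n_units, 12, 5),
    MAP = stats::rnorm(n_units, 1000, 300),
    soil_pH = stats::rnorm(n_units, 5.8, 0.7),
    Ndep = stats::rlnorm(n_units, log(8), 0.4),
    Sdep = stats::rlnorm(n_units, log(5), 0.5),
    myco = factor(sample(c("AM", "EcM"), n_units, TRUE, prob = c(0.4, 0.6)),
                  levels = c("AM", "EcM")),
    leaf_habit = factor(sample(c("deciduous", "evergreen"), n_units, TRUE,
                               prob = c(0.6, 0.4)),
                        levels = c("deciduous", "evergreen")),
    stringsAsFactors = FALSE)
  X <- cbind(MAT = tab$MAT, MAP = tab$MAP, soil_pH = tab$soil_pH,
             Ndep = tab$Ndep, Sdep = tab$Sdep,
             mycoEcM = as.numeric(tab$myco == "EcM"),
             leaf_habitevergreen = as.numeric(tab$leaf_habit == "evergreen"))
  eta <- drop(X[, names(beta), drop = FALSE] %*% beta)
  cum <- vapply(thresholds, function(a) stats::plogis(a - eta),
                numeric(n_units))   # n x (J-1) cumulative P(Y <= j)
  u <- stats::runif(n_units)
  cat_idx <- 1L + rowSums(u > cum)
  tab$shape <- factor(shape_levels()[cat_idx], levels = shape_levels(),
                      ordered = TRUE)
  list(table = tab, beta = beta, thresholds = thresholds)
}

#' Generate a Yule phylogeny with tip traits
#'
#' Pure-birth (Yule) tree, hence ultrametric, with traits evolved by
#' Brownian motion along the branches or randomly shuffled across tips
#' (destroying any signal).
#'
#' @param n_tips Number of tips (>= 3).
#' @param trait_model `"brownian"` or `"shuffled"`.
#' @param seed Integer seed.
#' @return List: `tree` (an `ape::phylo`), `trait` (named numeric).
#' @export
generate_phylogeny <- function(n_tips, trait_model = c("brownian", "shuffled"),
                               seed = 1L) {
  trait_model <- match.arg(trait_model)
  if (n_tips < 3) stop("generate_phylogeny: n_tips must be >= 3")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  if (trait_model == "shuffled") {
    names(trait) <- sample(names(trait))
    trait <- trait[tree$tip.label]
  }
  list(tree = tree, trait = trait)
}
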