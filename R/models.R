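## Candidate model families and their mean/likelihood functions.
##
## A "spec" describes one candidate model: the endpoint (growth or
## survival), whether a lognormal N term is present, which S form is used
## (none / sigmoid / lognormal), and -- for survival -- which of the two
## competition representations is used. Parameters travel as named numeric
## vectors whose names are fixed by `param_names()`.

#' Canonical tree-record column names
#'
#' The column schema shared by the synthetic generator, the ingest
#' validator and the fitters. Units: size in kg C, growth in kg C tree-1
#' yr-1, census interval in years, basal areas in m2 ha-1, temperature in
#' K, precipitation in dm, deposition in kg ha-1 yr-1.
#' @return Character vector of required column names.
#' @export
tree_record_columns <- function() {
  c("tree_id", "species", "division", "plot_id", "size_kgC",
    "growth_kgC_yr", "survived", "dt_yr", "ba_m2ha", "bal_m2ha",
    "temp_K", "precip_dm", "ndep_kgN_ha_yr", "sdep_kgS_ha_yr")
}

new_model_spec <- function(endpoint, has_N, s_form, competition_form = NA_character_,
                           is_intercept_only = FALSE) {
  spec <- structure(
    list(endpoint = endpoint, has_N = has_N, s_form = s_form,
         competition_form = competition_form,
         is_intercept_only = is_intercept_only),
    class = "forestcl_spec")
  spec$k <- length(param_names(spec))
  spec$label <- spec_label(spec)
  spec
}

spec_label <- function(spec) {
  if (spec$is_intercept_only) return(paste0(spec$endpoint, ":intercept"))
  parts <- "base"
  if (spec$has_N) parts <- c(parts, "N")
  if (spec$s_form != "none") parts <- c(parts, paste0("S", spec$s_form))
  lab <- paste(parts, collapse = "+")
  if (spec$endpoint == "survival") lab <- paste0(lab, ":", spec$competition_form)
  paste0(spec$endpoint, ":", lab)
}

#' @export
print.forestcl_spec <- function(x, ...) {
  cat("<model spec>", x$label, " k =", x$k, "\n")
  invisible(x)
}

#' Free-parameter names of a candidate model
#'
#' For growth models the Gaussian residual SD `sigma` is a fitted
#' parameter and is included; so `length(param_names(spec)) == spec$k`.
#'
#' @param spec A model spec from [enumerate_models()].
#' @return Character vector of parameter names in canonical order.
#' @export
param_names <- function(spec) {
  stopifnot(inherits(spec, "forestcl_spec"))
  if (spec$is_intercept_only) {
    return(if (spec$endpoint == "growth") c("a", "sigma") else "a")
  }
  base <- if (spec$endpoint == "growth") {
    c("a", "z", "a2", "a3")
  } else if (spec$competition_form == "A") {
    c("a", "zc1", "zc2", "zc3", "zc4", "br1", "br2", "br3")
  } else {
    c("a", "z1", "z2", "ba1", "ba2", "bl1", "bl2")
  }
  nm <- c(base, "t1", "t2", "p1", "p2")
  if (spec$has_N) nm <- c(nm, "n1", "n2")
  nm <- switch(spec$s_form,
    none = nm,
    sigmoid = c(nm, "s1", "s2", "s3"),
    lognormal = c(nm, "s1", "s2"))
  if (spec$endpoint == "growth") nm <- c(nm, "sigma")
  nm
}

#' Enumerate the candidate model family for an endpoint
#'
#' Growth has seven candidates of increasing complexity: intercept-only;
#' the "base" model (size, competition, temperature, precipitation); base
#' plus a lognormal N term; base plus a sigmoid or lognormal S term; and
#' base plus N together with either S form. Survival crosses the same six
#' structured candidates with two competition representations (form A:
#' saturating size and a BAL/BA crowding index; form B: lognormal size,
#' BA and BAL+1 terms) and adds a single intercept-only model, for 13.
#'
#' @param endpoint `"growth"` or `"survival"`.
#' @return List of model specs in enumeration order (used for AIC
#'   tie-breaking).
#' @export
enumerate_models <- function(endpoint = c("growth", "survival")) {
  endpoint <- match.arg(endpoint)
  structure_grid <- list(
    list(has_N = FALSE, s_form = "none"),
    list(has_N = TRUE,  s_form = "none"),
    list(has_N = FALSE, s_form = "sigmoid"),
    list(has_N = FALSE, s_form = "lognormal"),
    list(has_N = TRUE,  s_form = "sigmoid"),
    list(has_N = TRUE,  s_form = "lognormal"))
  if (endpoint == "growth") {
    specs <- c(
      list(new_model_spec("growth", FALSE, "none", is_intercept_only = TRUE)),
      lapply(structure_grid, function(g)
        new_model_spec("growth", g$has_N, g$s_form)))
  } else {
    specs <- list(new_model_spec("survival", FALSE, "none",
                                 is_intercept_only = TRUE))
    for (form in c("A", "B")) {
      specs <- c(specs, lapply(structure_grid, function(g)
        new_model_spec("survival", g$has_N, g$s_form, competition_form = form)))
    }
  }
  specs
}

check_params <- function(spec, params) {
  need <- param_names(spec)
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("missing parameter(s) for spec ", spec$label, ": ",
         paste(missing, collapse = ", "))
  }
  params[need]
}

s_term <- function(S, params, s_form) {
  switch(s_form,
    none = rep(1, length(S)),
    sigmoid = sulfur_sigmoid(S, params[["s1"]], params[["s2"]], params[["s3"]]),
    lognormal = {
      # Constrained-negative form: with s1 at or below the minimum observed
      # S only the decreasing limb of the lognormal is exercised.
      lognormal_modifier(floor_deposition(S), params[["s1"]], params[["s2"]])
    })
}

#' Expected growth rate under a candidate model
#'
#' Multiplicative model: a potential growth rate `a` scaled by a size
#' power `m^z`, a competition term `exp(a2*BAL + a3*ln BA)`, lognormal
#' temperature and precipitation modifiers, and optional lognormal N and
#' sigmoid/lognormal S deposition terms. The intercept-only model returns
#' `a` for every tree.
#'
#' @param records Data frame of tree records (see [tree_record_columns()]).
#' @param spec Growth model spec.
#' @param params Named parameter vector for `spec`.
#' @return Expected growth, kg C tree-1 yr-1, one value per record.
#' @export
growth_mean <- function(records, spec, params) {
  stopifnot(inherits(spec, "forestcl_spec"), spec$endpoint == "growth")
  n <- nrow(records)
  if (spec$is_intercept_only) return(rep(params[["a"]], n))
  params <- check_params(spec, params)
  mu <- params[["a"]] * records$size_kgC^params[["z"]] *
    exp(params[["a2"]] * records$bal_m2ha +
        params[["a3"]] * log(records$ba_m2ha)) *
    lognormal_modifier(records$temp_K, params[["t1"]], params[["t2"]]) *
    lognormal_modifier(records$precip_dm, params[["p1"]], params[["p2"]])
  if (spec$has_N) {
    mu <- mu * lognormal_modifier(floor_deposition(records$ndep_kgN_ha_yr),
                                  params[["n1"]], params[["n2"]])
  }
  mu * s_term(records$sdep_kgS_ha_yr, params, spec$s_form)
}

# Annual survival multiplier (the bracketed term raised to dt).
survival_bracket <- function(records, spec, params) {
  if (spec$is_intercept_only) return(rep(params[["a"]], nrow(records)))
  params <- check_params(spec, params)
  m <- records$size_kgC
  comp <- if (spec$competition_form == "A") {
    baratio <- records$bal_m2ha / records$ba_m2ha
    (1 - params[["zc1"]] * exp(-params[["zc2"]] * m)) *
      exp(-params[["zc3"]] * m^params[["zc4"]]) *
      exp(-params[["br1"]] * baratio^params[["br2"]] *
            records$ba_m2ha^params[["br3"]])
  } else {
    lognormal_modifier(m, params[["z1"]], params[["z2"]]) *
      lognormal_modifier(records$ba_m2ha, params[["ba1"]], params[["ba2"]]) *
      lognormal_modifier(records$bal_m2ha + 1, params[["bl1"]], params[["bl2"]])
  }
  br <- params[["a"]] * comp *
    lognormal_modifier(records$temp_K, params[["t1"]], params[["t2"]]) *
    lognormal_modifier(records$precip_dm, params[["p1"]], params[["p2"]])
  if (spec$has_N) {
    br <- br * lognormal_modifier(floor_deposition(records$ndep_kgN_ha_yr),
                                  params[["n1"]], params[["n2"]])
  }
  br * s_term(records$sdep_kgS_ha_yr, params, spec$s_form)
}

#' Survival probability over a record's census interval
#'
#' The bracketed annual survival (baseline multiplier `a` times size,
#' competition, climate and deposition terms) raised to the census
#' interval `dt_yr` in years. [survival_prob_10yr()] reports the same
#' bracket on the conventional 10-year scale.
#'
#' @inheritParams growth_mean
#' @param spec Survival model spec.
#' @return Survival probability per record, in [0, 1] for feasible
#'   parameters. Values outside (0, 1] for the annual bracket are returned
#'   as-is so the fitter can reject the parameter vector.
#' @export
survival_prob <- function(records, spec, params) {
  stopifnot(inherits(spec, "forestcl_spec"), spec$endpoint == "survival")
  survival_bracket(records, spec, params)^records$dt_yr
}

#' @rdname survival_prob
#' @export
survival_prob_10yr <- function(records, spec, params) {
  survival_bracket(records, spec, params)^10
}

#' Log-likelihood of a candidate model
#'
#' Growth: Gaussian log-density of observed growth around [growth_mean()]
#' with constant residual SD `sigma` (a fitted parameter). Survival:
#' Bernoulli log-mass with p from [survival_prob()]. Parameter vectors
#' that put any survival probability outside (0, 1) get `-Inf` (a
#' rejection the annealer treats as an infeasible move), not an error.
#'
#' @inheritParams growth_mean
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(records, spec, params) {
  if (spec$endpoint == "growth") {
    sigma <- params[["sigma"]]
    if (!is.finite(sigma) || sigma <= 0) return(-Inf)
    mu <- growth_mean(records, spec, params)
    if (any(!is.finite(mu))) return(-Inf)
    sum(stats::dnorm(records$growth_kgC_yr, mean = mu, sd = sigma, log = TRUE))
  } else {
    p <- survival_prob(records, spec, params)
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1 & records$survived == 0) ||
        any(p > 1)) {
      return(-Inf)
    }
    sum(ifelse(records$survived == 1, log(p), log1p(-p)))
  }
}
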