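test_that("AIC and AICc follow their closed forms", {
  expect_equal(aic(-10, 3), 26)
  expect_equal(aicc(-10, 3, 100), 26.25)
  expect_equal(aicc(-10, 3, 1e9), aic(-10, 3), tolerance = 1e-6)
  expect_error(aicc(-10, 3, 4), "n")
})

test_that("N-S correlation matches the textbook formula", {
  rec <- random_records(20)
  rec$sdep_kgS_ha_yr <- 0.5 * rec$ndep_kgN_ha_yr
  expect_equal(ns_correlation(rec), 1.0)
  # hand-checked 5-point table against brute-force sums
  rec5 <- random_records(5)
  rec5$ndep_kgN_ha_yr <- c(2, 4, 6, 8, 10)
  rec5$sdep_kgS_ha_yr <- c(1, 3, 2, 7, 6)
  n <- rec5$ndep_kgN_ha_yr; s <- rec5$sdep_kgS_ha_yr
  r_hand <- (sum(n * s) - 5 * mean(n) * mean(s)) /
    sqrt((sum(n^2) - 5 * mean(n)^2) * (sum(s^2) - 5 * mean(s)^2))
  expect_equal(ns_correlation(rec5), r_hand, tolerance = 1e-12)
  # independence: |r| small at large n
  set.seed(5)
  big <- random_records(10000)
  expect_lt(abs(ns_correlation(big)), 0.1)
  # zero variance is an undefined-correlation signal
  rec$sdep_kgS_ha_yr <- 3
  expect_true(is.na(ns_correlation(rec)))
})

make_fake_fit <- function(label_spec, aic_value) {
  structure(list(spec = label_spec, params = c(a = 1),
                 logLik = -(aic_value - 2 * label_spec$k) / 2,
                 AIC = aic_value, n_obs = 1000, converged = TRUE, seed = 1L),
            class = "forestcl_fit")
}

growth_spec <- function(label) {
  specs <- enumerate_models("growth")
  labels <- vapply(specs, `[[`, character(1), "label")
  specs[[match(paste0("growth:", label), labels)]]
}

test_that("candidate selection prefers separate N and S terms within the window", {
  fits <- list(make_fake_fit(growth_spec("base+N"), 100.0),
               make_fake_fit(growth_spec("base+N+Ssigmoid"), 103.5),
               make_fake_fit(growth_spec("base"), 105.0))
  sel <- select_model(fits, ns_r = 0.2)
  expect_equal(sel$status, "selected")
  expect_equal(sel$selected_fit$spec$label, "growth:base+N+Ssigmoid")
  expect_length(sel$candidate_set, 2)   # base at +5 is outside delta 4
  # invariant to a constant shift of all AICs
  fits2 <- lapply(fits, function(f) { f$AIC <- f$AIC + 1000; f })
  sel2 <- select_model(fits2, ns_r = 0.2)
  expect_equal(sel2$selected_fit$spec$label, sel$selected_fit$spec$label)
})

test_that("collinear N and S with no joint candidate excludes the unit", {
  fits <- list(make_fake_fit(growth_spec("base+N"), 100.0),
               make_fake_fit(growth_spec("base+N+Ssigmoid"), 105.0))
  sel <- select_model(fits, ns_r = 0.9)
  expect_equal(sel$status, "excluded_ns_collinearity")
  # same candidates with low correlation select base+N
  sel_lo <- select_model(fits, ns_r = 0.2)
  expect_equal(sel_lo$status, "selected")
  expect_equal(sel_lo$selected_fit$spec$label, "growth:base+N")
  # a deposition-free candidate set is never excluded
  fits3 <- list(make_fake_fit(growth_spec("intercept"), 90.0))
  sel3 <- select_model(fits3, ns_r = 0.95)
  expect_equal(sel3$status, "selected")
  expect_true(sel3$selected_fit$spec$is_intercept_only)
  # NA correlation treated as below threshold
  sel_na <- select_model(fits, ns_r = NA_real_)
  expect_equal(sel_na$status, "selected")
  expect_equal(select_model(list(), ns_r = 0.1)$status, "insufficient_data")
})

test_that("intercept-only annealing recovers the Gaussian ML solution", {
  set.seed(21)
  rec <- random_records(800)
  rec$growth_kgC_yr <- rnorm(800, 3, 2)
  spec <- enumerate_models("growth")[[1]]
  fit <- fit_model(rec, spec, fit_config(iterations = 6000, restarts = 2,
                                         seed = 4))
  expect_equal(fit$params[["a"]], mean(rec$growth_kgC_yr), tolerance = 0.02)
  sigma_ml <- sqrt(mean((rec$growth_kgC_yr - mean(rec$growth_kgC_yr))^2))
  expect_equal(fit$params[["sigma"]], sigma_ml, tolerance = 0.02)
  expect_equal(fit$AIC, 2 * spec$k - 2 * fit$logLik, tolerance = 1e-9)
})

test_that("annealing is deterministic, bounded, and improves on its start", {
  set.seed(22)
  rec <- random_records(300)
  spec <- enumerate_models("growth")[[3]]   # base+N
  cfg <- fit_config(iterations = 2000, restarts = 2, seed = 9)
  f1 <- fit_model(rec, spec, cfg)
  f2 <- fit_model(rec, spec, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$logLik, f2$logLik)
  b <- default_bounds(spec, rec)
  for (nm in names(f1$params)) {
    expect_gte(f1$params[[nm]], b[[nm]][1])
    expect_lte(f1$params[[nm]], b[[nm]][2])
  }
  init <- forestcl:::init_params(spec, rec, b)
  expect_gte(f1$logLik, log_likelihood(rec, spec, init))
})

test_that("a strong N effect is detected and no-effect data stays clean", {
  # simulate from base (no deposition terms) and from base+N; check the
  # selected model across replicates
  grad <- division_gradients()[division_gradients()$division == "22", ]
  n_rep <- 6
  cfg <- fit_config(iterations = 4000, restarts = 2, min_trees = 100)
  spurious <- 0; detected <- 0
  for (r in seq_len(n_rep)) {
    base_tp <- list("SP1|22|growth" = list(has_N = FALSE, s_form = "none"),
                    "SP1|22|survival" = list(has_N = FALSE, s_form = "none"))
    sc0 <- scenario_config("SP1", "22", n_trees_per_unit = 700,
                           true_params = base_tp, seed = 100 + r)
    gen0 <- generate_trees(sc0)
    specs <- enumerate_models("growth")[c(1, 2, 3)]  # intercept, base, base+N
    fits0 <- lapply(seq_along(specs), function(i) {
      c2 <- cfg; c2$seed <- 100 * r + i
      fit_model(gen0$trees, specs[[i]], c2)
    })
    sel0 <- select_model(fits0, ns_correlation(gen0$trees), cfg)
    if (sel0$status == "selected" &&
        forestcl:::spec_has_any_NS(sel0$selected_fit$spec)) {
      spurious <- spurious + 1
    }
    sc1 <- scenario_config("SP1", "22", n_trees_per_unit = 700,
                           true_params = list(
                             "SP1|22|growth" = list(has_N = TRUE, s_form = "none"),
                             "SP1|22|survival" = list(has_N = TRUE, s_form = "none")),
                           seed = 200 + r)
    gen1 <- generate_trees(sc1)
    fits1 <- lapply(seq_along(specs), function(i) {
      c2 <- cfg; c2$seed <- 300 * r + i
      fit_model(gen1$trees, specs[[i]], c2)
    })
    sel1 <- select_model(fits1, ns_correlation(gen1$trees), cfg)
    if (sel1$status == "selected" && sel1$selected_fit$spec$has_N) {
      detected <- detected + 1
    }
  }
  expect_lte(spurious, 2)           # AIC's known overfitting tolerance
  expect_gte(detected, n_rep - 1)   # strong true effect almost always kept
})
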