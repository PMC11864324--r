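make_shape_rows <- function() {
  data.frame(species = c("A", "A", "B", "C"),
             division = c("21", "22", "21", "22"),
             endpoint = "growth", pollutant = "N",
             shape = c("increase", "unimodal_sigmoid", "flat",
                       "not_applicable"),
             stringsAsFactors = FALSE)
}

make_plot_cov <- function() {
  data.frame(species = rep(c("A", "A", "B", "C"), each = 3),
             division = rep(c("21", "22", "21", "22"), each = 3),
             plot_id = paste0("p", 1:12),
             MAT_C = rep(c(8, 12, 9, 14), each = 3) + rep(c(-1, 0, 1), 4),
             MAP_mm = rep(c(900, 1100, 950, 1200), each = 3),
             soil_pH = c(5, 6, 7, 6, 6, 6, 7, 7, 7, 5.5, 5.5, 5.5),
             ndep_kgN_ha_yr = rep(c(8, 10, 9, 12), each = 3),
             sdep_kgS_ha_yr = rep(c(5, 6, 4, 7), each = 3),
             stringsAsFactors = FALSE)
}

make_traits <- function() {
  data.frame(species = c("A", "C"),
             mycorrhiza = c("AM", "EcM"),
             leaf_habit = c("deciduous", "evergreen"),
             stringsAsFactors = FALSE)
}

test_that("the covariate table averages plots and drops unusable units", {
  # C's row is not_applicable (dropped silently); B has no trait entry
  expect_warning(
    tab <- build_covariate_table(make_shape_rows(), make_plot_cov(),
                                 make_traits()),
    "trait")
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$species, "A")
  # plot pH {5,6,7} averages to 6 for species A division 21
  expect_equal(tab$soil_pH[tab$species == "A" & tab$division == "21"], 6)
  expect_true(is.ordered(tab$shape))
  expect_equal(attr(tab, "n_dropped_na_shape"), 1)
  expect_equal(attr(tab, "n_dropped_no_trait"), 1)
})

test_that("the collinearity screen flags strict exceedances only", {
  set.seed(50)
  d <- data.frame(x = rnorm(100))
  d$dup <- d$x                       # r = 1
  d$y <- rnorm(100)                  # independent
  scr <- collinearity_screen(d, threshold = 0.7)
  expect_true(any(scr$flagged$var1 == "x" & scr$flagged$var2 == "dup"))
  expect_false(any(scr$flagged$var2 == "y" | scr$flagged$var1 == "y"))
  # boundary: |r| exactly at the threshold is not flagged
  d2 <- data.frame(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  r_ab <- cor(d2$a, d2$b)
  scr2 <- collinearity_screen(d2, threshold = r_ab)
  expect_equal(nrow(scr2$flagged), 0)
  # constant column is flagged as undefined
  d$const <- 1
  scr3 <- collinearity_screen(d)
  expect_true(any(is.na(scr3$flagged$r)))
})

test_that("Nagelkerke R2 matches its formula and is monotone", {
  expect_equal(nagelkerke_r2(-100, -100, 50), 0)
  # frozen from the closed form: (1-exp(-0.2)) / (1-exp(-2))
  expect_equal(nagelkerke_r2(-90, -100, 100), 0.2096411, tolerance = 1e-6)
  r <- vapply(seq(-99, -80, by = 2), nagelkerke_r2, numeric(1),
              logLik_null = -100, n = 100)
  expect_true(all(diff(r) > 0))
  expect_error(nagelkerke_r2(-90, -100, 0), "n")
})

test_that("an intercept-only ordinal fit reproduces sample proportions", {
  set.seed(60)
  gen <- generate_shape_dataset(400, beta = c(MAT = 0), seed = 8)
  fit <- fit_proportional_odds(gen$table, shape ~ 1)
  pr <- predict(fit$fit, newdata = gen$table[1, ], type = "probs")
  emp <- as.numeric(prop.table(table(gen$table$shape)))
  expect_equal(as.numeric(pr), emp, tolerance = 1e-4)
  expect_equal(fit$nagelkerke_r2, 0)
})

test_that("predicted category probabilities sum to one", {
  gen <- generate_shape_dataset(300, beta = c(Ndep = 0.2, MAT = -0.1),
                                seed = 9)
  fit <- fit_proportional_odds(gen$table, shape ~ Ndep + MAT)
  pr <- predict(fit$fit, type = "probs")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-12)
  expect_true(all(diff(fit$thresholds) > 0))
  expect_equal(fit$odds_ratios$odds_ratio,
               exp(fit$odds_ratios$beta), tolerance = 1e-12)
})

test_that("the two-category ordinal fit equals binary logistic regression", {
  set.seed(61)
  n <- 400
  x <- rnorm(n)
  p <- plogis(-0.3 + 0.8 * x)
  y <- rbinom(n, 1, p)
  tab <- data.frame(x = x,
                    shape = factor(ifelse(y == 1, "decrease", "flat"),
                                   levels = c("flat", "decrease"),
                                   ordered = TRUE))
  ofit <- fit_proportional_odds(tab, shape ~ x,
                                control = list(reltol = 1e-14))
  gfit <- glm(y ~ x, family = binomial,
              control = glm.control(epsilon = 1e-14))
  expect_equal(unname(ofit$coefficients["x"]), unname(coef(gfit)["x"]),
               tolerance = 1e-6)
  expect_equal(unname(ofit$thresholds[1]), -unname(coef(gfit)[1]),
               tolerance = 1e-6)
})

test_that("stepwise selection keeps a true effect and obeys its contract", {
  hits <- 0
  n_rep <- 8
  for (r in seq_len(n_rep)) {
    gen <- generate_shape_dataset(350, beta = c(MAP = 0.004),
                                  thresholds = c(-1.5, 0.5, 2.5),
                                  seed = 400 + r)
    fit <- stepwise_aic(gen$table)
    terms_kept <- attr(terms(fit$formula), "term.labels")
    # the true driver is retained and never dressed up in an interaction
    if ("MAP" %in% terms_kept && !any(grepl("MAP:|:MAP", terms_kept))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, ceiling(0.8 * n_rep))
  # the step trace is monotone non-increasing in AIC
  gen <- generate_shape_dataset(350, beta = c(MAP = 0.004), seed = 499)
  fit <- stepwise_aic(gen$table)
  expect_true(all(diff(fit$step_trace$AIC) <= 1e-8))
  # the scope lists exactly 6 interactions
  labs <- attr(terms(stage2_scope()), "term.labels")
  expect_equal(sum(grepl(":", labs)), 6)
  expect_equal(sum(!grepl(":", labs)), 7)
})

test_that("Fisher tests agree with enumeration oracles", {
  tab <- matrix(c(5, 0, 0, 5), 2, 2)
  expect_equal(fisher_exact_shapes(tab)$p_value, oracle_fisher_2x2(tab),
               tolerance = 1e-12)
  expect_equal(fisher_exact_shapes(tab)$p_value, 2 / 252, tolerance = 1e-12)
  # identical columns: no association
  tab_null <- matrix(c(4, 4, 4, 4), 2, 2)
  expect_equal(fisher_exact_shapes(tab_null)$p_value, 1)
  # R x C Monte Carlo within 0.01 of exhaustive enumeration at tiny n
  tab3 <- matrix(c(3, 1, 0, 1, 2, 1, 0, 1, 3), 3, 3, byrow = TRUE)
  p_exact <- oracle_fisher_rxc(tab3)
  p_mc <- fisher_exact_shapes(tab3, B = 40000, seed = 3)$p_value
  expect_lt(abs(p_mc - p_exact), 0.01)
  # reproducible under a fixed seed, converging as B doubles
  expect_identical(fisher_exact_shapes(tab3, B = 5000, seed = 11)$p_value,
                   fisher_exact_shapes(tab3, B = 5000, seed = 11)$p_value)
  p_b <- fisher_exact_shapes(tab3, B = 80000, seed = 12)$p_value
  expect_lt(abs(p_b - p_exact), 0.005)
  expect_error(fisher_exact_shapes(matrix(0, 2, 2)), "empty")
})

test_that("one-way ANOVA and Tukey HSD match classical identities", {
  set.seed(70)
  # identical group means: F near zero, all pairwise p near 1
  v0 <- c(rnorm(20, 5, 1), rnorm(20, 5, 1), rnorm(20, 5, 1))
  g0 <- rep(c("a", "b", "c"), each = 20)
  # two groups: F = t^2
  v2 <- c(rnorm(15, 0), rnorm(15, 1)); g2 <- rep(c("x", "y"), each = 15)
  res2 <- anova_tukey(v2, g2)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  # three-group F against the sums-of-squares oracle
  v3 <- c(rnorm(10, 0), rnorm(10, 0.5), rnorm(10, 2))
  g3 <- rep(c("a", "b", "c"), each = 10)
  res3 <- anova_tukey(v3, g3)
  expect_equal(res3$F, oracle_anova_F(v3, g3), tolerance = 1e-10)
  expect_equal(res3$df, c(2, 27))
  expect_equal(nrow(res3$tukey), 3)
  expect_error(anova_tukey(v3, rep("a", 30)), "groups")
})

test_that("Blomberg's K is exactly 1 on a star phylogeny", {
  n <- 12
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:n, ":1", collapse = ","), ");"))
  set.seed(80)
  trait <- setNames(rnorm(n), paste0("t", 1:n))
  res <- blomberg_k(star, trait, n_perm = 0)
  expect_equal(res$K, 1, tolerance = 1e-12)
})

test_that("Brownian traits give K near 1 and shuffling destroys signal", {
  set.seed(81)
  k_bm <- k_sh <- numeric(12)
  for (i in 1:12) {
    bm <- generate_phylogeny(40, "brownian", seed = 800 + i)
    sh <- generate_phylogeny(40, "shuffled", seed = 800 + i)
    k_bm[i] <- blomberg_k(bm$tree, bm$trait, n_perm = 0)$K
    k_sh[i] <- blomberg_k(sh$tree, sh$trait, n_perm = 0)$K
  }
  expect_gt(mean(k_bm), 0.7)
  expect_lt(median(k_sh), median(k_bm))
  # permutation p: signal detected for Brownian, not after shuffling
  bm <- generate_phylogeny(40, "brownian", seed = 900)
  expect_lt(blomberg_k(bm$tree, bm$trait, n_perm = 199, seed = 1)$p_value,
            0.05)
})

test_that("Blomberg's K matches the independent phytools implementation", {
  skip_if_not_installed("phytools")
  gen <- generate_phylogeny(30, "brownian", seed = 77)
  ours <- blomberg_k(gen$tree, gen$trait, n_perm = 0)$K
  theirs <- unname(phytools::phylosig(gen$tree, gen$trait, method = "K"))
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-8)
})
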