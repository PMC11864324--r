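## Stage 2: ordinal vulnerability of response shapes against climate,
## soil, deposition and trait covariates, plus the supporting tests
## (collinearity screen, Fisher exact, ANOVA/Tukey, Blomberg's K).

#' Build the species x Division covariate table for the ordinal models
#'
#' One row per species x Division x endpoint x pollutant: the unit's
#' response shape joined with Division-level species means of the
#' long-term covariates (MAT degC, MAP mm, soil pH, N and S deposition,
#' averaged over the plots where the species occurs) and the species'
#' traits. Units with `not_applicable` shapes and species missing from
#' the trait table are dropped, with counts reported as attributes.
#'
#' @param shapes Data frame with columns species, division, endpoint,
#'   pollutant, shape.
#' @param plot_covariates Data frame with columns species, division,
#'   plot_id, MAT_C, MAP_mm, soil_pH, ndep_kgN_ha_yr, sdep_kgS_ha_yr.
#' @param traits Data frame with columns species, mycorrhiza
#'   (`"AM"`/`"EcM"`), leaf_habit (`"deciduous"`/`"evergreen"`).
#' @return Data frame of covariate rows with an ordered `shape` factor;
#'   attributes `n_dropped_na_shape` and `n_dropped_no_trait` count the
#'   exclusions.
#' @export
build_covariate_table <- function(shapes, plot_covariates, traits) {
  keep <- shapes$shape != "not_applicable"
  n_na <- sum(!keep)
  shapes <- shapes[keep, , drop = FALSE]
  has_trait <- shapes$species %in% traits$species
  n_notrait <- sum(!has_trait)
  if (n_notrait > 0) {
    warning(n_notrait, " unit(s) dropped: species missing from trait table (",
            paste(unique(shapes$species[!has_trait]), collapse = ", "), ")")
  }
  shapes <- shapes[has_trait, , drop = FALSE]
  agg <- stats::aggregate(
    plot_covariates[c("MAT_C", "MAP_mm", "soil_pH",
                      "ndep_kgN_ha_yr", "sdep_kgS_ha_yr")],
    by = plot_covariates[c("species", "division")], FUN = mean)
  names(agg) <- c("species", "division", "MAT", "MAP", "soil_pH",
                  "Ndep", "Sdep")
  out <- merge(shapes, agg, by = c("species", "division"), all.x = FALSE)
  out <- merge(out, traits[c("species", "mycorrhiza", "leaf_habit")],
               by = "species")
  out$shape <- shape_factor(out$shape)
  out$myco <- factor(out$mycorrhiza, levels = c("AM", "EcM"))
  out$leaf_habit <- factor(out$leaf_habit,
                           levels = c("deciduous", "evergreen"))
  out$mycorrhiza <- NULL
  out <- out[order(out$endpoint, out$pollutant, out$species, out$division), ]
  rownames(out) <- NULL
  attr(out, "n_dropped_na_shape") <- n_na
  attr(out, "n_dropped_no_trait") <- n_notrait
  out
}

#' Pairwise collinearity screen of the stage-2 predictors
#'
#' Pearson correlations among the continuous predictors; pairs with
#' `|r|` strictly above the threshold are flagged but never removed
#' (covariates are retained under the hypothesis-driven framework).
#' Constant columns yield `NA` and are flagged as undefined.
#'
#' @param table Covariate table from [build_covariate_table()] (or any
#'   data frame; non-numeric columns are ignored).
#' @param threshold Flagging threshold on `|r|` (default 0.7).
#' @return List with the correlation `matrix` and a data frame of
#'   `flagged` pairs (var1, var2, r).
#' @export
collinearity_screen <- function(table, threshold = 0.7) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("collinearity_screen needs at least 3 rows")
  cm <- suppressWarnings(stats::cor(num))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[idx]
  flag <- is.na(r) | abs(r) > threshold
  flagged <- data.frame(var1 = rownames(cm)[idx[flag, 1]],
                        var2 = colnames(cm)[idx[flag, 2]],
                        r = r[flag], stringsAsFactors = FALSE)
  list(matrix = cm, flagged = flagged, threshold = threshold)
}

#' Nagelkerke's pseudo R-squared
#'
#' Normalized likelihood-ratio R-squared,
#' \deqn{R^2 = \frac{1 - \exp\{2(L_0 - L_1)/n\}}{1 - \exp\{2 L_0 / n\}},}
#' with `L0`/`L1` the null and fitted log-likelihoods.
#'
#' @param logLik_fit,logLik_null Fitted and intercept-only
#'   log-likelihoods.
#' @param n Number of observations.
#' @return Scalar in [0, 1].
#' @export
nagelkerke_r2 <- function(logLik_fit, logLik_null, n) {
  if (n < 1) stop("nagelkerke_r2: n must be >= 1")
  (1 - exp(2 * (logLik_null - logLik_fit) / n)) /
    (1 - exp(2 * logLik_null / n))
}

#' Proportional-odds ordinal regression of response vulnerability
#'
#' Fits the cumulative-logit model P(Y <= j) = logistic(alpha_j - x'beta)
#' by maximum likelihood (via `MASS::polr`) and augments it with AICc,
#' Nagelkerke R-squared against the intercept-only fit, and per-predictor
#' odds ratios with 95% Wald confidence intervals.
#'
#' @param table Covariate table with an ordered `shape` outcome.
#' @param formula Model formula with `shape` on the left-hand side.
#' @param ... Passed on to `MASS::polr` (hence to `optim`), e.g.
#'   `control = list(reltol = 1e-12)`.
#' @return A `forestcl_ordinal` list: the underlying `polr` fit,
#'   `coefficients`, `thresholds`, `logLik`, `AIC`, `AICc`,
#'   `nagelkerke_r2`, `odds_ratios` (with `lo`/`hi` CI columns), `n`.
#' @export
fit_proportional_odds <- function(table, formula = shape ~ 1, ...) {
  table <- droplevels(table[!is.na(table$shape), , drop = FALSE])
  if (nlevels(table$shape) < 2) {
    stop("fit_proportional_odds: fewer than 2 outcome categories realized")
  }
  po_fit <- function(fm) {
    if (nlevels(table$shape) == 2L) {
      polr2(fm, table, ...)   # two realized categories: own ML path
    } else {
      MASS::polr(fm, data = table, Hess = TRUE, ...)
    }
  }
  fit <- po_fit(formula)
  null_fit <- if (length(attr(stats::terms(formula), "term.labels")) == 0) {
    fit
  } else {
    po_fit(shape ~ 1)
  }
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  k <- attr(stats::logLik(fit), "df")
  n <- fit$n
  beta <- fit$coefficients
  or <- NULL
  if (length(beta)) {
    se <- sqrt(diag(stats::vcov(fit)))[names(beta)]
    or <- data.frame(term = names(beta), beta = unname(beta),
                     se = unname(se),
                     odds_ratio = exp(unname(beta)),
                     lo = exp(unname(beta) - 1.96 * unname(se)),
                     hi = exp(unname(beta) + 1.96 * unname(se)),
                     stringsAsFactors = FALSE)
  }
  structure(list(fit = fit, coefficients = beta, thresholds = fit$zeta,
                 logLik = ll, AIC = aic(ll, k), AICc = aicc(ll, k, n),
                 nagelkerke_r2 = nagelkerke_r2(ll, ll0, n),
                 odds_ratios = or, n = n, formula = formula),
            class = "forestcl_ordinal")
}

#' @export
print.forestcl_ordinal <- function(x, ...) {
  cat("<proportional-odds fit> n =", x$n,
      " AICc =", format(x$AICc, digits = 6),
      " Nagelkerke R2 =", format(x$nagelkerke_r2, digits = 3), "\n")
  if (!is.null(x$odds_ratios)) {
    print(x$odds_ratios[c("term", "odds_ratio", "lo", "hi")], digits = 3)
  }
  invisible(x)
}

# Proportional-odds fit for a two-category outcome, where the
# cumulative-logit model reduces to binary logistic regression.
# MASS::polr requires three or more levels, so this case is fitted by
# direct ML on the same likelihood.
polr2 <- function(formula, data, control = list(reltol = 1e-12)) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  yi <- as.integer(y)
  nb <- ncol(X)
  nll <- function(par) {
    eta <- if (nb) drop(X %*% par[seq_len(nb)]) else 0
    p1 <- stats::plogis(par[nb + 1L] - eta)
    -sum(ifelse(yi == 1L, log(p1), log1p(-p1)))
  }
  start <- c(rep(0, nb), stats::qlogis(max(min(mean(yi == 1L), 0.99), 0.01)))
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = control)
  beta <- stats::setNames(opt$par[seq_len(nb)], colnames(X))
  zeta <- stats::setNames(opt$par[nb + 1L],
                          paste(levels(y)[1], levels(y)[2], sep = "|"))
  structure(list(coefficients = beta, zeta = zeta,
                 logLik = -opt$value, df = nb + 1L,
                 vcov = solve(opt$hessian), n = length(yi),
                 lev = levels(y), formula = formula),
            class = "forestcl_polr2")
}

#' @export
logLik.forestcl_polr2 <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' @export
vcov.forestcl_polr2 <- function(object, ...) {
  v <- object$vcov
  dimnames(v) <- list(c(names(object$coefficients), names(object$zeta)),
                      c(names(object$coefficients), names(object$zeta)))
  v
}

#' @export
predict.forestcl_polr2 <- function(object, newdata, type = "probs", ...) {
  X <- stats::model.matrix(stats::delete.response(
    stats::terms(object$formula)), newdata)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  eta <- if (length(object$coefficients))
    drop(X %*% object$coefficients) else rep(0, nrow(X))
  p1 <- stats::plogis(object$zeta - eta)
  pr <- cbind(p1, 1 - p1)
  colnames(pr) <- object$lev
  if (type == "probs") pr else object$lev[max.col(pr)]
}

#' The hypothesis-driven stage-2 model scope
#'
#' Seven main effects (MAT, MAP, soil pH, N and S deposition, mycorrhizal
#' association, leaf habit) and six first-order interactions:
#' MAT x MAP, MAT x Ndep, soil_pH x Sdep, Ndep x Sdep, Ndep x myco,
#' soil_pH x myco.
#' @return A formula with `shape` as outcome.
#' @export
stage2_scope <- function() {
  shape ~ MAT + MAP + soil_pH + Ndep + Sdep + myco + leaf_habit +
    MAT:MAP + MAT:Ndep + soil_pH:Sdep + Ndep:Sdep + Ndep:myco +
    soil_pH:myco
}

#' Stepwise AIC selection of the ordinal vulnerability model
#'
#' Starts from the full hypothesis-driven scope ([stage2_scope()]) and
#' performs bidirectional stepwise selection minimizing AIC (via
#' `MASS::stepAIC`), which respects marginality (an interaction is only
#' retained with its main effects). The selected model is refitted
#' through [fit_proportional_odds()] so AICc, Nagelkerke R-squared and
#' odds ratios are reported for it.
#'
#' @param table Covariate table for one endpoint x pollutant.
#' @param scope Full-model formula (default [stage2_scope()]).
#' @return A `forestcl_ordinal` with an extra `step_trace` data frame
#'   (the AIC path).
#' @export
stepwise_aic <- function(table, scope = stage2_scope()) {
  .step_data <- droplevels(table[!is.na(table$shape), , drop = FALSE])
  # stepAIC refits in the formula's environment; give the scope one that
  # carries the data
  environment(scope) <- environment()
  full <- MASS::polr(scope, data = .step_data, Hess = TRUE)
  stepped <- MASS::stepAIC(full, direction = "both", trace = 0)
  out <- fit_proportional_odds(.step_data, stats::formula(stepped))
  out$step_trace <- stepped$anova
  out
}

#' Fisher's exact test on a shape x Division contingency table
#'
#' 2 x 2 tables use the exact two-sided hypergeometric test (summing the
#' probabilities of tables no more likely than the observed one); larger
#' tables use a margin-preserving Monte-Carlo estimate
#' p = (1 + #[prob(sim) <= prob(obs)]) / (B + 1).
#'
#' @param contingency Matrix/table of non-negative integer counts.
#' @param B Monte-Carlo draws for tables larger than 2 x 2.
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return List with `p_value` and `method`.
#' @export
fisher_exact_shapes <- function(contingency, B = 10000L, seed = 1L) {
  contingency <- as.matrix(contingency)
  if (!length(contingency) || sum(contingency) == 0) {
    stop("fisher_exact_shapes: empty contingency table")
  }
  if (all(dim(contingency) == c(2L, 2L))) {
    res <- stats::fisher.test(contingency)
    return(list(p_value = res$p.value, method = "exact"))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  res <- stats::fisher.test(contingency, simulate.p.value = TRUE,
                            B = as.integer(B))
  list(p_value = res$p.value, method = "monte_carlo", B = as.integer(B))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Tests whether a Division-level covariate differs among groups, with
#' studentized-range pairwise comparisons.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (e.g. Division), at least 2 levels with
#'   at least 2 values each.
#' @return List with `F`, `df`, `p_value`, and the `tukey` data frame of
#'   pairwise differences and adjusted p-values.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("anova_tukey needs at least 2 groups")
  if (any(table(groups) < 2)) stop("anova_tukey needs >= 2 values per group")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = s[["F value"]][1], df = c(s[["Df"]][1], s[["Df"]][2]),
       p_value = s[["Pr(>F)"]][1],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Blomberg's K phylogenetic-signal statistic
#'
#' K compares the observed ratio of the trait's variance about the
#' phylogenetic (GLS) mean to its phylogenetically corrected variance
#' against the ratio expected under Brownian motion on the given tree:
#' K near 1 indicates Brownian-like signal, near 0 no signal. The
#' p-value is a tip-permutation test on the corrected mean squared error
#' (smaller MSE than permuted data indicates signal).
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param trait Named numeric vector; names must match the tip labels.
#' @param n_perm Number of tip permutations (0 skips the test).
#' @param seed Integer seed for the permutations.
#' @return List with `K`, `p_value` (NA when `n_perm = 0`), `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(trait)) || !all(tree$tip.label %in% names(trait))) {
    stop("blomberg_k: trait must be named by the tree's tip labels")
  }
  x <- trait[tree$tip.label]
  V <- ape::vcv(tree)
  n <- length(x)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("blomberg_k: singular phylogenetic covariance; ",
         "check for zero-length branches"))
  one <- rep(1, n)
  k_expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  mse_ratio <- function(x) {
    ahat <- sum(Vi %*% x) / sum(Vi)
    d <- x - ahat
    mse0 <- sum(d * d) / (n - 1)
    mse <- drop(t(d) %*% Vi %*% d) / (n - 1)
    c(ratio = mse0 / mse, mse = mse)
  }
  obs <- mse_ratio(x)
  K <- unname(obs["ratio"]) / k_expected
  p <- NA_real_
  if (n_perm > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      mp <- mse_ratio(sample(x))
      if (mp["mse"] <= obs["mse"]) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  list(K = K, p_value = p, n_perm = as.integer(n_perm))
}
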