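# Independent oracles used across the suite. These re-derive expected
# values by brute force or closed form, separately from the package code
# paths they check.

# One-record tree data frame with controllable covariates.
one_record <- function(size = 100, growth = 1, survived = 1L, dt = 10,
                       ba = 1, bal = 0, temp = 285, precip = 10,
                       ndep = 8, sdep = 5) {
  data.frame(tree_id = "t1", species = "SP", division = "21",
             plot_id = "p1", size_kgC = size, growth_kgC_yr = growth,
             survived = survived, dt_yr = dt, ba_m2ha = ba, bal_m2ha = bal,
             temp_K = temp, precip_dm = precip, ndep_kgN_ha_yr = ndep,
             sdep_kgS_ha_yr = sdep, stringsAsFactors = FALSE)
}

# Term-by-term product oracle for the growth mean, computed factor by
# factor with scalar arithmetic (no vectorized package path).
oracle_growth_mean <- function(rec, spec, p) {
  out <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (spec$is_intercept_only) { out[i] <- p[["a"]]; next }
    ln_mod <- function(x, c1, c2) exp(-0.5 * (log(x / c1) / c2)^2)
    v <- p[["a"]] * rec$size_kgC[i]^p[["z"]] *
      exp(p[["a2"]] * rec$bal_m2ha[i] + p[["a3"]] * log(rec$ba_m2ha[i])) *
      ln_mod(rec$temp_K[i], p[["t1"]], p[["t2"]]) *
      ln_mod(rec$precip_dm[i], p[["p1"]], p[["p2"]])
    if (spec$has_N) {
      v <- v * ln_mod(max(rec$ndep_kgN_ha_yr[i], 0.01), p[["n1"]], p[["n2"]])
    }
    S <- rec$sdep_kgS_ha_yr[i]
    if (spec$s_form == "sigmoid") {
      v <- v * (p[["s3"]] + (1 - p[["s3"]]) / (1 + (S / p[["s1"]])^p[["s2"]]))
    } else if (spec$s_form == "lognormal") {
      v <- v * ln_mod(max(S, 0.01), p[["s1"]], p[["s2"]])
    }
    out[i] <- v
  }
  out
}

# Same for the survival bracket (form A or B), raised to dt.
oracle_survival_prob <- function(rec, spec, p) {
  out <- numeric(nrow(rec))
  ln_mod <- function(x, c1, c2) exp(-0.5 * (log(x / c1) / c2)^2)
  for (i in seq_len(nrow(rec))) {
    if (spec$is_intercept_only) {
      out[i] <- p[["a"]]^rec$dt_yr[i]; next
    }
    m <- rec$size_kgC[i]
    comp <- if (spec$competition_form == "A") {
      (1 - p[["zc1"]] * exp(-p[["zc2"]] * m)) *
        exp(-p[["zc3"]] * m^p[["zc4"]]) *
        exp(-p[["br1"]] * (rec$bal_m2ha[i] / rec$ba_m2ha[i])^p[["br2"]] *
              rec$ba_m2ha[i]^p[["br3"]])
    } else {
      ln_mod(m, p[["z1"]], p[["z2"]]) *
        ln_mod(rec$ba_m2ha[i], p[["ba1"]], p[["ba2"]]) *
        ln_mod(rec$bal_m2ha[i] + 1, p[["bl1"]], p[["bl2"]])
    }
    v <- p[["a"]] * comp * ln_mod(rec$temp_K[i], p[["t1"]], p[["t2"]]) *
      ln_mod(rec$precip_dm[i], p[["p1"]], p[["p2"]])
    if (spec$has_N) {
      v <- v * ln_mod(max(rec$ndep_kgN_ha_yr[i], 0.01), p[["n1"]], p[["n2"]])
    }
    S <- rec$sdep_kgS_ha_yr[i]
    if (spec$s_form == "sigmoid") {
      v <- v * (p[["s3"]] + (1 - p[["s3"]]) / (1 + (S / p[["s1"]])^p[["s2"]]))
    } else if (spec$s_form == "lognormal") {
      v <- v * ln_mod(max(S, 0.01), p[["s1"]], p[["s2"]])
    }
    out[i] <- v^rec$dt_yr[i]
  }
  out
}

# Random valid parameter vector for a spec, anchored to a record set.
random_params <- function(spec, rec) {
  p <- c(a = if (spec$endpoint == "growth") runif(1, 0.5, 5) else
           runif(1, 0.9, 0.999))
  add <- function(p, nm, v) { p[nm] <- v; p }
  if (!spec$is_intercept_only) {
    if (spec$endpoint == "growth") {
      p <- add(p, "z", runif(1, 0, 1))
      p <- add(p, "a2", runif(1, -0.05, 0))
      p <- add(p, "a3", runif(1, -0.5, 0.5))
    } else if (spec$competition_form == "A") {
      p <- add(p, "zc1", runif(1, 0, 0.9)); p <- add(p, "zc2", runif(1, 0, 1))
      p <- add(p, "zc3", runif(1, 0, 0.01)); p <- add(p, "zc4", runif(1, 0.2, 1.5))
      p <- add(p, "br1", runif(1, 0, 0.5)); p <- add(p, "br2", runif(1, 0.2, 2))
      p <- add(p, "br3", runif(1, 0, 0.5))
    } else {
      p <- add(p, "z1", runif(1, 20, 200)); p <- add(p, "z2", runif(1, 1, 8))
      p <- add(p, "ba1", runif(1, 10, 40)); p <- add(p, "ba2", runif(1, 1, 8))
      p <- add(p, "bl1", runif(1, 2, 30)); p <- add(p, "bl2", runif(1, 1, 8))
    }
    p <- add(p, "t1", runif(1, 270, 300)); p <- add(p, "t2", runif(1, 1, 8))
    p <- add(p, "p1", runif(1, 3, 18)); p <- add(p, "p2", runif(1, 1, 8))
    if (spec$has_N) {
      p <- add(p, "n1", runif(1, 2, 20)); p <- add(p, "n2", runif(1, 0.5, 4))
    }
    if (spec$s_form == "sigmoid") {
      p <- add(p, "s1", runif(1, 1, 12)); p <- add(p, "s2", runif(1, 0.5, 5))
      p <- add(p, "s3", runif(1, 0, 0.9))
    } else if (spec$s_form == "lognormal") {
      p <- add(p, "s1", runif(1, 0.1, min(rec$sdep_kgS_ha_yr)))
      p <- add(p, "s2", runif(1, 0.5, 5))
    }
  }
  if (spec$endpoint == "growth") p <- add(p, "sigma", runif(1, 0.5, 3))
  p
}

random_records <- function(n) {
  ba <- runif(n, 5, 60)
  data.frame(tree_id = paste0("t", seq_len(n)), species = "SP",
             division = "21", plot_id = "p1",
             size_kgC = rlnorm(n, log(60), 1),
             growth_kgC_yr = rnorm(n, 1, 2),
             survived = rbinom(n, 1, 0.9),
             dt_yr = runif(n, 5, 10), ba_m2ha = ba,
             bal_m2ha = runif(n) * ba, temp_K = runif(n, 275, 295),
             precip_dm = runif(n, 4, 16), ndep_kgN_ha_yr = runif(n, 2, 18),
             sdep_kgS_ha_yr = runif(n, 0.5, 10), stringsAsFactors = FALSE)
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive enumeration of all R x C tables with the observed margins;
# two-sided p by probability ordering under the multivariate
# hypergeometric null.
oracle_fisher_rxc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  n <- sum(tab)
  log_prob <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(m))
  }
  R <- length(rs); C <- length(cs)
  p_obs <- log_prob(tab)
  total <- 0
  rec <- function(row, col_rem, acc) {
    if (row == R) {
      m <- rbind(acc, col_rem)
      if (all(col_rem >= 0)) {
        lp <- log_prob(m)
        if (lp <= p_obs + 1e-7) total <<- total + exp(lp)
      }
      return(invisible())
    }
    cells <- vector("list", C)
    fill_row <- function(j, left, this_row) {
      if (j == C) {
        if (left <= col_rem[C]) {
          rec(row + 1, col_rem - c(this_row, left),
              rbind(acc, c(this_row, left)))
        }
        return(invisible())
      }
      for (v in 0:min(left, col_rem[j])) {
        fill_row(j + 1, left - v, c(this_row, v))
      }
    }
    fill_row(1, rs[row], integer(0))
    invisible()
  }
  rec_acc <- matrix(numeric(0), nrow = 0, ncol = C)
  rec(1, cs, rec_acc)
  total
}

# Closed-form sums-of-squares one-way ANOVA oracle.
oracle_anova_F <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - gm)^2))
  ss_within <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2)))
  k <- nlevels(groups); n <- length(values)
  (ss_between / (k - 1)) / (ss_within / (n - k))
}
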