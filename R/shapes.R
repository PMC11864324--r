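## Response-shape classification on the ordered vulnerability scale and
## critical-load computation (direct and by sigmoid inversion).

#' Ordered vulnerability levels of a deposition response shape
#'
#' Least to most vulnerable: a curve increasing over the unit's observed
#' deposition range, a flat (no-response) curve, a unimodal (N) or
#' sigmoid (S) curve where part of the population responds negatively,
#' and a curve decreasing over the whole range.
#' @return Character vector of the four ordered levels.
#' @export
shape_levels <- function() c("increase", "flat", "unimodal_sigmoid", "decrease")

#' @rdname shape_levels
#' @param x Character vector of shape labels (may include
#'   `"not_applicable"`, which becomes `NA`).
#' @return `shape_factor()`: an ordered factor on the vulnerability scale.
#' @export
shape_factor <- function(x) {
  x[x == "not_applicable"] <- NA
  factor(x, levels = shape_levels(), ordered = TRUE)
}

#' Classify the nitrogen response shape of a selected fit
#'
#' The fitted N modifier peaks at `n1`. Over the unit's observed N range
#' the realized curve is monotone increasing when the peak lies at or
#' beyond the maximum, monotone decreasing when it lies at or below the
#' minimum, and unimodal when the peak is interior. Models without an N
#' term are flat; excluded units are `not_applicable`.
#'
#' @param selected A `forestcl_selection`.
#' @param n_range Numeric `c(min, max)` of observed N deposition,
#'   kg N ha-1 yr-1.
#' @return Shape label (see [shape_levels()]).
#' @export
classify_n_shape <- function(selected, n_range) {
  if (selected$status != "selected") return("not_applicable")
  if (n_range[1] >= n_range[2]) {
    stop("classify_n_shape: degenerate N range [", n_range[1], ", ",
         n_range[2], "]")
  }
  spec <- selected$selected_fit$spec
  if (!spec$has_N) return("flat")
  n1 <- selected$selected_fit$params[["n1"]]
  if (n1 >= n_range[2]) "increase"
  else if (n1 <= n_range[1]) "decrease"
  else "unimodal_sigmoid"
}

#' Classify the sulfur response shape of a selected fit
#'
#' Sulfur is constrained to non-positive responses: no S term is flat,
#' the lognormal form (decreasing limb only) is decreasing, and the
#' sigmoid form is sigmoid.
#'
#' @inheritParams classify_n_shape
#' @return Shape label (see [shape_levels()]).
#' @export
classify_s_shape <- function(selected) {
  if (selected$status != "selected") return("not_applicable")
  switch(selected$selected_fit$spec$s_form,
         none = "flat",
         lognormal = "decrease",
         sigmoid = "unimodal_sigmoid")
}

#' Critical load read directly from a fitted location parameter
#'
#' For N the critical load is the fitted `n1` (the deposition above which
#' the modifier, hence growth or survival, begins to decline); for the
#' lognormal S form it is `s1`.
#'
#' @param params Named parameter vector of the selected fit.
#' @param pollutant `"N"` or `"S"`.
#' @param s_form The selected spec's S form (needed for `pollutant = "S"`).
#' @return A `forestcl_cl` list: `pollutant`, `value` (kg ha-1 yr-1 or
#'   `NA` with a `status` explaining why), `basis`.
#' @export
critical_load_direct <- function(params, pollutant = c("N", "S"),
                                 s_form = "none") {
  pollutant <- match.arg(pollutant)
  cl <- function(value, basis, status = "defined") {
    structure(list(pollutant = pollutant, value = value, f = NA_real_,
                   basis = basis, status = status), class = "forestcl_cl")
  }
  if (pollutant == "N") {
    if (!"n1" %in% names(params)) {
      return(cl(NA_real_, "n1", "undefined: no N term in selected model"))
    }
    return(cl(params[["n1"]], "n1"))
  }
  if (s_form != "lognormal" || !"s1" %in% names(params)) {
    return(cl(NA_real_, "s1_lognormal",
              "undefined: no lognormal S term in selected model"))
  }
  cl(params[["s1"]], "s1_lognormal")
}

#' Critical load by inversion of the sigmoid sulfur term
#'
#' Setting the sigmoid S multiplier equal to `1 - f` (a fractional
#' reduction `f` in growth or survival) and solving for deposition gives
#' \deqn{CL = s_1 \left(\frac{f}{1 - f - s_3}\right)^{1/s_2}.}
#' Conventional choices of `f` are 0.05 for growth and 0.01 for survival.
#' When `f >= 1 - s3` the fitted curve never declines that far and the
#' critical load is reported as undefined rather than clipped.
#'
#' @param s1,s2,s3 Sigmoid parameters (see [sulfur_sigmoid()]).
#' @param f Fractional reduction defining the critical load, in
#'   (0, 1 - s3).
#' @return A `forestcl_cl` with basis `"sigmoid_inversion"`.
#' @export
critical_load_sigmoid <- function(s1, s2, s3, f) {
  stopifnot(s1 > 0, s2 > 0, s3 >= 0, s3 < 1, f > 0, f < 1)
  if (f >= 1 - s3) {
    return(structure(list(pollutant = "S", value = NA_real_, f = f,
                          basis = "sigmoid_inversion",
                          status = paste0("undefined: plateau s3 = ", s3,
                                          " never reaches reduction f = ", f)),
                     class = "forestcl_cl"))
  }
  value <- s1 * (f / (1 - f - s3))^(1 / s2)
  structure(list(pollutant = "S", value = value, f = f,
                 basis = "sigmoid_inversion", status = "defined"),
            class = "forestcl_cl")
}

#' @export
print.forestcl_cl <- function(x, ...) {
  cat("<critical load>", x$pollutant, "basis:", x$basis,
      if (is.na(x$value)) x$status else
        paste0(format(x$value, digits = 4), " kg ha-1 yr-1"), "\n")
  invisible(x)
}

#' Critical loads for one selected unit
#'
#' Applies [critical_load_direct()] for N (and lognormal S) and
#' [critical_load_sigmoid()] for sigmoid S fits, using the endpoint's
#' reduction fraction.
#'
#' @param selected A `forestcl_selection` with status `"selected"`.
#' @param f_growth,f_survival Reduction fractions for the sigmoid S
#'   inversion by endpoint.
#' @return List with elements `N` and `S`, each a `forestcl_cl`.
#' @export
unit_critical_loads <- function(selected, f_growth = 0.05, f_survival = 0.01) {
  stopifnot(selected$status == "selected")
  fit <- selected$selected_fit
  f <- if (selected$endpoint == "growth") f_growth else f_survival
  n_cl <- critical_load_direct(fit$params, "N")
  s_cl <- if (fit$spec$s_form == "sigmoid") {
    critical_load_sigmoid(fit$params[["s1"]], fit$params[["s2"]],
                          fit$params[["s3"]], f)
  } else {
    critical_load_direct(fit$params, "S", s_form = fit$spec$s_form)
  }
  list(N = n_cl, S = s_cl)
}
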