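#' Two-term lognormal modifier
#'
#' Unimodal multiplier used for the temperature, precipitation and nitrogen
#' terms of the growth and survival models (and for the lognormal sulfur
#' form). It peaks at 1 when `x == c1` and falls off symmetrically in
#' log space with width `c2`:
#' \deqn{\exp\{-\tfrac{1}{2}[\ln(x/c_1)/c_2]^2\}}
#'
#' @param x Positive covariate value(s) (e.g. temperature in K, N deposition
#'   in kg N ha-1 yr-1).
#' @param c1 Location of the peak, same units as `x`; must be > 0.
#' @param c2 Log-scale width (dimensionless); must be > 0.
#' @return Numeric vector in (0, 1], same length as `x`.
#' @examples
#' lognormal_modifier(300, 300, 2)              # 1 at the peak
#' lognormal_modifier(5 * exp(1), 5, 1)         # one ln-width out: exp(-0.5)
#' @export
lognormal_modifier <- function(x, c1, c2) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("lognormal_modifier: 'x' must be positive and finite")
  }
  if (!is.finite(c1) || c1 <= 0) stop("lognormal_modifier: 'c1' must be > 0")
  if (!is.finite(c2) || c2 <= 0) stop("lognormal_modifier: 'c2' must be > 0")
  exp(-0.5 * (log(x / c1) / c2)^2)
}

#' Sigmoid sulfur-deposition term
#'
#' Decreasing sigmoid multiplier applied to growth or annual survival:
#' \deqn{s_3 + \frac{1 - s_3}{1 + (S/s_1)^{s_2}}}
#' It is flat (about 1) at low deposition, passes the midpoint of its
#' decline at `S = s1`, declines with steepness `s2`, and levels off at the
#' plateau `s3` as deposition grows.
#'
#' @param S Sulfur deposition, kg S ha-1 yr-1; may be 0.
#' @param s1 Deposition at which half the total decline has occurred; > 0.
#' @param s2 Steepness of the decline; > 0.
#' @param s3 Lower plateau in [0, 1).
#' @return Numeric vector in (s3, 1].
#' @examples
#' sulfur_sigmoid(0, 10, 2, 0.2)    # 1: no deposition, no reduction
#' sulfur_sigmoid(10, 10, 2, 0.2)   # 0.6: halfway between 1 and the plateau
#' @export
sulfur_sigmoid <- function(S, s1, s2, s3) {
  if (!is.finite(s1) || s1 <= 0) stop("sulfur_sigmoid: 's1' must be > 0")
  if (!is.finite(s2) || s2 <= 0) stop("sulfur_sigmoid: 's2' must be > 0")
  if (!is.finite(s3) || s3 < 0 || s3 >= 1) {
    stop("sulfur_sigmoid: 's3' must lie in [0, 1)")
  }
  if (any(S < 0)) stop("sulfur_sigmoid: 'S' must be >= 0")
  s3 + (1 - s3) / (1 + (S / s1)^s2)
}

# Deposition floor applied before lognormal evaluation, so that zero N (or
# zero S under the lognormal form) stays in the modifier's domain.
DEPOSITION_EPS <- 0.01

floor_deposition <- function(x, eps = DEPOSITION_EPS) pmax(x, eps)
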