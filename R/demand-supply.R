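# Linear inverse demand P(y) = a - b*y (yuan/t), calibrated so the curve
# passes through the observed point with the stated own-price elasticity.
# Its integral (gross consumer benefit) gives the quadratic surplus terms of
# the welfare objective. Input supply is perfectly elastic, so the input-side
# integral collapses to sum(w_i * X_i) and needs no calibration.

#' Calibrate a linear inverse demand curve at an observed point
#'
#' Given an observed price `p0` (yuan/t), quantity `q0` (t) and own-price
#' elasticity `e < 0`, returns the intercept and slope of the line
#' \eqn{P(y) = a - b y} passing through the point with that point elasticity:
#' \eqn{b = p_0 / (|e| q_0)}, \eqn{a = p_0 (1 + 1/|e|)}.
#'
#' @param p0_yuan_per_t observed price, yuan/t.
#' @param q0_t observed quantity, t.
#' @param elasticity own-price elasticity (strictly negative).
#' @return list with vectors `intercept_a` (yuan/t) and `slope_b`
#'   (yuan/t per t).
#' @examples
#' calibrate_linear_inverse_demand(4350, 841000, -0.3)
#' @export
calibrate_linear_inverse_demand <- function(p0_yuan_per_t, q0_t, elasticity) {
  stopifnot(all(p0_yuan_per_t > 0), all(q0_t > 0))
  if (any(elasticity >= 0)) stop("elasticity must be strictly negative")
  ae <- abs(elasticity)
  list(intercept_a = p0_yuan_per_t * (1 + 1 / ae),
       slope_b = p0_yuan_per_t / (ae * q0_t))
}

#' Evaluate inverse demand at a quantity
#'
#' @param spec list or one-row data.frame with `intercept_a` and `slope_b`.
#' @param y_t quantity, t (vectorized).
#' @return price in yuan/t, floored at zero beyond the choke quantity.
#' @export
price_at_quantity <- function(spec, y_t) {
  stopifnot(all(y_t >= 0))
  pmax(spec$intercept_a - spec$slope_b * y_t, 0)
}

#' Gross consumer benefit (integral of inverse demand)
#'
#' \eqn{\int_0^y P(u) du = a y - b y^2 / 2} for an endogenous-price spec;
#' with `slope_b = 0` (fixed-price closure) this is just `a * y`. Errors if
#' `y` exceeds the choke quantity `a/b`, where the integrand would go
#' negative.
#'
#' @inheritParams price_at_quantity
#' @return benefit in yuan.
#' @export
gross_consumer_benefit <- function(spec, y_t) {
  stopifnot(all(y_t >= 0))
  a <- spec$intercept_a
  b <- spec$slope_b
  if (any(b > 0 & y_t > a / b * (1 + 1e-12))) {
    stop("quantity beyond the choke quantity a/b")
  }
  a * y_t - b * y_t^2 / 2
}

#' Apply a market closure to demand specs
#'
#' `P_free` (closed regional economy) leaves the calibrated curves untouched;
#' `P_fixed` (price taker) replaces each with a perfectly elastic curve at
#' the observed price (`slope_b = 0`, `intercept_a = p0` in yuan/t), turning
#' the surplus objective linear.
#'
#' @param specs demand data.frame with derived coefficients.
#' @param economy `"P_fixed"` or `"P_free"`.
#' @return demand data.frame with the closure applied.
#' @export
apply_closure <- function(specs, economy = c("P_free", "P_fixed")) {
  economy <- match.arg(economy)
  if (economy == "P_free") return(specs)
  out <- specs
  out$slope_b <- 0
  out$intercept_a <- out$p0_yuan_per_kg * 1000
  out
}
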