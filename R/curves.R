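#' Quadratic pressure-flow curve
#'
#' The elementary object of the model: every circuit component and every
#' tabulated pump speed is characterised by a quadratic relation
#' \deqn{P(Q) = K_1 Q^2 + K_2 Q + K_3}
#' with `P` in mmHg and `Q` in L/min. For passive components (cannulas,
#' tubing, oxygenator) `K1` carries the inertial (density-driven) losses,
#' `K2` the viscous losses, and `K3` is constrained to zero because a
#' passive element drops no pressure at zero flow. For a centrifugal pump
#' curve `K3` is the shut-off head: the maximum pressure the pump develops
#' against a fully obstructed circuit.
#'
#' @param k1 coefficient of \eqn{Q^2} (mmHg min^2 / L^2)
#' @param k2 coefficient of \eqn{Q} (mmHg min / L)
#' @param k3 constant offset (mmHg); shut-off head for pump curves
#' @return an object of class `quadratic_curve`
#' @examples
#' tube <- quadratic_curve(4, 0, 0)
#' eval_curve(tube, 5)   # 100 mmHg across 1 m of 3/8-inch tubing
#' @export
quadratic_curve <- function(k1, k2, k3 = 0) {
  for (v in list(k1, k2, k3)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("quadratic_curve coefficients must be finite scalars", call. = FALSE)
    }
  }
  structure(list(k1 = as.numeric(k1), k2 = as.numeric(k2), k3 = as.numeric(k3)),
            class = "quadratic_curve")
}

#' @export
print.quadratic_curve <- function(x, ...) {
  cat(sprintf("P(Q) = %g Q^2 + %g Q + %g  [mmHg; Q in L/min]\n",
              x$k1, x$k2, x$k3))
  invisible(x)
}

#' Evaluate a quadratic curve at given flows
#'
#' @param curve a [quadratic_curve]
#' @param q flow rate(s), L/min
#' @return pressure(s) in mmHg, `k1*q^2 + k2*q + k3`
#' @export
eval_curve <- function(curve, q) {
  stopifnot(inherits(curve, "quadratic_curve"))
  curve$k1 * q^2 + curve$k2 * q + curve$k3
}

#' Coefficient-wise sum of quadratic curves
#'
#' Series hydraulic elements add their pressure drops at equal flow, so the
#' circuit curve is the coefficient-wise sum of the component curves.
#'
#' @param curves a list of [quadratic_curve] objects
#' @return a [quadratic_curve]
#' @export
sum_curves <- function(curves) {
  if (length(curves) == 0L) {
    stop("cannot sum an empty list of curves", call. = FALSE)
  }
  quadratic_curve(
    k1 = sum(vapply(curves, `[[`, numeric(1), "k1")),
    k2 = sum(vapply(curves, `[[`, numeric(1), "k2")),
    k3 = sum(vapply(curves, `[[`, numeric(1), "k3"))
  )
}

#' Catalog point set
#'
#' A set of (flow, pressure) pairs digitised from a manufacturer catalog,
#' the raw material for [fit_quadratic_curve()].
#'
#' @param q flows (L/min, >= 0)
#' @param p pressures (mmHg)
#' @param source_label free-text provenance (component name, pump rpm, ...)
#' @return an object of class `catalog_points`
#' @export
catalog_points <- function(q, p, source_label = "points") {
  q <- as.numeric(q); p <- as.numeric(p)
  if (length(q) != length(p)) {
    stop("flow and pressure vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(!is.finite(p))) {
    stop("catalog points must be finite", call. = FALSE)
  }
  if (any(q < 0)) {
    stop("catalog flows must be non-negative", call. = FALSE)
  }
  structure(list(q = q, p = p, source_label = as.character(source_label)[1]),
            class = "catalog_points")
}

#' Fit a quadratic pressure-flow curve to catalog points
#'
#' Ordinary least squares fit of `p ~ q^2 + q (+ 1)`. With
#' `constrain_zero_intercept = TRUE` the intercept K3 is fixed at zero and
#' only (K1, K2) are estimated -- the appropriate model for passive
#' components, which drop no pressure at zero flow. Pump curves are fitted
#' unconstrained so that K3 estimates the shut-off head. With exactly as
#' many points as free parameters the fit interpolates the points exactly.
#'
#' @param points a [catalog_points] object (or a data.frame with columns
#'   `q` and `p`)
#' @param constrain_zero_intercept force K3 = 0 (passive components)
#' @return a [quadratic_curve]
#' @export
fit_quadratic_curve <- function(points, constrain_zero_intercept = FALSE) {
  if (is.data.frame(points)) {
    points <- catalog_points(points$q, points$p)
  }
  stopifnot(inherits(points, "catalog_points"))
  q <- points$q; p <- points$p
  n_par <- if (constrain_zero_intercept) 2L else 3L
  if (length(q) < n_par) {
    stop(sprintf(
      "fitting degeneracy for '%s': %d point(s) but %d free coefficients",
      points$source_label, length(q), n_par), call. = FALSE)
  }
  if (length(unique(q)) < n_par) {
    stop(sprintf(
      "fitting degeneracy for '%s': only %d distinct flow value(s), need %d",
      points$source_label, length(unique(q)), n_par), call. = FALSE)
  }
  df <- data.frame(q = q, p = p)
  fit <- if (constrain_zero_intercept) {
    stats::lm(p ~ 0 + I(q^2) + q, data = df)
  } else {
    stats::lm(p ~ I(q^2) + q, data = df)
  }
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) {
    stop(sprintf("fitting degeneracy for '%s': singular design",
                 points$source_label), call. = FALSE)
  }
  if (constrain_zero_intercept) {
    quadratic_curve(k1 = cf[["I(q^2)"]], k2 = cf[["q"]], k3 = 0)
  } else {
    quadratic_curve(k1 = cf[["I(q^2)"]], k2 = cf[["q"]],
                    k3 = cf[["(Intercept)"]])
  }
}
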