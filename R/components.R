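COMPONENT_KINDS <- c("drainage_cannula", "return_cannula",
                     "connecting_tube", "oxygenator")

#' Passive circuit component
#'
#' A cannula, connecting tube or oxygenator, represented by its quadratic
#' pressure-drop curve. Passive components must have K3 = 0: at zero flow a
#' passive element drops zero pressure, which is also what makes the
#' drainage-to-return pressure walk close exactly on the venous bath.
#'
#' @param name identifier
#' @param kind one of `"drainage_cannula"`, `"return_cannula"`,
#'   `"connecting_tube"`, `"oxygenator"`
#' @param curve a [quadratic_curve] with `k3 == 0`
#' @param size_fr optional French size (cannulas)
#' @param length_m optional length in metres (tubes)
#' @return an object of class `passive_component`
#' @export
passive_component <- function(name, kind, curve, size_fr = NULL,
                              length_m = NULL) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  stopifnot(inherits(curve, "quadratic_curve"))
  if (curve$k3 != 0) {
    stop(sprintf(
      "passive component '%s' must have k3 = 0 (zero flow => zero drop), got %g",
      name, curve$k3), call. = FALSE)
  }
  structure(list(name = as.character(name), kind = kind, curve = curve,
                 size_fr = size_fr, length_m = length_m),
            class = "passive_component")
}

#' Default 3/8-inch connecting tube
#'
#' The connecting-tube model is a pure quadratic drop per unit length,
#' \eqn{\Delta P = a L Q^2}, with the default coefficient
#' `a = 4` mmHg min^2/L^2 per metre calibrated so that 1 m of 3/8-inch
#' tubing drops 100 mmHg at 5 L/min (the Alfred ECMO guideline anchor).
#' The split between the quadratic and linear terms is configurable via
#' `k1_per_m` / `k2_per_m` for users with measured tube data.
#'
#' @param name identifier
#' @param length_m tube length in metres
#' @param k1_per_m quadratic coefficient per metre (default 4)
#' @param k2_per_m linear coefficient per metre (default 0)
#' @return a [passive_component] of kind `connecting_tube`
#' @examples
#' component_pressure_drop(connecting_tube("t", 1), 5)  # 100 mmHg
#' @export
connecting_tube <- function(name, length_m, k1_per_m = 4, k2_per_m = 0) {
  if (!is.numeric(length_m) || length_m <= 0) {
    stop("tube length must be a positive number of metres", call. = FALSE)
  }
  passive_component(
    name, "connecting_tube",
    quadratic_curve(k1 = k1_per_m * length_m, k2 = k2_per_m * length_m, k3 = 0),
    length_m = length_m
  )
}

#' @export
print.passive_component <- function(x, ...) {
  cat(sprintf("<%s '%s'> ", x$kind, x$name))
  print(x$curve)
  invisible(x)
}

#' Pressure drop across a passive component
#'
#' @param component a [passive_component]
#' @param q flow rate(s), L/min, must be >= 0 (retrograde flow is outside
#'   the model's domain)
#' @param q_max upper end of the validated flow range; evaluation beyond it
#'   is allowed but flagged with a warning as extrapolation
#' @return pressure drop(s) in mmHg
#' @export
component_pressure_drop <- function(component, q, q_max = 10) {
  stopifnot(inherits(component, "passive_component"))
  if (any(q < 0)) {
    stop(sprintf("negative flow for component '%s': retrograde flow is not modelled",
                 component$name), call. = FALSE)
  }
  if (any(q > q_max)) {
    warning(sprintf("flow %g L/min beyond validated range [0, %g] for '%s': extrapolating",
                    max(q), q_max, component$name), call. = FALSE)
  }
  eval_curve(component$curve, q)
}

#' Centrifugal pump model
#'
#' A pump is a family of head-versus-flow curves, one per tabulated
#' rotational speed. Each curve must have a positive shut-off head
#' (K3 > 0, the head at zero flow) and non-increasing head over the
#' operating flow range; higher speeds shift the curve upward. No
#' interpolation between tabulated speeds is performed.
#'
#' @param name identifier
#' @param curves_by_rpm named list of [quadratic_curve], names are rpm values
#' @param q_max flow range (L/min) over which monotonicity is checked
#' @return an object of class `pump_model`
#' @export
pump_model <- function(name, curves_by_rpm, q_max = 10) {
  if (length(curves_by_rpm) == 0L || is.null(names(curves_by_rpm)) ||
      any(names(curves_by_rpm) == "")) {
    stop("curves_by_rpm must be a non-empty list named by rpm", call. = FALSE)
  }
  rpms <- suppressWarnings(as.numeric(names(curves_by_rpm)))
  if (any(is.na(rpms))) {
    stop("curves_by_rpm names must be numeric rotational speeds", call. = FALSE)
  }
  for (i in seq_along(curves_by_rpm)) {
    cv <- curves_by_rpm[[i]]
    stopifnot(inherits(cv, "quadratic_curve"))
    if (cv$k3 <= 0) {
      stop(sprintf("pump '%s' at %s rpm: shut-off head (k3) must be > 0, got %g",
                   name, names(curves_by_rpm)[i], cv$k3), call. = FALSE)
    }
    # head must not increase with flow anywhere on [0, q_max]
    dhead <- function(q) 2 * cv$k1 * q + cv$k2
    if (dhead(0) > 1e-12 || dhead(q_max) > 1e-12) {
      stop(sprintf("pump '%s' at %s rpm: head must be non-increasing in flow over [0, %g]",
                   name, names(curves_by_rpm)[i], q_max), call. = FALSE)
    }
  }
  structure(list(name = as.character(name), curves_by_rpm = curves_by_rpm,
                 q_max = q_max),
            class = "pump_model")
}

#' @export
print.pump_model <- function(x, ...) {
  cat(sprintf("<pump '%s'> tabulated speeds: %s rpm\n", x$name,
              paste(names(x$curves_by_rpm), collapse = ", ")))
  invisible(x)
}

#' Look up a pump curve at a tabulated speed
#'
#' @param pump a [pump_model]
#' @param rpm a tabulated rotational speed; untabulated speeds raise an
#'   error listing the available ones (no silent interpolation)
#' @return the [quadratic_curve] for that speed
#' @export
pump_curve_at <- function(pump, rpm) {
  stopifnot(inherits(pump, "pump_model"))
  key <- which(abs(as.numeric(names(pump$curves_by_rpm)) - rpm) < 1e-9)
  if (length(key) != 1L) {
    stop(sprintf("pump '%s' has no curve tabulated at %g rpm; available: %s",
                 pump$name, rpm,
                 paste(names(pump$curves_by_rpm), collapse = ", ")),
         call. = FALSE)
  }
  pump$curves_by_rpm[[key]]
}

#' Pump head at a tabulated speed and flow
#'
#' Evaluates the pump's head-flow curve for the given speed. At `q = 0`
#' this is exactly the shut-off head K3.
#'
#' @inheritParams pump_curve_at
#' @param q flow rate(s), L/min, >= 0
#' @return head(s) in mmHg
#' @export
pump_head_at <- function(pump, rpm, q) {
  if (any(q < 0)) {
    stop("negative flow through the pump is not modelled", call. = FALSE)
  }
  eval_curve(pump_curve_at(pump, rpm), q)
}
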