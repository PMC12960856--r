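#' ECMO circuit definition
#'
#' The ordered series circuit the prediction consumes: drainage-side
#' components (patient to pump, typically drainage cannula then connecting
#' tube 1), the pump at one tabulated speed, and return-side components
#' (pump to patient, typically connecting tube 2, oxygenator, connecting
#' tube 3, return cannula). The named taps are positional: P1 sits after
#' the last drainage-side component (pump inlet), P2 immediately before the
#' oxygenator, P3 immediately after it.
#'
#' @param drainage_side list of [passive_component], patient to pump
#' @param pump a [pump_model]
#' @param rpm rotational speed; must be tabulated in the pump model
#' @param return_side list of [passive_component], pump to patient
#' @param cvp central venous pressure, mmHg (bench default 0: open bath)
#' @param bed_height_cm height of the bed/bath above pump level, cm, >= 0
#' @return an object of class `circuit_definition`
#' @export
circuit_definition <- function(drainage_side, pump, rpm, return_side,
                               cvp = 0, bed_height_cm = 0) {
  stopifnot(inherits(pump, "pump_model"))
  for (comp in c(drainage_side, return_side)) {
    stopifnot(inherits(comp, "passive_component"))
  }
  if (length(drainage_side) + length(return_side) < 1L) {
    stop("circuit needs at least one passive component", call. = FALSE)
  }
  if (bed_height_cm < 0) {
    stop("bed height must be >= 0 cm", call. = FALSE)
  }
  pump_curve_at(pump, rpm)  # validates the speed is tabulated
  structure(list(drainage_side = drainage_side, pump = pump, rpm = rpm,
                 return_side = return_side, cvp = cvp,
                 bed_height_cm = bed_height_cm),
            class = "circuit_definition")
}

#' @export
print.circuit_definition <- function(x, ...) {
  cat("<ecmo circuit>\n")
  cat("  drainage side:", paste(vapply(x$drainage_side, `[[`, "", "name"),
                                collapse = " -> "), "\n")
  cat(sprintf("  pump: %s @ %g rpm\n", x$pump$name, x$rpm))
  cat("  return side:  ", paste(vapply(x$return_side, `[[`, "", "name"),
                                collapse = " -> "), "\n")
  cat(sprintf("  CVP %g mmHg, bed height %g cm\n", x$cvp, x$bed_height_cm))
  invisible(x)
}

#' Total passive pressure-flow curve of a circuit
#'
#' Coefficient-wise sum of every passive component's curve (drainage plus
#' return side). Because each passive curve has K3 = 0, the total also has
#' K3 = 0.
#'
#' @param circuit a [circuit_definition]
#' @return a [quadratic_curve]
#' @export
total_passive_curve <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_definition"))
  comps <- c(circuit$drainage_side, circuit$return_side)
  sum_curves(lapply(comps, `[[`, "curve"))
}

#' Solve the circuit/pump operating point
#'
#' Finds the flow `q*` at which the pump head equals the total passive
#' pressure drop -- the intersection of the circuit and pump curves,
#' obtained in closed form via the quadratic formula. Among real roots, the
#' stable operating point is the one where the pump curve crosses the
#' circuit curve from above (the head surplus changes sign + to -); for the
#' physically typical downward-opening head surplus with positive shut-off
#' head this root is unique and positive.
#'
#' @param circuit a [circuit_definition]
#' @param q_max upper end of the physical flow domain (L/min)
#' @return an object of class `operating_point`: list with `q` (L/min) and
#'   `pump_head` (mmHg)
#' @export
solve_operating_point <- function(circuit, q_max = 10) {
  stopifnot(inherits(circuit, "circuit_definition"))
  cc <- total_passive_curve(circuit)
  pc <- pump_curve_at(circuit$pump, circuit$rpm)
  intersect_curves(cc, pc, q_max = q_max)
}

#' Intersect a circuit curve with a pump curve
#'
#' Curve-level workhorse behind [solve_operating_point()]: finds the stable
#' positive root of the head surplus `pump(q) - circuit(q)` by the
#' quadratic formula.
#'
#' @param circuit_curve total passive [quadratic_curve] of the circuit
#' @param pump_curve pump head [quadratic_curve] at the chosen speed
#' @param q_max flow domain upper bound (L/min)
#' @return an `operating_point`
#' @export
intersect_curves <- function(circuit_curve, pump_curve, q_max = 10) {
  stopifnot(inherits(circuit_curve, "quadratic_curve"),
            inherits(pump_curve, "quadratic_curve"))
  cc <- circuit_curve
  pc <- pump_curve
  # head surplus d(q) = pump(q) - circuit(q) = a q^2 + b q + c; root with
  # d'(root) < 0 is the stable crossing
  a <- pc$k1 - cc$k1
  b <- pc$k2 - cc$k2
  c <- pc$k3 - cc$k3

  roots <- if (abs(a) < 1e-300) {
    if (abs(b) < 1e-300) numeric(0) else -c / b
  } else {
    disc <- b^2 - 4 * a * c
    if (disc < 0) {
      stop("no operating point: pump and circuit curves do not intersect (negative discriminant)",
           call. = FALSE)
    }
    sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  }
  pos <- roots[roots > 0]
  if (length(pos) == 0L) {
    stop("no operating point: no positive-flow intersection of pump and circuit curves",
         call. = FALSE)
  }
  dprime <- if (abs(a) < 1e-300) rep(b, length(pos)) else 2 * a * pos + b
  stable <- pos[dprime < 0]
  if (length(stable) == 0L) {
    stop("no operating point: no stable crossing (pump curve never crosses the circuit curve from above)",
         call. = FALSE)
  }
  if (length(stable) > 1L) {
    stop(sprintf("ambiguous operating point: two stable candidates at q = %s L/min",
                 paste(signif(stable, 6), collapse = ", ")), call. = FALSE)
  }
  q_star <- stable[[1]]
  if (q_star > q_max) {
    warning(sprintf("operating point %g L/min beyond flow domain [0, %g]: extrapolating",
                    q_star, q_max), call. = FALSE)
  }
  structure(list(q = q_star, pump_head = eval_curve(pc, q_star)),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("operating point: Q = %.3f L/min, pump head = %.1f mmHg\n",
              x$q, x$pump_head))
  invisible(x)
}

#' Walk node pressures around the circuit
#'
#' Starting from the CVP at the drainage bath, sequentially subtracts each
#' drainage-side pressure drop at the operating flow, adds the pump head,
#' and subtracts each return-side drop, recording the pressure at every
#' node. P1 is the node after the last drainage-side component, P2 the node
#' just before the oxygenator, P3 the node just after it. The final node
#' closes the loop back onto the CVP exactly (energy balance).
#'
#' @param circuit a [circuit_definition]
#' @param op the [operating_point] solved for this circuit
#' @param tol consistency tolerance for the energy balance, mmHg
#' @return an object of class `pressure_profile`: data.frame of node
#'   pressures plus named taps `p1`, `p2`, `p3` and `bed_height_cm` (0 at
#'   this stage; see [apply_bed_height()])
#' @export
walk_pressures <- function(circuit, op, tol = 1e-6) {
  stopifnot(inherits(circuit, "circuit_definition"),
            inherits(op, "operating_point"))
  q <- op$q
  head_q <- pump_head_at(circuit$pump, circuit$rpm, q)
  total_drop <- eval_curve(total_passive_curve(circuit), q)
  if (abs(head_q - op$pump_head) > tol || abs(head_q - total_drop) > tol) {
    stop(sprintf("operating point inconsistent with circuit: pump head %.6g, total drop %.6g",
                 head_q, total_drop), call. = FALSE)
  }

  labels <- "drainage bath (CVP)"
  pressures <- circuit$cvp
  p <- circuit$cvp
  for (comp in circuit$drainage_side) {
    p <- p - suppressWarnings(component_pressure_drop(comp, q))
    labels <- c(labels, paste0("after ", comp$name))
    pressures <- c(pressures, p)
  }
  p1 <- p  # pump inlet
  p <- p + op$pump_head
  labels <- c(labels, "pump outlet")
  pressures <- c(pressures, p)
  p2 <- NA_real_; p3 <- NA_real_
  kinds <- vapply(circuit$return_side, `[[`, "", "kind")
  oxy_idx <- which(kinds == "oxygenator")
  for (i in seq_along(circuit$return_side)) {
    comp <- circuit$return_side[[i]]
    if (length(oxy_idx) == 1L && i == oxy_idx) p2 <- p
    p <- p - suppressWarnings(component_pressure_drop(comp, q))
    labels <- c(labels, paste0("after ", comp$name))
    pressures <- c(pressures, p)
    if (length(oxy_idx) == 1L && i == oxy_idx) p3 <- p
  }
  labels[length(labels)] <- paste0(labels[length(labels)], " / return bath (CVP)")

  structure(list(
    node_pressures = data.frame(node = labels, pressure_mmhg = pressures,
                                stringsAsFactors = FALSE),
    p1 = p1, p2 = p2, p3 = p3,
    q = q, cvp = circuit$cvp, bed_height_cm = 0
  ), class = "pressure_profile")
}

#' @export
print.pressure_profile <- function(x, ...) {
  df <- x$node_pressures
  df$pressure_mmhg <- round(df$pressure_mmhg, 1)
  print(df, row.names = FALSE)
  cat(sprintf("P1 = %.1f, P2 = %.1f, P3 = %.1f mmHg (bed height %g cm)\n",
              x$p1, x$p2, x$p3, x$bed_height_cm))
  invisible(x)
}

#' Retrieve a named tap pressure
#'
#' @param profile a [pressure_profile]
#' @param tap one of `"P1"`, `"P2"`, `"P3"`
#' @return the tap pressure in mmHg; circuits without an oxygenator have no
#'   P2/P3 and raise an error when those taps are requested
#' @export
tap_pressure <- function(profile, tap = c("P1", "P2", "P3")) {
  stopifnot(inherits(profile, "pressure_profile"))
  tap <- match.arg(tap)
  val <- profile[[tolower(tap)]]
  if (is.na(val)) {
    stop(sprintf("tap %s is undefined: circuit has no oxygenator", tap),
         call. = FALSE)
  }
  val
}

#' Apply the bed-height hydrostatic offset
#'
#' Elevating the bed (patient/bath level) above the pump/oxygenator level
#' converts potential energy into pressure at every pump-level node:
#' `h` cm of water column adds `h / 1.36` mmHg to P1, P2, P3 and all other
#' interior nodes, while the bath-level endpoints (CVP nodes) and the flow
#' rate are unchanged. Optionally the blood specific gravity of 1.05 can be
#' included; by default it is omitted as its effect is minimal.
#'
#' @param profile a [pressure_profile] (as produced by [walk_pressures()],
#'   i.e. expressed at bed height 0)
#' @param bed_height_cm height of bed above pump level, cm, >= 0
#' @param include_specific_gravity multiply the offset by 1.05
#' @return a new [pressure_profile] with the offset applied
#' @export
apply_bed_height <- function(profile, bed_height_cm,
                             include_specific_gravity = FALSE) {
  stopifnot(inherits(profile, "pressure_profile"))
  if (bed_height_cm < 0) {
    stop("bed height must be >= 0 cm", call. = FALSE)
  }
  offset <- bed_height_cm / 1.36
  if (include_specific_gravity) offset <- offset * 1.05
  out <- profile
  n <- nrow(out$node_pressures)
  interior <- setdiff(seq_len(n), c(1L, n))
  out$node_pressures$pressure_mmhg[interior] <-
    out$node_pressures$pressure_mmhg[interior] + offset
  out$p1 <- out$p1 + offset
  if (!is.na(out$p2)) out$p2 <- out$p2 + offset
  if (!is.na(out$p3)) out$p3 <- out$p3 + offset
  out$bed_height_cm <- profile$bed_height_cm + bed_height_cm
  out
}

#' Predict ECMO flow rate and circuit pressures
#'
#' The full four-step prediction: (1) component curves are already fitted
#' in the circuit definition; (2) solve the operating point; (3) walk the
#' node pressures from the drainage side; (4) apply the circuit's
#' bed-height hydrostatic offset. Returns the headline outputs.
#'
#' @param circuit a [circuit_definition]
#' @param q_max flow domain upper bound (L/min)
#' @param include_specific_gravity include the 1.05 blood specific gravity
#'   factor in the hydrostatic offset
#' @return an object of class `ecmo_prediction`: list with `q` (L/min),
#'   `p1`, `p2`, `p3` (mmHg) and the full `profile`
#' @export
predict_circuit <- function(circuit, q_max = 10,
                            include_specific_gravity = FALSE) {
  op <- tryCatch(solve_operating_point(circuit, q_max = q_max),
                 error = function(e) {
                   stop(sprintf("operating-point step failed: %s",
                                conditionMessage(e)), call. = FALSE)
                 })
  profile <- tryCatch(walk_pressures(circuit, op),
                      error = function(e) {
                        stop(sprintf("pressure-walk step failed: %s",
                                     conditionMessage(e)), call. = FALSE)
                      })
  profile <- apply_bed_height(profile, circuit$bed_height_cm,
                              include_specific_gravity)
  structure(list(q = op$q, p1 = profile$p1, p2 = profile$p2,
                 p3 = profile$p3, pump_head = op$pump_head,
                 profile = profile),
            class = "ecmo_prediction")
}

#' @export
print.ecmo_prediction <- function(x, ...) {
  cat(sprintf("Q = %.2f L/min | P1 = %.1f, P2 = %.1f, P3 = %.1f mmHg\n",
              x$q, x$p1, x$p2, x$p3))
  invisible(x)
}
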