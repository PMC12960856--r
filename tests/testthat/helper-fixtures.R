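# Shared fixtures built in code.

# Toy circuit engineered so the hand-bookkept pressure walk is exact:
# total passive curve (3,0,0) against pump (-1,0,100) gives q* = 5 and
# per-component drops at q* of drain 10, tube1 2, tube2 3, oxygenator 20,
# tube3 3, return 37 (head 75).
toy_circuit <- function(cvp = 0, bed_height_cm = 0, shutoff = 100) {
  circuit_definition(
    drainage_side = list(
      passive_component("drain", "drainage_cannula", quadratic_curve(0.40, 0, 0)),
      passive_component("tube1", "connecting_tube", quadratic_curve(0.08, 0, 0))
    ),
    pump = pump_model("pump", list(`3000` = quadratic_curve(-1, 0, shutoff))),
    rpm = 3000,
    return_side = list(
      passive_component("tube2", "connecting_tube", quadratic_curve(0.12, 0, 0)),
      passive_component("oxy", "oxygenator", quadratic_curve(0.80, 0, 0)),
      passive_component("tube3", "connecting_tube", quadratic_curve(0.12, 0, 0)),
      passive_component("return", "return_cannula", quadratic_curve(1.48, 0, 0))
    ),
    cvp = cvp, bed_height_cm = bed_height_cm
  )
}

# Random solvable circuit: pump surplus is a downward parabola positive at
# q = 0, so exactly one stable positive crossing exists.
random_circuit <- function() {
  comps <- list(
    passive_component("d", "drainage_cannula",
                      quadratic_curve(runif(1, 0.5, 4), runif(1, 0, 6), 0)),
    passive_component("t", "connecting_tube",
                      quadratic_curve(runif(1, 1, 8), 0, 0)),
    passive_component("o", "oxygenator",
                      quadratic_curve(runif(1, 0.2, 2), runif(1, 1, 6), 0)),
    passive_component("r", "return_cannula",
                      quadratic_curve(runif(1, 1, 8), runif(1, 2, 10), 0))
  )
  pump <- pump_model("p", list(`3000` = quadratic_curve(
    -runif(1, 0.5, 4), -runif(1, 0, 5), runif(1, 60, 400))))
  circuit_definition(
    drainage_side = comps[1:2], pump = pump, rpm = 3000,
    return_side = comps[3:4],
    cvp = runif(1, -5, 15), bed_height_cm = sample(c(0, 40, 80), 1)
  )
}

# Independent grid-scan oracle for the operating point: minimise
# |circuit(q) - pump(q)| on a fine grid.
grid_scan_operating_point <- function(circuit, q_max = 10, step = 1e-4) {
  qs <- seq(step, q_max, by = step)
  cc <- total_passive_curve(circuit)
  pc <- pump_curve_at(circuit$pump, circuit$rpm)
  gap <- abs(eval_curve(cc, qs) - eval_curve(pc, qs))
  qs[which.min(gap)]
}

# Independent normal-equations OLS oracle for the quadratic fit.
normal_equations_fit <- function(q, p, constrain_zero_intercept = FALSE) {
  X <- if (constrain_zero_intercept) cbind(q^2, q) else cbind(q^2, q, 1)
  beta <- solve(t(X) %*% X, t(X) %*% p)
  if (constrain_zero_intercept) c(k1 = beta[1], k2 = beta[2], k3 = 0)
  else c(k1 = beta[1], k2 = beta[2], k3 = beta[3])
}
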