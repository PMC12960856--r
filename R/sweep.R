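#' Factorial sweep grid
#'
#' The cartesian product of drainage-cannula sizes, return-cannula sizes,
#' pump speeds and bed heights evaluated on a shared backbone of tubes and
#' oxygenator. The bench design of 2 x 2 x 3 x 3 = 36 combinations is the
#' default shape.
#'
#' @param drainage_refs component names of candidate drainage cannulas
#' @param return_refs component names of candidate return cannulas
#' @param rpms pump speeds (each must be tabulated in the pump model)
#' @param bed_heights_cm bed heights in cm
#' @param pump_ref pump name
#' @param tube1_ref,tube2_ref,tube3_ref connecting-tube component names
#' @param oxygenator_ref oxygenator component name
#' @param cvp central venous pressure, mmHg
#' @return an object of class `sweep_grid`
#' @export
sweep_grid <- function(drainage_refs = c("drain_18fr", "drain_22fr"),
                       return_refs = c("return_14fr", "return_18fr"),
                       rpms = c(2500, 3000, 3500),
                       bed_heights_cm = c(0, 40, 80),
                       pump_ref = "centrifugal",
                       tube1_ref = "tube1", tube2_ref = "tube2",
                       tube3_ref = "tube3",
                       oxygenator_ref = "oxygenator",
                       cvp = 0) {
  stopifnot(length(drainage_refs) >= 1, length(return_refs) >= 1,
            length(rpms) >= 1, length(bed_heights_cm) >= 1)
  structure(list(drainage_refs = drainage_refs, return_refs = return_refs,
                 rpms = rpms, bed_heights_cm = bed_heights_cm,
                 pump_ref = pump_ref, tube1_ref = tube1_ref,
                 tube2_ref = tube2_ref, tube3_ref = tube3_ref,
                 oxygenator_ref = oxygenator_ref, cvp = cvp),
            class = "sweep_grid")
}

grid_circuit <- function(grid, library, drain, ret, rpm, height) {
  circuit_definition(
    drainage_side = list(get_component(library, drain),
                         get_component(library, grid$tube1_ref)),
    pump = get_pump(library, grid$pump_ref),
    rpm = rpm,
    return_side = list(get_component(library, grid$tube2_ref),
                       get_component(library, grid$oxygenator_ref),
                       get_component(library, grid$tube3_ref),
                       get_component(library, ret)),
    cvp = grid$cvp,
    bed_height_cm = height
  )
}

#' Run the factorial prediction sweep
#'
#' Predicts flow and pressures for every combination of the grid, in the
#' deterministic nested order drainage -> return -> rpm -> height. A
#' combination without a valid operating point is kept as a row with its
#' error message in the `error` column rather than aborting the sweep; if
#' any row failed, the returned table carries `attr(, "n_failed") > 0`.
#'
#' @param grid a [sweep_grid]
#' @param library a [component_library]
#' @return data.frame with columns `combo_id`, `drain`, `return_cannula`,
#'   `drain_fr`, `return_fr`, `rpm`, `bed_height_cm`, `q_l_min`, `p1_mmhg`,
#'   `p2_mmhg`, `p3_mmhg`, `error`
#' @export
run_sweep <- function(grid, library) {
  stopifnot(inherits(grid, "sweep_grid"),
            inherits(library, "component_library"))
  rows <- list()
  i <- 0L
  for (drain in grid$drainage_refs) {
    for (ret in grid$return_refs) {
      for (rpm in grid$rpms) {
        for (height in grid$bed_heights_cm) {
          i <- i + 1L
          res <- tryCatch({
            circ <- grid_circuit(grid, library, drain, ret, rpm, height)
            pred <- suppressWarnings(predict_circuit(circ))
            list(q = pred$q, p1 = pred$p1, p2 = pred$p2, p3 = pred$p3,
                 error = NA_character_)
          }, error = function(e) {
            list(q = NA_real_, p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
                 error = conditionMessage(e))
          })
          dcomp <- library$components[[drain]]
          rcomp <- library$components[[ret]]
          rows[[i]] <- data.frame(
            combo_id = sprintf("c%02d", i),
            drain = drain, return_cannula = ret,
            drain_fr = dcomp$size_fr %||% NA_real_,
            return_fr = rcomp$size_fr %||% NA_real_,
            rpm = rpm, bed_height_cm = height,
            q_l_min = res$q, p1_mmhg = res$p1, p2_mmhg = res$p2,
            p3_mmhg = res$p3, error = res$error,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- sum(!is.na(out$error))
  out
}

#' Synthetic bench specification
#'
#' Parameters of the synthetic measurement generator: a sweep grid plus
#' Gaussian measurement-noise standard deviations and a seed. The default
#' noise levels (0.12 L/min on flow, 10 mmHg on pressures) emulate the
#' bench-scale disagreement the model is expected to show against a real
#' rig; sd 0 produces measurements equal to the predictions.
#'
#' @param grid a [sweep_grid]
#' @param sd_flow Gaussian noise sd on flow, L/min, >= 0
#' @param sd_pressure Gaussian noise sd on each pressure tap, mmHg, >= 0
#' @param seed integer RNG seed; fixes the output exactly
#' @return an object of class `synthetic_bench_spec`
#' @export
synthetic_bench_spec <- function(grid = sweep_grid(), sd_flow = 0.12,
                                 sd_pressure = 10, seed = 1L) {
  stopifnot(inherits(grid, "sweep_grid"), sd_flow >= 0, sd_pressure >= 0)
  structure(list(grid = grid, sd_flow = sd_flow, sd_pressure = sd_pressure,
                 seed = as.integer(seed)),
            class = "synthetic_bench_spec")
}

#' Generate a synthetic bench-measurement table
#'
#' Runs the sweep and perturbs each prediction with seeded Gaussian noise:
#' `measured = predicted + N(0, sd)` independently for flow and each
#' pressure tap. The same spec (same seed) always produces the identical
#' table. Output uses the measurement-CSV column layout.
#'
#' @param spec a [synthetic_bench_spec]
#' @param library a [component_library]
#' @return data.frame with columns `combo_id`, `drain_fr`, `return_fr`,
#'   `rpm`, `bed_height_cm`, `q_meas_l_min`, `p1_mmhg`, `p2_mmhg`,
#'   `p3_mmhg`
#' @export
generate_synthetic_bench <- function(spec, library = default_component_library()) {
  stopifnot(inherits(spec, "synthetic_bench_spec"))
  preds <- run_sweep(spec$grid, library)
  if (attr(preds, "n_failed") > 0) {
    bad <- preds$combo_id[!is.na(preds$error)]
    stop(sprintf("cannot synthesise measurements: unsolvable combination(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(preds)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  data.frame(
    combo_id = preds$combo_id,
    drain_fr = preds$drain_fr, return_fr = preds$return_fr,
    rpm = preds$rpm, bed_height_cm = preds$bed_height_cm,
    q_meas_l_min = preds$q_l_min + stats::rnorm(n, 0, spec$sd_flow),
    p1_mmhg = preds$p1_mmhg + stats::rnorm(n, 0, spec$sd_pressure),
    p2_mmhg = preds$p2_mmhg + stats::rnorm(n, 0, spec$sd_pressure),
    p3_mmhg = preds$p3_mmhg + stats::rnorm(n, 0, spec$sd_pressure),
    stringsAsFactors = FALSE
  )
}

#' Validate sweep predictions against a measurement table
#'
#' Joins a prediction table (from [run_sweep()]) with a measurement table
#' (measurement-CSV layout) on `combo_id` and computes the agreement
#' statistics for the four series: flow, P1, P2, P3.
#'
#' @param predictions data.frame from [run_sweep()]
#' @param measurements data.frame in measurement-CSV layout
#' @return data.frame with one [compute_validation_stats()] row per series
#' @export
validate_predictions <- function(predictions, measurements) {
  m <- merge(predictions, measurements, by = "combo_id",
             suffixes = c("_pred", "_meas"))
  if (nrow(m) < 2L) {
    stop("insufficient overlapping combos between predictions and measurements",
         call. = FALSE)
  }
  if (anyNA(m$q_l_min)) {
    stop("prediction table contains failed rows; resolve them before validating",
         call. = FALSE)
  }
  series <- list(
    paired_series(m$q_l_min, m$q_meas_l_min, "flow", m$combo_id),
    paired_series(m$p1_mmhg_pred, m$p1_mmhg_meas, "P1", m$combo_id),
    paired_series(m$p2_mmhg_pred, m$p2_mmhg_meas, "P2", m$combo_id),
    paired_series(m$p3_mmhg_pred, m$p3_mmhg_meas, "P3", m$combo_id)
  )
  do.call(rbind, lapply(series, function(s)
    as.data.frame(compute_validation_stats(s))))
}
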