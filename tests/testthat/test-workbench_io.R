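test_that("the factorial bench grid produces 36 deterministic rows", {
  lib <- default_component_library()
  tab <- run_sweep(sweep_grid(), lib)
  expect_equal(nrow(tab), 36)
  expect_equal(attr(tab, "n_failed"), 0)
  # nested loop order: drainage -> return -> rpm -> height
  expect_equal(tab$drain, rep(c("drain_18fr", "drain_22fr"), each = 18))
  expect_equal(tab$rpm[1:9], rep(c(2500, 3000, 3500), each = 3))
  expect_equal(tab$bed_height_cm[1:3], c(0, 40, 80))
  # byte-identical across runs
  expect_identical(tab, run_sweep(sweep_grid(), lib))
})

test_that("a singleton grid equals a direct prediction", {
  lib <- default_component_library()
  grid <- sweep_grid(drainage_refs = "drain_18fr", return_refs = "return_14fr",
                     rpms = 3000, bed_heights_cm = 40)
  tab <- run_sweep(grid, lib)
  expect_equal(nrow(tab), 1)
  circ <- circuit_definition(
    drainage_side = list(lib$components$drain_18fr, lib$components$tube1),
    pump = lib$pumps$centrifugal, rpm = 3000,
    return_side = list(lib$components$tube2, lib$components$oxygenator,
                       lib$components$tube3, lib$components$return_14fr),
    cvp = 0, bed_height_cm = 40)
  pred <- predict_circuit(circ)
  expect_equal(tab$q_l_min, pred$q)
  expect_equal(tab$p1_mmhg, pred$p1)
  expect_equal(tab$p2_mmhg, pred$p2)
  expect_equal(tab$p3_mmhg, pred$p3)
})

test_that("unsolvable combinations are flagged per row, not fatal", {
  lib <- default_component_library()
  grid <- sweep_grid(rpms = c(3000, 2750))  # 2750 untabulated
  tab <- run_sweep(grid, lib)
  expect_equal(nrow(tab), 2 * 2 * 2 * 3)
  bad <- tab$rpm == 2750
  expect_true(all(is.na(tab$q_l_min[bad])))
  expect_true(all(grepl("2750", tab$error[bad])))
  expect_true(all(!is.na(tab$q_l_min[!bad])))
  expect_equal(attr(tab, "n_failed"), sum(bad))
})

test_that("component library round-trips through YAML including point-file fits", {
  dir <- withr::local_tempdir()
  pts <- file.path(dir, "tube_points.csv")
  write.csv(data.frame(flow_l_min = c(1, 5), pressure_mmhg = c(4, 100)),
            pts, row.names = FALSE)
  lib_file <- file.path(dir, "lib.yaml")
  writeLines(c(
    "components:",
    "  - name: drain_a",
    "    kind: drainage_cannula",
    "    k1: 2.5",
    "    k2: 4.0",
    "    k3: 0",
    "    size_fr: 18",
    "  - name: tube_a",
    "    kind: connecting_tube",
    "    points_file: tube_points.csv",
    "pumps:",
    "  - name: pump_a",
    "    curves:",
    "      '3000': {k1: -2, k2: -1, k3: 250}",
    "      '3500': {k1: -2, k2: -1, k3: 340}"
  ), lib_file)
  lib <- load_component_library(lib_file)
  expect_equal(lib$components$drain_a$curve, quadratic_curve(2.5, 4, 0))
  expect_equal(lib$components$drain_a$size_fr, 18)
  # {(1,4),(5,100)} under the zero-intercept constraint fits (4, 0, 0)
  expect_equal(lib$components$tube_a$curve$k1, 4, tolerance = 1e-9)
  expect_equal(lib$components$tube_a$curve$k2, 0, tolerance = 1e-9)
  expect_equal(pump_head_at(lib$pumps$pump_a, 3000, 0), 250)

  # a passive entry with nonzero k3 violates the load-time invariant
  bad_file <- file.path(dir, "bad.yaml")
  writeLines(c("components:",
               "  - name: leaky",
               "    kind: oxygenator",
               "    k1: 1",
               "    k2: 1",
               "    k3: 5"), bad_file)
  expect_error(load_component_library(bad_file), "k3 = 0")
})

test_that("circuit configs load against a library and reject broken refs", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "circuit.json")
  writeLines(jsonlite::toJSON(list(
    drainage_side = c("drain_18fr", "tube1"),
    pump = "centrifugal", rpm = 3000,
    return_side = c("tube2", "oxygenator", "tube3", "return_14fr"),
    cvp_mmhg = 4, bed_height_cm = 40), auto_unbox = TRUE), cfg)
  lib <- default_component_library()
  circ <- load_circuit_config(cfg, lib)
  expect_s3_class(circ, "circuit_definition")
  expect_equal(circ$cvp, 4)
  expect_equal(circ$bed_height_cm, 40)
  expect_equal(length(circ$return_side), 4)

  bad <- file.path(dir, "bad.json")
  writeLines(jsonlite::toJSON(list(
    drainage_side = c("no_such_cannula"), pump = "centrifugal", rpm = 3000,
    return_side = c("return_14fr")), auto_unbox = TRUE), bad)
  expect_error(load_circuit_config(bad, lib), "no_such_cannula")
})

test_that("a noiseless synthetic bench validates with perfect agreement end-to-end", {
  lib <- default_component_library()
  spec <- synthetic_bench_spec(sd_flow = 0, sd_pressure = 0, seed = 3)
  meas <- generate_synthetic_bench(spec, lib)
  expect_equal(nrow(meas), 36)
  report <- validate_predictions(run_sweep(spec$grid, lib), meas)
  expect_equal(report$label, c("flow", "P1", "P2", "P3"))
  expect_equal(report$r2, rep(1, 4))
  expect_equal(report$rmsd, rep(0, 4))
  expect_equal(report$bias_median, rep(0, 4))
  expect_equal(report$slope, rep(1, 4))
  expect_equal(report$intercept, rep(0, 4), tolerance = 1e-9)
})

test_that("the synthetic bench is seed-deterministic and leaves the RNG alone", {
  lib <- default_component_library()
  spec <- synthetic_bench_spec(seed = 17)
  a <- generate_synthetic_bench(spec, lib)
  set.seed(99)
  state <- .Random.seed
  b <- generate_synthetic_bench(spec, lib)
  expect_identical(a, b)
  expect_identical(.Random.seed, state)
  c <- generate_synthetic_bench(synthetic_bench_spec(seed = 18), lib)
  expect_false(identical(a$q_meas_l_min, c$q_meas_l_min))
})

test_that("small-noise bench recovers identity agreement within 3 standard errors", {
  lib <- default_component_library()
  spec <- synthetic_bench_spec(sd_flow = 0.05, sd_pressure = 2, seed = 11)
  meas <- generate_synthetic_bench(spec, lib)
  report <- validate_predictions(run_sweep(spec$grid, lib), meas)
  for (i in seq_len(nrow(report))) {
    row <- report[i, ]
    # reconstruct the slope/intercept standard errors from the series
    pred <- switch(row$label,
                   flow = run_sweep(spec$grid, lib)$q_l_min,
                   P1 = run_sweep(spec$grid, lib)$p1_mmhg,
                   P2 = run_sweep(spec$grid, lib)$p2_mmhg,
                   P3 = run_sweep(spec$grid, lib)$p3_mmhg)
    sd_true <- if (row$label == "flow") spec$sd_flow else spec$sd_pressure
    sxx <- sum((pred - mean(pred))^2)
    se_slope <- sd_true / sqrt(sxx)
    se_int <- sd_true * sqrt(1 / length(pred) + mean(pred)^2 / sxx)
    expect_lt(abs(row$slope - 1), 3 * se_slope)
    expect_lt(abs(row$intercept - 0), 3 * se_int)
    expect_gt(row$r2, 0.9)
  }
})

test_that("recovered flow RMSD estimates the injected noise level", {
  # E[RMSD] for iid Gaussian error of sd 0.1 over n = 36 is ~0.1; the mean
  # over Monte-Carlo repetitions must land within 10%
  lib <- default_component_library()
  grid <- sweep_grid()
  preds <- run_sweep(grid, lib)
  rmsds <- vapply(1:200, function(k) {
    spec <- synthetic_bench_spec(grid, sd_flow = 0.1, sd_pressure = 1,
                                 seed = 1000 + k)
    meas <- generate_synthetic_bench(spec, lib)
    sqrt(mean((preds$q_l_min - meas$q_meas_l_min)^2))
  }, numeric(1))
  expect_lt(abs(mean(rmsds) - 0.1), 0.01)
})

test_that("the CLI round-trips sweep -> synth-bench -> validate", {
  cli <- system.file("exec", "ecmoflow", package = "ecmoflow")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  pred_csv <- file.path(dir, "pred.csv")
  meas_csv <- file.path(dir, "meas.csv")
  expect_equal(system2("Rscript", c(cli, "sweep", "--out", pred_csv),
                       stderr = FALSE), 0L)
  expect_equal(system2("Rscript", c(cli, "synth-bench", "--seed", "7",
                                    "--sd-flow", "0", "--sd-pressure", "0",
                                    "--out", meas_csv), stderr = FALSE), 0L)
  out <- system2("Rscript", c(cli, "validate", "--pred", pred_csv,
                              "--meas", meas_csv), stdout = TRUE,
                 stderr = FALSE)
  report <- read.csv(text = out)
  expect_equal(report$label, c("flow", "P1", "P2", "P3"))
  expect_equal(report$rmsd, rep(0, 4))
  expect_equal(report$r2, rep(1, 4))
})

test_that("the shipped synthetic library matches the built-in one", {
  path <- system.file("extdata", "synthetic_library.yaml", package = "ecmoflow")
  expect_true(nzchar(path))
  lib <- load_component_library(path)
  ref <- default_component_library()
  expect_setequal(names(lib$components), names(ref$components))
  for (nm in names(ref$components)) {
    expect_equal(lib$components[[nm]]$curve$k1, ref$components[[nm]]$curve$k1,
                 tolerance = 1e-9)
    expect_equal(lib$components[[nm]]$curve$k2, ref$components[[nm]]$curve$k2,
                 tolerance = 1e-9)
  }
  circ <- load_circuit_config(
    system.file("extdata", "example_circuit.yaml", package = "ecmoflow"), lib)
  pred <- predict_circuit(circ)
  expect_gt(pred$q, 0)
  expect_lt(pred$p1, 0)  # suction side below bath pressure at this height
})
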