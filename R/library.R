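#' Component library
#'
#' A named collection of passive components and pumps against which circuit
#' configurations resolve their references.
#'
#' @param components list of [passive_component]
#' @param pumps list of [pump_model]
#' @return an object of class `component_library`
#' @export
component_library <- function(components = list(), pumps = list()) {
  for (x in components) stopifnot(inherits(x, "passive_component"))
  for (x in pumps) stopifnot(inherits(x, "pump_model"))
  names(components) <- vapply(components, `[[`, "", "name")
  names(pumps) <- vapply(pumps, `[[`, "", "name")
  if (anyDuplicated(names(components)) || anyDuplicated(names(pumps))) {
    stop("duplicate component or pump names in library", call. = FALSE)
  }
  structure(list(components = components, pumps = pumps),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component library: %d components, %d pump(s)>\n",
              length(x$components), length(x$pumps)))
  for (comp in x$components) print(comp)
  for (p in x$pumps) print(p)
  invisible(x)
}

get_component <- function(library, ref) {
  comp <- library$components[[ref]]
  if (is.null(comp)) {
    stop(sprintf("unresolvable component reference '%s'; available: %s",
                 ref, paste(names(library$components), collapse = ", ")),
         call. = FALSE)
  }
  comp
}

get_pump <- function(library, ref) {
  p <- library$pumps[[ref]]
  if (is.null(p)) {
    stop(sprintf("unresolvable pump reference '%s'; available: %s",
                 ref, paste(names(library$pumps), collapse = ", ")),
         call. = FALSE)
  }
  p
}

#' Built-in synthetic component library
#'
#' A self-contained bench-like component set: two drainage cannulas (18 and
#' 22 Fr), two return cannulas (14 and 18 Fr), an oxygenator, three
#' 3/8-inch connecting tubes at the default Alfred-guideline calibration,
#' and one centrifugal pump tabulated at 2500, 3000 and 3500 rpm. The
#' coefficient values are synthetic: they are shape-plausible (smaller
#' cannulas are steeper; higher speeds raise the shut-off head; flows land
#' in the 2.5-4.5 L/min range) but are NOT any manufacturer's published
#' characteristics.
#'
#' @return a [component_library]
#' @export
default_component_library <- function() {
  component_library(
    components = list(
      passive_component("drain_18fr", "drainage_cannula",
                        quadratic_curve(2.6, 4.5, 0), size_fr = 18),
      passive_component("drain_22fr", "drainage_cannula",
                        quadratic_curve(1.4, 2.5, 0), size_fr = 22),
      passive_component("return_14fr", "return_cannula",
                        quadratic_curve(6.5, 9.0, 0), size_fr = 14),
      passive_component("return_18fr", "return_cannula",
                        quadratic_curve(2.8, 5.0, 0), size_fr = 18),
      passive_component("oxygenator", "oxygenator",
                        quadratic_curve(0.8, 4.0, 0)),
      connecting_tube("tube1", length_m = 0.5),
      connecting_tube("tube2", length_m = 0.5),
      connecting_tube("tube3", length_m = 1.0)
    ),
    pumps = list(
      pump_model("centrifugal", list(
        `2500` = quadratic_curve(-2.0, -3.0, 180),
        `3000` = quadratic_curve(-2.0, -3.0, 260),
        `3500` = quadratic_curve(-2.0, -3.0, 350)
      ))
    )
  )
}

#' Read a catalog CSV of flow/pressure pairs
#'
#' Expects a UTF-8 comma-separated file with header
#' `flow_l_min,pressure_mmhg`.
#'
#' @param path file path
#' @param source_label provenance label (defaults to the file name)
#' @return a [catalog_points] object
#' @export
read_catalog_csv <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) {
    stop(sprintf("catalog file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("flow_l_min", "pressure_mmhg")
  if (!all(need %in% names(df))) {
    stop(sprintf("catalog %s must have header %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  catalog_points(df$flow_l_min, df$pressure_mmhg, source_label)
}

parse_curve_entry <- function(entry, where) {
  has_k <- all(c("k1", "k2", "k3") %in% names(entry))
  has_pts <- "points_file" %in% names(entry)
  if (has_k == has_pts) {
    stop(sprintf("%s: give either k1/k2/k3 or points_file, not both/neither",
                 where), call. = FALSE)
  }
  list(has_points = has_pts, entry = entry)
}

#' Load a component library from YAML or JSON
#'
#' Schema: a top-level `components` list, each entry with `name`, `kind`
#' (one of drainage_cannula, return_cannula, connecting_tube, oxygenator),
#' and either explicit `k1`/`k2`/`k3` or a `points_file` catalog CSV
#' (fitted at load time with the intercept constrained to zero); optional
#' `size_fr` and `length_m`. A top-level `pumps` list, each entry with
#' `name` and `curves`, a map keyed by rpm whose values again carry
#' `k1`/`k2`/`k3` or `points_file` (fitted unconstrained). Relative
#' `points_file` paths resolve against the library file's directory. All
#' type invariants (passive k3 = 0, pump shut-off head > 0) are enforced at
#' load time.
#'
#' @param path a `.yaml`/`.yml` or `.json` file
#' @return a [component_library]
#' @export
load_component_library <- function(path) {
  spec <- read_config(path)
  base_dir <- dirname(path)
  resolve <- function(f) if (grepl("^/", f)) f else file.path(base_dir, f)

  components <- lapply(spec$components, function(entry) {
    where <- sprintf("%s: component '%s'", basename(path),
                     entry$name %||% "<unnamed>")
    if (is.null(entry$name) || is.null(entry$kind)) {
      stop(sprintf("%s: 'name' and 'kind' are required", where),
           call. = FALSE)
    }
    pe <- parse_curve_entry(entry, where)
    curve <- if (pe$has_points) {
      fit_quadratic_curve(read_catalog_csv(resolve(entry$points_file),
                                           source_label = entry$name),
                          constrain_zero_intercept = TRUE)
    } else {
      quadratic_curve(entry$k1, entry$k2, entry$k3)
    }
    passive_component(entry$name, entry$kind, curve,
                      size_fr = entry$size_fr, length_m = entry$length_m)
  })

  pumps <- lapply(spec$pumps, function(entry) {
    where <- sprintf("%s: pump '%s'", basename(path),
                     entry$name %||% "<unnamed>")
    if (is.null(entry$name) || is.null(entry$curves)) {
      stop(sprintf("%s: 'name' and 'curves' are required", where),
           call. = FALSE)
    }
    curves <- lapply(names(entry$curves), function(rpm) {
      ce <- entry$curves[[rpm]]
      pe <- parse_curve_entry(ce, sprintf("%s @ %s rpm", where, rpm))
      if (pe$has_points) {
        fit_quadratic_curve(read_catalog_csv(resolve(ce$points_file),
                                             source_label = sprintf("%s@%s",
                                                                    entry$name,
                                                                    rpm)),
                            constrain_zero_intercept = FALSE)
      } else {
        quadratic_curve(ce$k1, ce$k2, ce$k3)
      }
    })
    names(curves) <- names(entry$curves)
    pump_model(entry$name, curves)
  })

  component_library(components = components, pumps = pumps)
}

#' Load a circuit configuration from YAML or JSON
#'
#' Schema: `drainage_side` and `return_side` (lists of component names),
#' `pump` (pump name), `rpm`, optional `cvp_mmhg` (default 0) and
#' `bed_height_cm` (default 0). References resolve against `library`.
#'
#' @param path a `.yaml`/`.yml` or `.json` file
#' @param library a [component_library]
#' @return a [circuit_definition]
#' @export
load_circuit_config <- function(path, library) {
  spec <- read_config(path)
  stopifnot(inherits(library, "component_library"))
  for (key in c("drainage_side", "pump", "rpm", "return_side")) {
    if (is.null(spec[[key]])) {
      stop(sprintf("%s: missing required key '%s'", basename(path), key),
           call. = FALSE)
    }
  }
  circuit_definition(
    drainage_side = lapply(unlist(spec$drainage_side), get_component,
                           library = library),
    pump = get_pump(library, spec$pump),
    rpm = as.numeric(spec$rpm),
    return_side = lapply(unlist(spec$return_side), get_component,
                         library = library),
    cvp = as.numeric(spec$cvp_mmhg %||% 0),
    bed_height_cm = as.numeric(spec$bed_height_cm %||% 0)
  )
}

read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop(sprintf("unsupported config format '.%s' (use YAML or JSON): %s",
                 ext, path), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
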