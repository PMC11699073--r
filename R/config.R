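#' Simulation run configuration
#'
#' Bundles every tunable parameter of the encounter risk simulation into a
#' validated list of class `"strike_config"`. All defaults can be overridden
#' here or from a YAML file via [read_config()].
#'
#' @param n_iterations Number of bootstrap iterations (default 1000).
#' @param seed Integer seed controlling every random draw of a run.
#' @param years Calendar years to simulate; `NULL` uses all years present in
#'   the transit data. Each year is simulated independently and per-iteration
#'   annual mortality is averaged across years.
#' @param encounter_radius Encounter (detection) radius in metres; one whale
#'   body length, default 13.5.
#' @param whale_speed Whale swimming speed in m/s used by the encounter
#'   kernel (default 1.0).
#' @param whale_height Vertical extent of an adult whale in metres
#'   (default 3); enters the unavoidable-zone test.
#' @param class_draft Named numeric vector of nominal drafts (m) per size
#'   class; also the upper bound of the random dive start depth.
#' @param suction_scalar Named numeric vector of propeller-suction scalars
#'   per size class (1 for vessels under 350 ft, 2 for OGVs).
#' @param descent_rate_range Range (m/s) of the uniform whale descent rate,
#'   default `c(0.81, 2.0)`.
#' @param reaction_distance_range Range (m) of the uniform whale reaction
#'   distance, default `c(10, 1200)`.
#' @param lethality_coefficients A [lethality_coefficients()] object.
#' @param correction_factor Multiplier (>= 1) applied to Small/Medium
#'   encounter probabilities to compensate for vessels absent from AIS;
#'   default 3.5.
#' @param species_indicator 0/1 species indicator passed to the lethality
#'   logistic (1 = non-humpback large whale; right whales use 1).
#' @param min_cell_depth Cells with mean depth strictly below this (m) are
#'   excluded (default 3).
#' @param cell_area Nominal grid cell area in square metres (default 1e8 for
#'   a 10 x 10 km cell).
#' @param speed_limits Retained vessel speed range in knots,
#'   default `c(0.2, 50)`.
#' @param disable_avoidance If `TRUE`, the avoidance outcome is forced to 0
#'   (used by sensitivity sweeps to bound the no-avoidance case).
#' @param recompute_elapsed If `TRUE`, counterfactual speed transforms
#'   recompute cell transit time as `segment_length / speed`; the default
#'   `FALSE` keeps the observed elapsed times (see the methods vignette).
#'
#' @return A list of class `"strike_config"`.
#' @seealso [read_config()], [write_config()], [lethality_coefficients()]
#' @export
#' @examples
#' cfg <- run_config(n_iterations = 100, seed = 42)
#' cfg$class_draft
run_config <- function(n_iterations = 1000L,
                       seed = 1L,
                       years = NULL,
                       encounter_radius = 13.5,
                       whale_speed = 1.0,
                       whale_height = 3,
                       class_draft = c(SmallMedium = 5, Large = 5, OGV = 15),
                       suction_scalar = c(SmallMedium = 1, Large = 1, OGV = 2),
                       descent_rate_range = c(0.81, 2.0),
                       reaction_distance_range = c(10, 1200),
                       lethality_coefficients = default_lethality_coefficients(),
                       correction_factor = 3.5,
                       species_indicator = 1,
                       min_cell_depth = 3,
                       cell_area = 1e8,
                       speed_limits = c(0.2, 50),
                       disable_avoidance = FALSE,
                       recompute_elapsed = FALSE) {
  cfg <- list(
    n_iterations = as.integer(n_iterations), seed = as.integer(seed),
    years = years, encounter_radius = encounter_radius,
    whale_speed = whale_speed, whale_height = whale_height,
    class_draft = class_draft, suction_scalar = suction_scalar,
    descent_rate_range = descent_rate_range,
    reaction_distance_range = reaction_distance_range,
    lethality_coefficients = lethality_coefficients,
    correction_factor = correction_factor,
    species_indicator = species_indicator,
    min_cell_depth = min_cell_depth, cell_area = cell_area,
    speed_limits = speed_limits,
    disable_avoidance = isTRUE(disable_avoidance),
    recompute_elapsed = isTRUE(recompute_elapsed)
  )
  class(cfg) <- "strike_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$n_iterations < 1L) .err("n_iterations must be >= 1")
  if (cfg$encounter_radius < 0) .err("encounter_radius must be >= 0")
  if (cfg$whale_speed < 0) .err("whale_speed must be >= 0")
  if (cfg$whale_height < 0) .err("whale_height must be >= 0")
  for (nm in c("class_draft", "suction_scalar")) {
    v <- cfg[[nm]]
    if (!all(size_classes() %in% names(v)))
      .err(nm, " must be named for all of: ",
           paste(size_classes(), collapse = ", "))
    if (any(v <= 0)) .err(nm, " entries must be > 0")
  }
  for (nm in c("descent_rate_range", "reaction_distance_range",
               "speed_limits")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      .err(nm, " must be a finite length-2 range with min <= max")
  }
  if (cfg$correction_factor < 1)
    .err("correction_factor must be >= 1")
  if (!cfg$species_indicator %in% c(0, 1))
    .err("species_indicator must be 0 or 1")
  if (cfg$cell_area <= 0) .err("cell_area must be > 0")
  if (!inherits(cfg$lethality_coefficients, "lethality_coefficients"))
    .err("lethality_coefficients must be built with lethality_coefficients()")
  cfg
}

#' @export
print.strike_config <- function(x, ...) {
  cat("Strike risk run configuration\n")
  cat(sprintf("  iterations: %d   seed: %d\n", x$n_iterations, x$seed))
  cat(sprintf("  encounter radius: %.1f m   whale speed: %.2f m/s   whale height: %.1f m\n",
              x$encounter_radius, x$whale_speed, x$whale_height))
  cat("  class draft (m):   ",
      paste(sprintf("%s=%g", names(x$class_draft), x$class_draft), collapse = "  "), "\n")
  cat("  suction scalar:    ",
      paste(sprintf("%s=%g", names(x$suction_scalar), x$suction_scalar), collapse = "  "), "\n")
  cat(sprintf("  descent rate: [%g, %g] m/s   reaction distance: [%g, %g] m\n",
              x$descent_rate_range[1], x$descent_rate_range[2],
              x$reaction_distance_range[1], x$reaction_distance_range[2]))
  cat(sprintf("  Small/Medium correction factor: %g\n", x$correction_factor))
  invisible(x)
}

#' Read or write a run configuration as YAML
#'
#' `read_config()` loads a YAML file and merges it over the [run_config()]
#' defaults; `write_config()` does the reverse. The YAML layout mirrors the
#' argument names of [run_config()]; the lethality block is a mapping with
#' keys `intercept`, `beta_speed`, `beta_size` (mapping by size class),
#' `beta_species` and `beta_speed_species`.
#'
#' @param path File path.
#' @param config A `"strike_config"` object.
#' @return `read_config()` returns a `"strike_config"`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    .err("unknown config entries: ", paste(bad, collapse = ", "))
  if (!is.null(raw$lethality_coefficients)) {
    lc <- raw$lethality_coefficients
    raw$lethality_coefficients <- lethality_coefficients(
      intercept = lc$intercept, beta_speed = lc$beta_speed,
      beta_size = unlist(lc$beta_size),
      beta_species = if (is.null(lc$beta_species)) 0 else lc$beta_species,
      beta_speed_species =
        if (is.null(lc$beta_speed_species)) 0 else lc$beta_speed_species)
  }
  for (nm in c("class_draft", "suction_scalar"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(run_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "strike_config"))
  out <- unclass(config)
  lc <- out$lethality_coefficients
  out$lethality_coefficients <- list(
    intercept = lc$intercept, beta_speed = lc$beta_speed,
    beta_size = as.list(lc$beta_size), beta_species = lc$beta_species,
    beta_speed_species = lc$beta_speed_species)
  out$class_draft <- as.list(out$class_draft)
  out$suction_scalar <- as.list(out$suction_scalar)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Hash a configuration for run metadata
#'
#' MD5 digest of the deparsed configuration, recorded in results so that a
#' stored run can be matched to the exact parameter set that produced it.
#'
#' @param config A `"strike_config"` object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

# Resolve a sweep parameter name into a modified config. Supports top-level
# scalar names ("whale_speed"), "<range>_min"/"<range>_max" aliases, and
# dotted paths into named vectors ("class_draft.OGV").
set_config_param <- function(config, name, value) {
  stopifnot(inherits(config, "strike_config"))
  cfg <- unclass(config)
  range_alias <- c(descent_rate_min = 1, descent_rate_max = 2,
                   reaction_distance_min = 1, reaction_distance_max = 2)
  if (name %in% names(range_alias)) {
    field <- if (grepl("^descent", name)) "descent_rate_range"
             else "reaction_distance_range"
    cfg[[field]][range_alias[[name]]] <- value
  } else if (grepl(".", name, fixed = TRUE)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]) ||
        !parts[2] %in% names(cfg[[parts[1]]]))
      .err("unknown config parameter: ", name)
    cfg[[parts[1]]][[parts[2]]] <- value
  } else if (name %in% names(cfg) &&
             !name %in% c("lethality_coefficients", "years")) {
    cfg[[name]] <- if (is.logical(cfg[[name]])) isTRUE(value) else value
  } else {
    .err("unknown config parameter: ", name)
  }
  class(cfg) <- "strike_config"
  validate_config(cfg)
}
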