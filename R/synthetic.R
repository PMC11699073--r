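#' Synthetic scenario specification
#'
#' Parameters of the synthetic study system: a shelf-like bathymetry grid,
#' monthly whale density surfaces built from seasonally shifting hotspots,
#' and class-specific vessel traffic. The defaults emulate the qualitative
#' structure of the real system -- ocean-going vessels concentrated in an
#' offshore lane, Large vessels spread over the shelf, Small/Medium traffic
#' nearshore and summer-peaking, whales wintering in the south of the domain
#' and shifting north in summer, and a population of 350 whales of which a
#' month-specific fraction is inside the modelled domain.
#'
#' @param grid_shape Integer `c(nx, ny)`: columns (offshore direction) and
#'   rows (south to north).
#' @param shelf List with `min_depth` (m), `max_depth` (m), `exponent`
#'   (curvature of the depth-vs-offshore-distance profile) and `noise_sd`
#'   (lognormal roughness). The deterministic profile increases monotonically
#'   offshore.
#' @param hotspots List of density hotspots, each a list with `x`,
#'   `y_winter`, `y_summer` (the centre migrates between these with the
#'   season), `spread` (Gaussian sd in cell units) and `weight`.
#' @param in_domain_fraction Length-12 vector: fraction of the population
#'   inside the domain each month (January first).
#' @param population_total Total population size (default 350).
#' @param traffic Per-class traffic settings; see Details.
#' @param exempt_fraction Probability a transit is exempt from speed
#'   restrictions.
#' @param years Calendar years to generate traffic for.
#' @param segment_length_range Range (m) of cell-crossing segment lengths
#'   (at most the 10 km cell size).
#' @param region_breaks Fractional latitude breaks passed to
#'   [region_bands()].
#' @param seed Integer seed; identical spec and seed give a byte-identical
#'   scenario.
#'
#' @details Traffic per class is a list with `intensity` (expected transits
#'   per cell-month at unit spatial weight), `season` (length-12 multiplier),
#'   `speed_mean`/`speed_sd` (knots; draws are clipped into the valid
#'   0.2--50 knot range) and a spatial pattern: `lane_x`/`lane_sd` for OGVs,
#'   `depth_range`/`deep_weight` for Large vessels, `nearshore_decay` for
#'   Small/Medium.
#'
#' @return A list of class `"scenario_spec"`.
#' @seealso [generate_scenario()]
#' @export
scenario_spec <- function(grid_shape = c(12L, 16L),
                          shelf = list(min_depth = 0.3, max_depth = 250,
                                       exponent = 2, noise_sd = 0.05),
                          hotspots = list(
                            list(x = 3, y_winter = 3, y_summer = 12,
                                 spread = 2.2, weight = 1),
                            list(x = 5, y_winter = 5, y_summer = 13,
                                 spread = 3.0, weight = 1)),
                          in_domain_fraction = c(0.9, 0.9, 0.9, 0.85, 0.6,
                                                 0.45, 0.35, 0.35, 0.45,
                                                 0.7, 0.9, 0.9),
                          population_total = 350,
                          traffic = list(
                            SmallMedium = list(intensity = 2.5,
                                               speed_mean = 18, speed_sd = 6,
                                               season = c(1, 1, 1, 1.5, 3, 3,
                                                          3, 3, 2, 1.5, 1, 1),
                                               nearshore_decay = 1.5),
                            Large = list(intensity = 3,
                                         speed_mean = 10, speed_sd = 3,
                                         season = c(0.8, 0.8, 0.9, 1, 1.2,
                                                    1.3, 1.3, 1.3, 1.2, 1,
                                                    0.9, 0.8),
                                         depth_range = c(3, 150),
                                         deep_weight = 0.25),
                            OGV = list(intensity = 12,
                                       speed_mean = 14, speed_sd = 3,
                                       season = rep(1, 12),
                                       lane_x = 6, lane_sd = 1.2)),
                          exempt_fraction = 0.05,
                          years = 2021L,
                          segment_length_range = c(2000, 10000),
                          region_breaks = c(0.25, 0.5, 0.65),
                          seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), shelf = shelf,
               hotspots = hotspots,
               in_domain_fraction = in_domain_fraction,
               population_total = population_total, traffic = traffic,
               exempt_fraction = exempt_fraction, years = as.integer(years),
               segment_length_range = segment_length_range,
               region_breaks = region_breaks, seed = as.integer(seed))
  class(spec) <- "scenario_spec"
  validate_scenario_spec(spec)
}

validate_scenario_spec <- function(spec) {
  if (length(spec$grid_shape) != 2L || any(spec$grid_shape < 2L))
    .err("grid_shape must be two integers >= 2")
  if (spec$population_total <= 0) .err("population_total must be > 0")
  if (length(spec$in_domain_fraction) != 12L ||
      any(spec$in_domain_fraction < 0) || any(spec$in_domain_fraction > 1))
    .err("in_domain_fraction must be 12 values in [0, 1]")
  if (!all(size_classes() %in% names(spec$traffic)))
    .err("traffic must be specified for all of: ",
         paste(size_classes(), collapse = ", "))
  for (cl in size_classes()) {
    tcl <- spec$traffic[[cl]]
    if (tcl$intensity < 0 || !is.finite(tcl$intensity))
      .err("traffic intensity for ", cl, " must be finite and >= 0")
    if (length(tcl$season) != 12L || any(tcl$season < 0))
      .err("traffic season for ", cl, " must be 12 non-negative values")
  }
  if (spec$exempt_fraction < 0 || spec$exempt_fraction > 1)
    .err("exempt_fraction must be in [0, 1]")
  nh <- vapply(spec$hotspots, function(h) {
    h$x >= 0 && h$x <= spec$grid_shape[1] - 1 &&
      h$y_winter >= 0 && h$y_winter <= spec$grid_shape[2] - 1 &&
      h$y_summer >= 0 && h$y_summer <= spec$grid_shape[2] - 1
  }, TRUE)
  if (!all(nh)) .err("hotspot centres must lie within the grid")
  spec
}

# Deterministic shelf depth profile at column x (0-based).
shelf_depth <- function(shelf, x, nx) {
  shelf$min_depth +
    (shelf$max_depth - shelf$min_depth) * ((x + 0.5) / nx)^shelf$exponent
}

#' Generate a shelf-like bathymetry grid
#'
#' Depth follows a monotone offshore profile (shallow at `x = 0`, deepening
#' toward `x = nx - 1`) with multiplicative lognormal roughness. Under the
#' default spec the nearshore column is shallower than the 3 m whale-depth
#' cutoff (exercising the cell filter) and early-shelf columns fall below
#' the 33 m OGV unavoidable-zone threshold.
#'
#' @param spec A [scenario_spec()].
#' @return Cell table as from [make_grid_cells()] (regions unset).
#' @export
generate_bathymetry <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed + 101L)
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  cells <- make_grid_cells(nx, ny, mean_depth = 0)
  base <- shelf_depth(spec$shelf, cells$x_index, nx)
  cells$mean_depth <- base * exp(rnorm(nrow(cells), 0, spec$shelf$noise_sd))
  cells
}

# Seasonal position weight: 0 in January, 1 in July.
season_phase <- function(month) (1 - cos(2 * pi * (month - 1) / 12)) / 2

#' Generate monthly whale density surfaces
#'
#' Places Gaussian hotspots whose centres migrate from their winter to their
#' summer position and back over the year, then scales each monthly surface
#' so it sums exactly to `population_total * in_domain_fraction[month]`.
#'
#' @param spec A [scenario_spec()].
#' @param cells Retained cell table (after the depth filter).
#' @return Density data frame (`cell_id`, `month`, `year`, `n_w`), one
#'   surface per month and year.
#' @export
generate_density <- function(spec, cells) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed + 202L)
  out <- vector("list", 12L * length(spec$years))
  k <- 0L
  for (yr in spec$years) {
    for (m in 1:12) {
      w <- numeric(nrow(cells))
      ph <- season_phase(m)
      for (h in spec$hotspots) {
        cy <- h$y_winter + ph * (h$y_summer - h$y_winter)
        w <- w + h$weight * exp(-((cells$x_index - h$x)^2 +
                                  (cells$y_index - cy)^2) /
                                  (2 * h$spread^2))
      }
      target <- spec$population_total * spec$in_domain_fraction[m]
      nw <- if (target == 0) {
        numeric(nrow(cells))
      } else if (sum(w) == 0) {
        rep(target / nrow(cells), nrow(cells))
      } else {
        w * (target / sum(w))
      }
      k <- k + 1L
      out[[k]] <- data.frame(cell_id = cells$cell_id, month = m, year = yr,
                             n_w = nw, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Spatial traffic weight of each cell for one size class.
traffic_weight <- function(class, tcl, cells) {
  switch(class,
    OGV = exp(-((cells$x_index - tcl$lane_x)^2) / (2 * tcl$lane_sd^2)),
    Large = ifelse(cells$mean_depth >= tcl$depth_range[1] &
                     cells$mean_depth <= tcl$depth_range[2],
                   1, tcl$deep_weight),
    SmallMedium = exp(-cells$x_index / tcl$nearshore_decay))
}

.class_category_pool <- list(
  SmallMedium = c("recreational", "fishing", "passenger"),
  Large = c("fishing", "passenger", "towing"),
  OGV = c("cargo", "tanker", "cruise"))

.class_length_range <- list(SmallMedium = c(26, 64.9),
                            Large = c(65, 350),
                            OGV = c(351, 1100))

.class_draft_range <- list(SmallMedium = c(1, 3), Large = c(3, 6),
                           OGV = c(10, 15))

#' Generate synthetic vessel traffic
#'
#' Transit counts per cell-month-class are Poisson with intensity
#' `intensity * spatial_weight * season[month]`; each transit gets a speed
#' drawn from the class Normal distribution clipped into the valid
#' 0.2--50 knot range, a segment length within the cell, an elapsed time
#' consistent with its speed (`segment / speed`), plausible length, draft
#' and category, and a Bernoulli exemption flag.
#'
#' @param spec A [scenario_spec()].
#' @param cells Retained cell table.
#' @return A validated transit data frame ([transit_schema()] columns).
#' @export
generate_traffic <- function(spec, cells) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed + 303L)
  rows <- list()
  counter <- 0L
  for (yr in spec$years) {
    for (cl in size_classes()) {
      tcl <- spec$traffic[[cl]]
      w <- traffic_weight(cl, tcl, cells)
      for (m in 1:12) {
        lam <- tcl$intensity * w * tcl$season[m]
        n_cell <- rpois(length(lam), lam)
        n <- sum(n_cell)
        if (n == 0L) next
        idx <- rep.int(seq_along(n_cell), n_cell)
        speed <- pmin(50, pmax(0.2, rnorm(n, tcl$speed_mean, tcl$speed_sd)))
        seg <- runif(n, spec$segment_length_range[1],
                     spec$segment_length_range[2])
        lr <- .class_length_range[[cl]]
        dr <- .class_draft_range[[cl]]
        rows[[length(rows) + 1L]] <- data.frame(
          transit_id = sprintf("t%08d", counter + seq_len(n)),
          cell_id = cells$cell_id[idx],
          month = m, year = yr,
          category = sample(.class_category_pool[[cl]], n, replace = TRUE),
          size_class = cl,
          length_ft = round(runif(n, lr[1], lr[2]), 1),
          draft_m = round(runif(n, dr[1], dr[2]), 2),
          speed_kn = round(speed, 2),
          segment_length_m = round(seg, 1),
          elapsed_s = round(seg / (speed * .KN2MS), 1),
          exempt = runif(n) < spec$exempt_fraction,
          stringsAsFactors = FALSE)
        counter <- counter + n
      }
    }
  }
  if (!length(rows)) {
    tr <- data.frame(transit_id = character(), cell_id = character(),
                     month = integer(), year = integer(),
                     category = character(), size_class = character(),
                     length_ft = numeric(), draft_m = numeric(),
                     speed_kn = numeric(), segment_length_m = numeric(),
                     elapsed_s = numeric(), exempt = logical(),
                     stringsAsFactors = FALSE)
    return(tr)
  }
  validate_transits(do.call(rbind, rows))
}

#' Generate a complete synthetic scenario
#'
#' Runs the full input-generation pipeline: bathymetry, whale-depth cell
#' filter, region assignment (latitude bands), monthly density surfaces,
#' class-specific traffic, and the default regional depth-exposure profiles.
#' The result feeds directly into [strike_risk()].
#'
#' @param spec A [scenario_spec()].
#' @return A [strike_scenario()] object.
#' @export
#' @examples
#' sc <- generate_scenario(scenario_spec(seed = 7))
#' sc
generate_scenario <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  cells <- generate_bathymetry(spec)
  cells <- filter_cells_by_depth(cells, min_depth = 3)
  cells <- assign_cell_region(
    cells, region_bands(spec$grid_shape[1], spec$grid_shape[2],
                        spec$region_breaks))
  density <- generate_density(spec, cells)
  transits <- generate_traffic(spec, cells)
  sc <- strike_scenario(transits, density, cells,
                        default_depth_profiles())
  sc$spec <- spec
  sc
}

#' Write or read a scenario as a directory of CSV files
#'
#' Writes `transits.csv`, `density.csv`, `bathymetry.csv` and
#' `profiles.csv` in the same dialects the grid readers consume, so a
#' written scenario round-trips through [read_scenario()].
#'
#' @param scenario A [strike_scenario()].
#' @param dir Directory path (created if needed).
#' @return `dir` (write) or a `"strike_scenario"` (read), invisibly/visibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "strike_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transits(scenario$transits, file.path(dir, "transits.csv"))
  write_density(scenario$density, file.path(dir, "density.csv"))
  write_bathymetry(scenario$cells, file.path(dir, "bathymetry.csv"))
  write_depth_profiles(scenario$profiles, file.path(dir, "profiles.csv"))
  invisible(dir)
}

#' @rdname write_scenario
#' @param config A [run_config()] used for transit filtering on read.
#' @param quiet Suppress filter messages.
#' @export
read_scenario <- function(dir, config = run_config(), quiet = TRUE) {
  cells <- read_bathymetry(file.path(dir, "bathymetry.csv"))
  cells <- filter_cells_by_depth(cells, config$min_cell_depth)
  transits <- load_and_filter_transits(file.path(dir, "transits.csv"),
                                       config, quiet = quiet)
  density <- read_density(file.path(dir, "density.csv"), cells)
  profiles <- read_depth_profiles(file.path(dir, "profiles.csv"))
  strike_scenario(transits, density, cells, profiles)
}
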