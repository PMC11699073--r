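#' Assemble a simulation scenario
#'
#' Bundles and cross-validates the four inputs of a run: the transit table,
#' the monthly density surfaces, the retained grid cells (with depth and
#' region) and the regional depth-exposure profiles. Every transit and
#' density record must resolve to a retained cell, and every cell region
#' must have an exposure profile.
#'
#' @param transits Validated transit data frame ([transit_schema()]).
#' @param density Density data frame (`cell_id`, `month`, `year`, `n_w`).
#' @param cells Retained cell table with `mean_depth` and `region`.
#' @param profiles Regional depth-exposure profiles.
#' @return A list of class `"strike_scenario"`.
#' @seealso [strike_risk()], [generate_scenario()]
#' @export
strike_scenario <- function(transits, density, cells,
                            profiles = default_depth_profiles()) {
  transits <- validate_transits(transits)
  profiles <- validate_depth_profiles(profiles)
  if (anyNA(cells$mean_depth)) .err("cells must all have a mean_depth")
  if (anyNA(cells$region))
    .err("cells must all carry a region (run assign_cell_region first)")
  density <- validate_density(density, cells)
  unknown <- setdiff(unique(transits$cell_id), cells$cell_id)
  if (length(unknown))
    .err("transits reference cells not in the retained grid: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  missing_prof <- setdiff(unique(cells$region), profiles$region)
  if (length(missing_prof))
    .err("no depth profile for region(s): ",
         paste(missing_prof, collapse = ", "))
  structure(list(transits = transits, density = density, cells = cells,
                 profiles = profiles),
            class = "strike_scenario")
}

#' @export
print.strike_scenario <- function(x, ...) {
  cat("Strike risk scenario\n")
  cat(sprintf("  %d retained cells, %d transits, %d density records\n",
              nrow(x$cells), nrow(x$transits), nrow(x$density)))
  yrs <- sort(unique(x$transits$year))
  if (length(yrs)) cat("  years:", paste(yrs, collapse = ", "), "\n")
  tab <- table(factor(x$transits$size_class, levels = size_classes()))
  cat("  transits by class: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

# Precompute every deterministic per-transit quantity for one transit set.
# Transits are put in transit_id order so that random draws, generated
# positionally, line up between paired scenario runs.
prepare_engine <- function(transits, density, cells, profiles, config) {
  tr <- transits[order(transits$transit_id), , drop = FALSE]
  ci <- match(tr$cell_id, cells$cell_id)
  if (anyNA(ci))
    .err("transits reference cells not in the retained grid: ",
         paste(utils::head(unique(tr$cell_id[is.na(ci)]), 5),
               collapse = ", "))
  if (any(cells$mean_depth[ci] < config$min_cell_depth))
    .err("transits cross cells shallower than the ", config$min_cell_depth,
         " m cutoff; filter cells and transits first")
  n <- nrow(tr)
  region <- cells$region[ci]
  bottom <- cells$mean_depth[ci]
  pi5 <- profiles$p_above_5m[match(region, profiles$region)]
  pi15 <- profiles$p_above_15m[match(region, profiles$region)]
  p_sd <- ifelse(tr$size_class == "OGV", pi15, pi5)
  v_ms <- tr$speed_kn * .KN2MS
  ep <- encounter_params(config$encounter_radius, config$whale_speed,
                         config$cell_area)
  lam_t <- if (n) encounter_probability(ep, v_ms, tr$elapsed_s) else numeric(0)
  corr <- ifelse(tr$size_class == "SmallMedium", config$correction_factor, 1)
  p_enc <- pmin(1, pmax(0, lam_t * p_sd * corr))
  draft <- unname(config$class_draft[tr$size_class])
  sz <- strike_zone(draft, unname(config$suction_scalar[tr$size_class]))
  p_leth <- if (n) lethality_probability(config$lethality_coefficients,
                                         tr$speed_kn, tr$size_class,
                                         config$species_indicator)
            else numeric(0)
  dkey <- paste(density$cell_id, density$month, density$year)
  nw <- density$n_w[match(paste(tr$cell_id, tr$month, tr$year), dkey)]
  nw[is.na(nw)] <- 0
  list(n = n, transits = tr, p_enc = p_enc, sz = sz,
       start_max = draft, bottom = bottom, v_ms = v_ms, p_leth = p_leth,
       n_w = nw,
       class_rows = lapply(size_classes(),
                           function(cl) which(tr$size_class == cl)))
}

# One stochastic replicate over a prepared transit set. Five draw vectors
# are generated unconditionally in a fixed order so that paired scenario
# runs consume identical variates transit by transit.
sim_mortality <- function(prep, config) {
  n <- prep$n
  if (n == 0L) return(numeric(0))
  u_strike <- runif(n)
  start <- runif(n) * prep$start_max
  rate <- runif(n, config$descent_rate_range[1], config$descent_rate_range[2])
  dist <- runif(n, config$reaction_distance_range[1],
                config$reaction_distance_range[2])
  u_leth <- runif(n)
  depth <- start + rate * dist / prep$v_ms
  avoid <- depth > prep$sz &
    prep$bottom > prep$sz + config$whale_height
  if (config$disable_avoidance) avoid <- rep(FALSE, n)
  (u_strike < prep$p_enc) * (!avoid) * (u_leth < prep$p_leth) * prep$n_w
}

#' Simulate the mortality contribution of one transit
#'
#' Runs the full per-transit composition once: the per-capita encounter
#' expectation times the strike-depth probability (scaled by the
#' Small/Medium correction factor where applicable, clamped into \[0, 1\])
#' gives the strike probability; a struck whale then gets one avoidance-dive
#' draw, and a non-avoided strike one lethality draw. The contribution is
#' `strike * (1 - avoid) * lethal * n_w`.
#'
#' @param transit One-row transit data frame.
#' @param cell One-row cell table row (supplies `mean_depth`, `region`).
#' @param n_w Expected whale count in the cell that month.
#' @param profiles Regional depth-exposure profiles.
#' @param config A [run_config()].
#' @param seed Optional seed for the draws.
#' @return Non-negative mortality contribution (real-valued: the binary
#'   outcome scaled by `n_w`).
#' @export
simulate_transit <- function(transit, cell, n_w,
                             profiles = default_depth_profiles(),
                             config = run_config(), seed = NULL) {
  stopifnot(nrow(transit) == 1L, nrow(cell) == 1L, n_w >= 0)
  cells <- cell
  if (!"region" %in% names(cells) || is.na(cells$region))
    .err("cell must carry a region")
  density <- data.frame(cell_id = transit$cell_id, month = transit$month,
                        year = transit$year, n_w = n_w,
                        stringsAsFactors = FALSE)
  prep <- prepare_engine(validate_transits(transit), density, cells,
                         validate_depth_profiles(profiles), config)
  if (!is.null(seed)) set.seed(seed)
  sum(sim_mortality(prep, config))
}

#' Simulate one annual replicate
#'
#' One stochastic pass over a transit set: the sum over months, cells and
#' transits of [simulate_transit()] contributions, returned by vessel size
#' class. Deterministic under `seed`.
#'
#' @param transits Validated transit data frame.
#' @param density Density surfaces covering the transits' months.
#' @param cells Retained cell table.
#' @param profiles Regional depth-exposure profiles.
#' @param config A [run_config()].
#' @param seed Optional seed.
#' @return Named numeric vector of mortality totals per size class.
#' @export
simulate_year <- function(transits, density, cells,
                          profiles = default_depth_profiles(),
                          config = run_config(), seed = NULL) {
  sc <- strike_scenario(transits, density, cells, profiles)
  prep <- prepare_engine(sc$transits, sc$density, sc$cells, sc$profiles,
                         config)
  if (!is.null(seed)) set.seed(seed)
  mort <- sim_mortality(prep, config)
  setNames(vapply(prep$class_rows, function(ix) sum(mort[ix]), 0),
           size_classes())
}

#' Bootstrap the annual vessel-strike mortality estimate
#'
#' The main model run. Each of `config$n_iterations` iterations redraws
#' every stochastic model component (strike occurrence, avoidance-dive
#' geometry, lethality outcome) for every transit, giving one replicate of
#' annual mortality per vessel size class; years are simulated independently
#' and averaged within each iteration. Iteration-level random substreams are
#' derived from `config$seed`, and draws are consumed positionally in
#' transit-id order, so two runs that share a seed and transit ids -- e.g. a
#' real-world run and its [slow_all_transform()] counterfactual -- reuse
#' identical draws for everything except the quantities that depend on
#' speed.
#'
#' @param scenario A [strike_scenario()].
#' @param config A [run_config()].
#' @return An object of class `"strike_risk"` with components
#'   \describe{
#'     \item{draws}{long data frame of per-iteration, per-year class totals}
#'     \item{summary}{per-class mean, sd and median of the per-iteration
#'       annual (across-year average) mortality}
#'     \item{cell_month}{mean mortality surface by cell, month and class}
#'     \item{apportionment}{percent of total risk per class (when total
#'       risk is positive)}
#'     \item{seed, config_hash, config, n_iterations, years}{run metadata}
#'   }
#' @seealso [apportion_risk()], [compare_scenarios()], [sensitivity_sweep()]
#' @export
#' @examples
#' sc <- generate_scenario(scenario_spec(grid_shape = c(8, 8), seed = 3))
#' fit <- strike_risk(sc, run_config(n_iterations = 50, seed = 3))
#' summary(fit)
strike_risk <- function(scenario, config = run_config()) {
  stopifnot(inherits(scenario, "strike_scenario"))
  config <- validate_config(config)
  years <- config$years
  if (is.null(years)) years <- sort(unique(scenario$transits$year))
  if (!length(years)) years <- sort(unique(scenario$density$year))
  if (!length(years)) years <- NA_integer_
  n_iter <- config$n_iterations
  preps <- lapply(years, function(yr) {
    tr <- scenario$transits[!is.na(yr) & scenario$transits$year == yr, ,
                            drop = FALSE]
    prepare_engine(tr, scenario$density, scenario$cells,
                   scenario$profiles, config)
  })
  set.seed(config$seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max - 1L,
                                n_iter * length(years)),
                     nrow = n_iter)
  cls <- size_classes()
  totals <- array(0, dim = c(n_iter, length(years), 3L))
  transit_sums <- lapply(preps, function(p) numeric(p$n))
  for (it in seq_len(n_iter)) {
    for (iy in seq_along(years)) {
      set.seed(seed_mat[it, iy])
      mort <- sim_mortality(preps[[iy]], config)
      if (length(mort)) {
        transit_sums[[iy]] <- transit_sums[[iy]] + mort
        totals[it, iy, ] <- vapply(preps[[iy]]$class_rows,
                                   function(ix) sum(mort[ix]), 0)
      }
    }
  }
  draws <- data.frame(
    iteration = rep(rep(seq_len(n_iter), length(years)), each = 3L),
    year = rep(rep(years, each = n_iter), each = 3L),
    size_class = rep(cls, n_iter * length(years)),
    mortality = as.vector(aperm(totals, c(3, 1, 2))),
    stringsAsFactors = FALSE)
  annual <- apply(totals, c(1, 3), mean)   # iteration x class, across years
  summ <- data.frame(
    size_class = cls,
    mean = apply(annual, 2, mean),
    sd = apply(annual, 2, sd),
    median = apply(annual, 2, median),
    stringsAsFactors = FALSE)
  cm <- do.call(rbind, lapply(seq_along(years), function(iy) {
    p <- preps[[iy]]
    if (p$n == 0L) return(NULL)
    data.frame(cell_id = p$transits$cell_id, month = p$transits$month,
               size_class = p$transits$size_class,
               m = transit_sums[[iy]] / n_iter, stringsAsFactors = FALSE)
  }))
  cell_month <- if (is.null(cm) || !nrow(cm)) {
    data.frame(cell_id = character(), month = integer(),
               size_class = character(), mortality = numeric(),
               stringsAsFactors = FALSE)
  } else {
    agg <- aggregate(m ~ cell_id + month + size_class, data = cm,
                     FUN = function(v) sum(v) / length(years))
    names(agg)[names(agg) == "m"] <- "mortality"
    agg[order(agg$size_class, agg$month, agg$cell_id), , drop = FALSE]
  }
  rownames(cell_month) <- NULL
  means <- setNames(summ$mean, summ$size_class)
  res <- structure(list(
    draws = draws, summary = summ, cell_month = cell_month,
    apportionment = if (any(means > 0)) apportion_risk(means) else NULL,
    seed = config$seed, config_hash = config_hash(config), config = config,
    n_iterations = n_iter, years = years, scenario = scenario),
    class = "strike_risk")
  res
}

#' Apportion total risk across vessel size classes
#'
#' Each class's share of total risk: its mean annual mortality divided by
#' the sum over classes, times 100.
#'
#' @param class_means Named numeric vector of mean annual mortality per
#'   size class (at least one positive, none negative).
#' @return Named numeric vector of percentages summing to 100.
#' @export
#' @examples
#' apportion_risk(c(OGV = 15.96, Large = 2.47, SmallMedium = 2.05))
apportion_risk <- function(class_means) {
  if (any(!is.finite(class_means)) || any(class_means < 0))
    .err("class means must be finite and >= 0")
  if (!any(class_means > 0))
    .err("cannot apportion risk: all class means are zero")
  100 * class_means / sum(class_means)
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs the bootstrap varying one configuration parameter at a time while
#' holding everything else -- including the base seed, hence the random
#' substreams -- fixed. Parameter names follow `set_config_param`: top-level
#' scalars (`"whale_speed"`, `"correction_factor"`, `"disable_avoidance"`,
#' ...), range endpoints (`"descent_rate_max"`, `"reaction_distance_min"`,
#' ...) and dotted entries of named vectors (`"class_draft.OGV"`).
#'
#' @param scenario A [strike_scenario()].
#' @param config Baseline [run_config()].
#' @param grid Named list mapping parameter names to value vectors; an
#'   empty list yields only the baseline rows.
#' @return Data frame with columns `parameter`, `value`, `size_class`,
#'   `mean`, `sd`; the baseline appears as parameter `"(baseline)"`.
#' @export
sensitivity_sweep <- function(scenario, config = run_config(),
                              grid = list()) {
  stopifnot(is.list(grid))
  row_of <- function(res, parameter, value) {
    data.frame(parameter = parameter, value = value,
               size_class = res$summary$size_class,
               mean = res$summary$mean, sd = res$summary$sd,
               stringsAsFactors = FALSE)
  }
  out <- list(row_of(strike_risk(scenario, config), "(baseline)", NA_real_))
  for (nm in names(grid)) {
    for (val in grid[[nm]]) {
      cfg <- set_config_param(config, nm, val)
      out[[length(out) + 1L]] <-
        row_of(strike_risk(scenario, cfg), nm, as.numeric(val))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a bootstrap result to CSV files
#'
#' Writes `draws.csv` (iteration-level totals), `cell_month.csv` (mean
#' mortality surface), `summary.csv`, and a `metadata.txt` sidecar with the
#' seed and configuration hash.
#'
#' @param result A `"strike_risk"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "strike_risk"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$draws, file.path(dir, "draws.csv"), row.names = FALSE)
  write.csv(result$cell_month, file.path(dir, "cell_month.csv"),
            row.names = FALSE)
  write.csv(result$summary, file.path(dir, "summary.csv"),
            row.names = FALSE)
  writeLines(c(sprintf("seed: %d", result$seed),
               sprintf("config_hash: %s", result$config_hash),
               sprintf("n_iterations: %d", result$n_iterations),
               sprintf("years: %s", paste(result$years, collapse = ","))),
             file.path(dir, "metadata.txt"))
  invisible(dir)
}
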