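#' Strike-zone depth of a vessel
#'
#' The depth band within which a whale can be struck: vessel draft times a
#' propeller-suction scalar. The scalar is 1 for Small/Medium and Large
#' vessels and 2 for ocean-going vessels, whose hydrodynamics draw a whale
#' toward the hull from as deep as twice the draft.
#'
#' @param draft Vessel draft in metres (>= 0); vectorised.
#' @param suction_scalar Dimensionless scalar (> 0); vectorised.
#' @return Strike-zone depth in metres.
#' @export
#' @examples
#' strike_zone(15, 2)  # OGV: 30 m
#' strike_zone(5, 1)   # Large: 5 m
strike_zone <- function(draft, suction_scalar = 1) {
  if (any(!is.finite(draft)) || any(draft < 0))
    .err("draft must be finite and >= 0")
  if (any(!is.finite(suction_scalar)) || any(suction_scalar <= 0))
    .err("suction_scalar must be finite and > 0")
  draft * suction_scalar
}

#' Whale depth when the vessel arrives
#'
#' Depth reached by a whale that starts its avoidance dive at
#' `start_depth` when the vessel is `reaction_distance` away and descends at
#' `descent_rate` until the vessel arrives:
#' `start_depth + descent_rate * reaction_distance / vessel_speed`.
#'
#' @param start_depth Initial whale depth in metres (>= 0); vectorised.
#' @param descent_rate Descent rate in m/s (>= 0); vectorised.
#' @param reaction_distance Distance (m) at which the whale reacts (>= 0);
#'   vectorised.
#' @param vessel_speed Vessel speed in m/s (> 0); vectorised.
#' @return Whale depth (m) at vessel arrival.
#' @export
#' @examples
#' whale_depth_at_arrival(2, 1.0, 500, knots_to_ms(10))
whale_depth_at_arrival <- function(start_depth, descent_rate,
                                   reaction_distance, vessel_speed) {
  if (any(!is.finite(vessel_speed)) || any(vessel_speed <= 0))
    .err("vessel_speed must be finite and > 0")
  if (any(start_depth < 0) || any(descent_rate < 0) ||
      any(reaction_distance < 0))
    .err("start_depth, descent_rate and reaction_distance must be >= 0")
  start_depth + descent_rate * reaction_distance / vessel_speed
}

#' Binary vertical-avoidance outcome
#'
#' A whale avoids the strike (outcome 1) only if it is deeper than the
#' vessel's strike zone when the vessel arrives *and* the water column
#' leaves it room to be there: bottom depth must exceed strike zone plus
#' whale height. Both inequalities are strict, so ties count as struck and
#' any bottom depth at or below `strike_zone + whale_height` is an
#' unavoidable zone (outcome 0 for every whale depth). For an OGV
#' (strike zone 30 m) with a 3 m whale this makes waters shallower than
#' 33 m unavoidable.
#'
#' @param whale_depth Whale depth (m) at vessel arrival; vectorised.
#' @param strike_zone Strike-zone depth (m); vectorised.
#' @param bottom_depth Cell mean bottom depth (m); vectorised.
#' @param whale_height Whale vertical extent (m), default 3.
#' @return Integer 0/1 avoidance indicator.
#' @export
#' @examples
#' avoid_outcome(35, 30, 40, 3)  # 1: deep enough, room below
#' avoid_outcome(35, 30, 32, 3)  # 0: unavoidable zone
avoid_outcome <- function(whale_depth, strike_zone, bottom_depth,
                          whale_height = 3) {
  if (any(whale_depth < 0) || any(strike_zone < 0) ||
      any(bottom_depth < 0) || any(whale_height < 0))
    .err("avoid_outcome inputs must be >= 0")
  as.integer(whale_depth > strike_zone &
             bottom_depth > strike_zone + whale_height)
}

#' Random avoidance-dive draws
#'
#' Draws the three stochastic components of the avoidance geometry as
#' independent uniforms on their configured ranges: start depth on
#' \[0, `start_depth_max`\] (the class maximum draft), descent rate on
#' `config$descent_rate_range` and reaction distance on
#' `config$reaction_distance_range`.
#'
#' @param n Number of draws.
#' @param start_depth_max Upper bound (m) of the start depth; the nominal
#'   class draft.
#' @param config A [run_config()] supplying the two ranges.
#' @return Data frame with columns `start_depth`, `descent_rate`,
#'   `reaction_distance`.
#' @export
draw_avoidance <- function(n, start_depth_max, config = run_config()) {
  stopifnot(n >= 0, all(start_depth_max >= 0))
  data.frame(
    start_depth = runif(n, 0, start_depth_max),
    descent_rate = runif(n, config$descent_rate_range[1],
                         config$descent_rate_range[2]),
    reaction_distance = runif(n, config$reaction_distance_range[1],
                              config$reaction_distance_range[2])
  )
}
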