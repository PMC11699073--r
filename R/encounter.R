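#' Encounter kernel parameters
#'
#' @param radius Detection radius in metres (one whale body length,
#'   default 13.5). An encounter is a proximity event in which the vessel
#'   passes within this distance of the whale.
#' @param whale_speed Whale swimming speed in m/s.
#' @param cell_area Area of the grid cell in square metres.
#' @return A list of class `"encounter_params"`.
#' @seealso [encounter_probability()]
#' @export
encounter_params <- function(radius = 13.5, whale_speed = 1.0,
                             cell_area = 1e8) {
  if (radius < 0) .err("radius must be >= 0")
  if (whale_speed < 0) .err("whale_speed must be >= 0")
  if (cell_area <= 0) .err("cell_area must be > 0")
  structure(list(radius = radius, whale_speed = whale_speed,
                 cell_area = cell_area),
            class = "encounter_params")
}

# Gerritsen-Strickler effective relative speed between two populations of
# randomly moving particles with speeds u and v: (b^2 + 3 a^2) / (3 a) with
# a = max(u, v), b = min(u, v). Reduces to the faster speed when the slower
# one is 0.
gs_relative_speed <- function(u, v) {
  a <- pmax(u, v)
  b <- pmin(u, v)
  ifelse(a > 0, (b^2 + 3 * a^2) / (3 * a), 0)
}

#' Per-capita encounter probability for one cell transit
#'
#' Expected number of proximity events between one randomly moving whale and
#' one vessel transiting a grid cell, under the two-dimensional
#' random-movement (ideal gas) encounter model: the vessel sweeps a strip of
#' width `2 * radius` at the Gerritsen--Strickler effective relative speed
#' \eqn{\tilde v = (u^2 + 3 v^2) / (3 v)} (for vessel speed \eqn{v \ge} whale
#' speed \eqn{u}; the symmetric form otherwise), so
#' \deqn{\lambda_e t = \frac{2 R \, \tilde v \, t}{A}.}
#'
#' The returned value is an expected count and may exceed 1 for extreme
#' parameters; the simulation engine clamps the product with the strike-depth
#' probability into \[0, 1\] before using it as a Bernoulli probability.
#' With a stationary whale (`whale_speed = 0`) the expression reduces exactly
#' to the swept-strip form \eqn{2 R L / A} with \eqn{L} the transit length.
#'
#' @param params An [encounter_params()] object.
#' @param vessel_speed Vessel speed in m/s (> 0); vectorised.
#' @param transit_time Seconds the vessel spends in the cell (> 0);
#'   vectorised.
#' @return Non-negative numeric vector of expected per-capita encounters.
#' @export
#' @examples
#' p <- encounter_params(radius = 13.5, whale_speed = 0, cell_area = 1e8)
#' # stationary whale, 10 km transit: swept strip 2 * 13.5 * 1e4 / 1e8
#' encounter_probability(p, vessel_speed = 5.144, transit_time = 1e4 / 5.144)
encounter_probability <- function(params, vessel_speed, transit_time) {
  stopifnot(inherits(params, "encounter_params"))
  if (any(!is.finite(vessel_speed)) || any(vessel_speed <= 0))
    .err("vessel_speed must be finite and > 0")
  if (any(!is.finite(transit_time)) || any(transit_time <= 0))
    .err("transit_time must be finite and > 0")
  vt <- gs_relative_speed(params$whale_speed, vessel_speed)
  2 * params$radius * vt * transit_time / params$cell_area
}
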