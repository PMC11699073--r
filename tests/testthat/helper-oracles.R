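# Independent oracles used to validate the model kernels. Everything here
# is deliberately written from first principles (its own arithmetic), not by
# calling the package's implementation paths.

# Brute-force moving-points encounter oracle. The whale starts uniformly in
# an L x L cell (L = sqrt(area)) with a uniform random heading; the vessel
# moves in a straight line. Positions evolve on a torus (periodic wrap keeps
# the uniform spatial density exact), and an encounter is a minimum
# whale-vessel distance below `radius` at any time in [0, t]. The minimum
# toroidal distance of linear relative motion is computed exactly as the
# smallest point-to-segment distance over periodic images.
mc_encounter_oracle <- function(radius, whale_speed, vessel_speed,
                                transit_time, area = 1e8, nsim = 1e5,
                                seed = 1) {
  set.seed(seed)
  L <- sqrt(area)
  theta <- runif(nsim, 0, 2 * pi)
  wx <- whale_speed * cos(theta) - vessel_speed  # relative velocity
  wy <- whale_speed * sin(theta)
  px <- runif(nsim, 0, L)
  py <- runif(nsim, 0, L)
  sx <- wx * transit_time                        # relative displacement
  sy <- wy * transit_time
  K <- ceiling((max(whale_speed + vessel_speed) * transit_time) / L) + 1L
  d2min <- rep(Inf, nsim)
  seg2 <- sx^2 + sy^2
  for (kx in -K:K) {
    for (ky in -K:K) {
      ax <- px + kx * L
      ay <- py + ky * L
      # distance from origin to segment [a, a + s]
      tpar <- pmin(1, pmax(0, -(ax * sx + ay * sy) / pmax(seg2, 1e-300)))
      cx <- ax + tpar * sx
      cy <- ay + tpar * sy
      d2min <- pmin(d2min, cx^2 + cy^2)
    }
  }
  p_hat <- mean(d2min < radius^2)
  list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / nsim), nsim = nsim)
}

# Numerically integrated probability that a whale fails to avoid: marginal
# over the three independent uniform dive draws. The reaction-distance
# dimension is integrated analytically through the uniform CDF; start depth
# and descent rate by a midpoint product rule (the integrand is then
# continuous, so the rule converges fast).
p_noavoid_quad <- function(sz, bottom, whale_height, start_max,
                           descent_range, react_range, v_ms, m = 301) {
  if (bottom <= sz + whale_height) return(1)
  s0 <- (seq_len(m) - 0.5) / m * start_max
  r <- descent_range[1] + (seq_len(m) - 0.5) / m * diff(descent_range)
  g <- expand.grid(s0 = s0, r = r)
  # whale depth exceeds sz iff reaction distance > (sz - s0) * v / r
  dcrit <- (sz - g$s0) * v_ms / g$r
  F_d <- pmin(1, pmax(0, (dcrit - react_range[1]) / diff(react_range)))
  mean(F_d)   # P(whale depth <= sz) = P(not avoided)
}

# Closed-form expected annual mortality per class for a small scenario,
# written with its own arithmetic end to end.
expected_mortality_oracle <- function(transits, cells, density, profiles,
                                      config) {
  kn2ms <- 0.514444
  out <- c(SmallMedium = 0, Large = 0, OGV = 0)
  for (i in seq_len(nrow(transits))) {
    tr <- transits[i, ]
    cell <- cells[cells$cell_id == tr$cell_id, ]
    d <- density[density$cell_id == tr$cell_id &
                 density$month == tr$month & density$year == tr$year, ]
    n_w <- if (nrow(d)) d$n_w else 0
    prof <- profiles[profiles$region == cell$region, ]
    p_sd <- if (tr$size_class == "OGV") prof$p_above_15m else prof$p_above_5m
    v <- tr$speed_kn * kn2ms
    u <- config$whale_speed
    vtilde <- if (v >= u) (u^2 + 3 * v^2) / (3 * v) else
      (v^2 + 3 * u^2) / (3 * u)
    lam_t <- 2 * config$encounter_radius * vtilde * tr$elapsed_s /
      config$cell_area
    corr <- if (tr$size_class == "SmallMedium") config$correction_factor else 1
    p_enc <- min(1, lam_t * p_sd * corr)
    draft <- config$class_draft[[tr$size_class]]
    sz <- draft * config$suction_scalar[[tr$size_class]]
    p_na <- p_noavoid_quad(sz, cell$mean_depth, config$whale_height, draft,
                           config$descent_rate_range,
                           config$reaction_distance_range, v)
    co <- config$lethality_coefficients
    lp <- co$intercept + co$beta_speed * tr$speed_kn +
      co$beta_size[[tr$size_class]] +
      co$beta_species * config$species_indicator +
      co$beta_speed_species * tr$speed_kn * config$species_indicator
    p_leth <- 1 / (1 + exp(-lp))
    out[tr$size_class] <- out[tr$size_class] +
      p_enc * p_na * p_leth * n_w
  }
  out
}
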