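test_that("degenerate transits contribute nothing", {
  cfg <- run_config()
  cell <- fixture_cells()[1, ]
  tr <- tr_row("t1", cell$cell_id, class = "OGV", speed = 14)
  # no whales
  expect_equal(simulate_transit(tr, cell, n_w = 0, config = cfg, seed = 1), 0)
  # whale never within strike depth
  prof0 <- data.frame(region = cell$region, p_above_5m = 0, p_above_15m = 0)
  for (s in 1:20)
    expect_equal(simulate_transit(tr, cell, n_w = 5, profiles = prof0,
                                  config = cfg, seed = s), 0)
})

test_that("a forced strike-no-avoid-lethal path returns n_w exactly", {
  # encounter certain (enormous transit time), exposure certain,
  # unavoidable water, lethality pinned at ~1
  cfg <- run_config(lethality_coefficients = lethality_coefficients(
    50, 0, c(SmallMedium = 0, Large = 0, OGV = 0)))
  cell <- data.frame(cell_id = "c9_9", x_index = 9, y_index = 9, area = 1e8,
                     mean_depth = 4, region = "CapeCodBay")
  prof1 <- data.frame(region = "CapeCodBay", p_above_5m = 1,
                      p_above_15m = 1)
  tr <- tr_row("t1", "c9_9", class = "Large", speed = 10, elapsed = 1e7)
  for (s in 1:5)
    expect_equal(simulate_transit(tr, cell, n_w = 2, profiles = prof1,
                                  config = cfg, seed = s), 2)
})

test_that("an empty transit set simulates to zero for every class", {
  out <- simulate_year(fixture_transits()[0, ], fixture_density(),
                       fixture_cells(), seed = 1)
  expect_equal(out, c(SmallMedium = 0, Large = 0, OGV = 0))
})

test_that("a transit referencing an unknown cell is a grid mismatch error", {
  tr <- tr_row("t1", "c99_99", class = "Large")
  expect_error(simulate_year(tr, fixture_density(), fixture_cells()),
               "not in the retained grid")
})

test_that("bootstrap mean matches the numerically integrated expectation", {
  cfg <- run_config(n_iterations = 2000, seed = 11)
  sc <- fixture_scenario()
  expected <- expected_mortality_oracle(sc$transits, sc$cells, sc$density,
                                        sc$profiles, cfg)
  fit <- strike_risk(sc, cfg)
  ann <- with(fit$draws, tapply(mortality, list(iteration, size_class), sum))
  for (cl in size_classes()) {
    se <- sd(ann[, cl]) / sqrt(nrow(ann))
    expect_lt(abs(mean(ann[, cl]) - expected[[cl]]), 3 * se)
  }
})

test_that("class totals conserve the per-cell-month mortality surface", {
  fit <- strike_risk(fixture_scenario(), run_config(n_iterations = 300,
                                                    seed = 4))
  by_class <- tapply(fit$cell_month$mortality, fit$cell_month$size_class,
                     sum)
  for (cl in size_classes())
    expect_equal(unname(by_class[cl]),
                 fit$summary$mean[fit$summary$size_class == cl],
                 tolerance = 1e-12)
})

test_that("mortality is exactly linear in the density surface", {
  cfg <- run_config(n_iterations = 200, seed = 9)
  sc1 <- fixture_scenario()
  dens2 <- fixture_density()
  dens2$n_w <- 2 * dens2$n_w
  sc2 <- strike_scenario(fixture_transits(), dens2, fixture_cells())
  f1 <- strike_risk(sc1, cfg)
  f2 <- strike_risk(sc2, cfg)
  # shared seed, per-capita draws: doubling N_w doubles every draw exactly
  expect_equal(f2$draws$mortality, 2 * f1$draws$mortality,
               tolerance = 1e-12)
})

test_that("expected mortality scales with the small-vessel correction factor", {
  sm_only <- fixture_transits()
  sm_only <- sm_only[sm_only$size_class == "SmallMedium", ]
  sc <- strike_scenario(sm_only, fixture_density(), fixture_cells())
  n_it <- 3000
  f1 <- strike_risk(sc, run_config(n_iterations = n_it, seed = 5,
                                   correction_factor = 1))
  f2 <- strike_risk(sc, run_config(n_iterations = n_it, seed = 5,
                                   correction_factor = 2))
  a1 <- with(subset(f1$draws, size_class == "SmallMedium"),
             tapply(mortality, iteration, sum))
  a2 <- with(subset(f2$draws, size_class == "SmallMedium"),
             tapply(mortality, iteration, sum))
  d <- a2 - 2 * a1  # shared substreams couple the runs
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(n_it) + 1e-12)
})

test_that("identical seed and config reproduce the result bit for bit", {
  cfg <- run_config(n_iterations = 100, seed = 21)
  f1 <- strike_risk(fixture_scenario(), cfg)
  f2 <- strike_risk(fixture_scenario(), cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$cell_month, f2$cell_month)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$config_hash, f2$config_hash)
})

test_that("multi-year runs average annual mortality across years", {
  tr <- fixture_transits()
  tr2 <- tr
  tr2$year <- 2022L
  tr2$transit_id <- sub("^t", "u", tr2$transit_id)
  dens <- fixture_density()
  dens2 <- dens
  dens2$year <- 2022L
  sc <- strike_scenario(rbind(tr, tr2), rbind(dens, dens2), fixture_cells())
  fit <- strike_risk(sc, run_config(n_iterations = 150, seed = 2))
  expect_equal(fit$years, c(2021L, 2022L))
  ann <- with(fit$draws, tapply(mortality, list(iteration, size_class),
                                mean))  # mean across the two years
  for (cl in size_classes())
    expect_equal(mean(ann[, cl]),
                 fit$summary$mean[fit$summary$size_class == cl],
                 tolerance = 1e-12)
})

test_that("risk apportionment is the normalised share of class means", {
  ap <- apportion_risk(c(OGV = 15.96, Large = 2.47, SmallMedium = 2.05))
  expect_equal(round(unname(ap["SmallMedium"]), 2), 10.01)
  expect_equal(sum(ap), 100)
  expect_equal(unname(apportion_risk(c(a = 0, b = 3, c = 0))["b"]), 100)
  expect_equal(unname(apportion_risk(c(1, 1, 2))), c(25, 25, 50))
  expect_error(apportion_risk(c(0, 0, 0)), "zero")
})

test_that("sensitivity sweeps vary one parameter at a time with shared draws", {
  sc <- fixture_scenario()
  cfg <- run_config(n_iterations = 150, seed = 13)
  base <- sensitivity_sweep(sc, cfg, grid = list())
  expect_equal(unique(base$parameter), "(baseline)")
  expect_equal(nrow(base), 3)

  sw <- sensitivity_sweep(sc, cfg, grid = list(
    disable_avoidance = TRUE,
    descent_rate_max = c(2.0, 3.0, 4.0)))
  # removing avoidance cannot reduce mortality (exact, paired draws)
  for (cl in size_classes()) {
    b <- base$mean[base$size_class == cl]
    noav <- sw$mean[sw$parameter == "disable_avoidance" &
                    sw$size_class == cl]
    expect_gte(noav, b)
  }
  # faster maximum descent weakly increases avoidance, so mortality is
  # non-increasing along the sweep (paired draws make this exact)
  for (cl in size_classes()) {
    ms <- sw$mean[sw$parameter == "descent_rate_max" & sw$size_class == cl]
    expect_true(all(diff(ms) <= 1e-12))
  }
  expect_error(sensitivity_sweep(sc, cfg, grid = list(warp_drive = 2)),
               "unknown config parameter")
})

test_that("zero density or zero traffic yields exactly zero mortality", {
  dens0 <- fixture_density()
  dens0$n_w <- 0
  f <- strike_risk(strike_scenario(fixture_transits(), dens0,
                                   fixture_cells()),
                   run_config(n_iterations = 50, seed = 1))
  expect_true(all(f$draws$mortality == 0))
  f2 <- strike_risk(strike_scenario(fixture_transits()[0, ],
                                    fixture_density(), fixture_cells()),
                    run_config(n_iterations = 50, seed = 1))
  expect_true(all(f2$draws$mortality == 0))
})

test_that("results write to CSV with reproducible metadata", {
  tmp <- withr::local_tempdir()
  fit <- strike_risk(fixture_scenario(), run_config(n_iterations = 40,
                                                    seed = 3))
  write_result(fit, tmp)
  expect_true(all(file.exists(file.path(tmp, c("draws.csv",
                                               "cell_month.csv",
                                               "summary.csv",
                                               "metadata.txt")))))
  meta <- readLines(file.path(tmp, "metadata.txt"))
  expect_match(meta[1], "seed: 3")
  expect_match(meta[2], fit$config_hash)
})
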