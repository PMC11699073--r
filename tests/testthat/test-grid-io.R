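write_transit_csv <- function(transits) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write.csv(transits, path, row.names = FALSE)
  path
}

test_that("track-quality filters drop erroneous speeds and zero elapsed times", {
  tr <- rbind(
    tr_row("a", "c0_0", speed = 55),             # > 50 kn
    tr_row("b", "c0_0", speed = 0.1),            # < 0.2 kn
    tr_row("c", "c0_0", speed = 10),
    tr_row("d", "c0_0", speed = 0.2),            # boundary kept
    tr_row("e", "c0_0", speed = 50),             # boundary kept
    tr_row("f", "c0_0", speed = 10, elapsed = 0) # zero elapsed
  )
  out <- suppressMessages(
    load_and_filter_transits(write_transit_csv(tr)))
  expect_setequal(out$transit_id, c("c", "d", "e"))

  # filtering is idempotent
  out2 <- filter_transits(out, quiet = TRUE)
  expect_identical(out, out2)
})

test_that("size class is assigned from the length bins", {
  tr <- rbind(
    tr_row("a", "c0_0", length_ft = 26),   # Small/Medium lower edge
    tr_row("b", "c0_0", length_ft = 64.9),
    tr_row("c", "c0_0", length_ft = 65),   # Large lower edge
    tr_row("d", "c0_0", length_ft = 350),
    tr_row("e", "c0_0", length_ft = 351),  # OGV
    tr_row("f", "c0_0", length_ft = 20)    # below 26 ft: dropped
  )
  tr$size_class <- "Large"  # deliberately wrong; length wins
  out <- suppressMessages(
    load_and_filter_transits(write_transit_csv(tr)))
  expect_equal(setNames(out$size_class, out$transit_id),
               c(a = "SmallMedium", b = "SmallMedium", c = "Large",
                 d = "Large", e = "OGV"))
})

test_that("malformed transit rows produce errors naming row and field", {
  tr <- rbind(tr_row("a", "c0_0"), tr_row("b", "c0_0"))
  tr$speed_kn[2] <- "fast"
  expect_error(filter_transits(tr), "row 2.*speed_kn")
  tr2 <- rbind(tr_row("a", "c0_0"))
  tr2$size_class <- "Gigantic"
  tr2$length_ft <- NA
  expect_error(filter_transits(tr2), "unknown size class")
})

test_that("imputation fills gaps from same-category donors and is reproducible", {
  tr <- rbind(
    tr_row("a", "c0_0", category = "bulk", draft_m = 11),
    tr_row("b", "c0_0", category = "bulk", draft_m = 13),
    tr_row("c", "c0_0", category = "bulk", draft_m = NA),
    tr_row("d", "c0_0", category = "ferry", draft_m = 6))
  out <- impute_vessel_characteristics(tr, seed = 1)
  expect_true(out$draft_m[3] %in% c(11, 13))
  expect_identical(out[c(1, 2, 4), ],
                   validate_transits(tr)[c(1, 2, 4), ])
  expect_identical(out, impute_vessel_characteristics(tr, seed = 1))

  # complete input passes through untouched
  full <- validate_transits(tr[c(1, 2, 4), ])
  expect_identical(impute_vessel_characteristics(full, seed = 3), full)

  # no donors in the category -> informative error
  lonely <- tr_row("x", "c0_0", category = "submarine", draft_m = NA)
  expect_error(impute_vessel_characteristics(lonely, seed = 1),
               "donors.*submarine")
})

test_that("imputed drafts follow the uniform donor distribution", {
  tr <- do.call(rbind, lapply(seq_len(1000), function(i)
    tr_row(sprintf("m%04d", i), "c0_0", category = "bulk", draft_m = NA)))
  donors <- rbind(tr_row("d1", "c0_0", category = "bulk", draft_m = 10),
                  tr_row("d2", "c0_0", category = "bulk", draft_m = 20))
  out <- impute_vessel_characteristics(rbind(donors, tr), seed = 9)
  # mean of 1000 uniform draws from {10, 20}: 15 +/- 3 * 5/sqrt(1000)
  expect_lt(abs(mean(out$draft_m[-(1:2)]) - 15), 3 * 5 / sqrt(1000))
})

test_that("density aggregation sums nested fine cells and conserves abundance", {
  fine <- expand.grid(x_index = 0:3, y_index = 0:3)
  fine$month <- 1L; fine$year <- 2021L
  one_block <- fine$x_index < 2 & fine$y_index < 2
  fine$n_w <- 0
  fine$n_w[one_block] <- c(0.1, 0.2, 0.3, 0.4)
  coarse <- aggregate_density_grid(fine)
  expect_equal(coarse$n_w[coarse$cell_id == "c0_0"], 1.0)
  expect_equal(sum(coarse$n_w), sum(fine$n_w))

  # all-zero surface stays zero
  fine$n_w <- 0
  expect_true(all(aggregate_density_grid(fine)$n_w == 0))

  # random surface: exact conservation, across months
  set.seed(4)
  big <- expand.grid(x_index = 0:9, y_index = 0:7, month = 1:3)
  big$year <- 2021L
  big$n_w <- runif(nrow(big), 0, 2)
  agg <- aggregate_density_grid(big)
  expect_equal(sum(agg$n_w), sum(big$n_w))
  for (m in 1:3)
    expect_equal(sum(agg$n_w[agg$month == m]),
                 sum(big$n_w[big$month == m]))

  # non-nesting (fractional indices) is an error
  fine$x_index <- fine$x_index + 0.5
  expect_error(aggregate_density_grid(fine), "nest")
})

test_that("the whale-depth cell filter is strict at 3 m", {
  cells <- make_grid_cells(5, 2, mean_depth = c(2.9, 3.0, 1, 2, 50,
                                                10, 20, 30, 2.99, 3.01))
  kept <- filter_cells_by_depth(cells)
  expect_false("c0_0" %in% kept$cell_id)  # 2.9 removed
  expect_true("c1_0" %in% kept$cell_id)   # 3.0 retained
  expect_equal(nrow(kept), 6)             # 4 of 10 below 3 m
  cells$mean_depth[1] <- NA
  expect_error(filter_cells_by_depth(cells), "mean_depth")
})

test_that("region assignment covers the grid and breaks boundary ties in fixed order", {
  cells <- make_grid_cells(4, 8, mean_depth = 50)
  bands <- region_bands(4, 8, breaks = c(0.25, 0.5, 0.75))
  out <- assign_cell_region(cells, bands)
  expect_false(anyNA(out$region))
  expect_equal(unique(out$region[out$y_index == 0]), "Southeast")
  expect_equal(unique(out$region[out$y_index == 7]), "Northeast")

  # centroid exactly on a shared edge goes to the first region in the
  # fixed order (Southeast before MidAtlantic)
  shared <- list(
    Southeast = cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)),
    MidAtlantic = cbind(c(0, 2, 2, 0), c(1, 1, 2, 2)))
  pt <- data.frame(cell_id = "p", x_index = 1, y_index = 1)
  expect_equal(assign_cell_region(pt, shared)$region, "Southeast")

  # centroid outside every region is an error, never a default
  outside <- data.frame(cell_id = "q", x_index = 10, y_index = 10)
  expect_error(assign_cell_region(outside, shared), "outside")
})

test_that("gridded inputs round-trip through their CSV dialects", {
  tmp <- withr::local_tempdir()
  cells <- assign_cell_region(make_grid_cells(3, 4, mean_depth = 10 + 1:12),
                              region_bands(3, 4))
  write_bathymetry(cells, file.path(tmp, "b.csv"))
  back <- read_bathymetry(file.path(tmp, "b.csv"))
  expect_equal(back[c("cell_id", "x_index", "y_index", "mean_depth",
                      "region")],
               cells[c("cell_id", "x_index", "y_index", "mean_depth",
                       "region")])

  dens <- data.frame(cell_id = cells$cell_id[1:3], month = 2L,
                     year = 2021L, n_w = c(0.5, 1.25, 0))
  write_density(dens, file.path(tmp, "d.csv"))
  expect_equal(read_density(file.path(tmp, "d.csv"), cells), dens)
  dens$n_w[1] <- -1
  expect_error(write_density(dens, file.path(tmp, "d.csv")), ">= 0")
})
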