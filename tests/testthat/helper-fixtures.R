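# Small hand-built fixtures shared across test files.

tr_row <- function(id, cell, month = 1, year = 2021, class = "Large",
                   speed = 10, seg = 8000,
                   elapsed = seg / (speed * 0.514444),
                   exempt = FALSE, category = "cat",
                   length_ft = c(SmallMedium = 45, Large = 200,
                                 OGV = 500)[[class]],
                   draft_m = c(SmallMedium = 2, Large = 4, OGV = 12)[[class]]) {
  data.frame(transit_id = id, cell_id = cell, month = month, year = year,
             category = category, size_class = class, length_ft = length_ft,
             draft_m = draft_m, speed_kn = speed, segment_length_m = seg,
             elapsed_s = elapsed, exempt = exempt, stringsAsFactors = FALSE)
}

# Four cells spanning the avoidable/unavoidable depth regimes and all four
# regions: c3_0 (5 m, Cape Cod Bay) is unavoidable for every class, c0_0
# (20 m) and c2_0 (30 m) only for OGVs, c1_0 (100 m) for none.
fixture_cells <- function() {
  data.frame(
    cell_id = c("c0_0", "c1_0", "c2_0", "c3_0"),
    x_index = 0:3, y_index = 0L, area = 1e8,
    mean_depth = c(20, 100, 30, 5),
    region = c("MidAtlantic", "Northeast", "Southeast", "CapeCodBay"),
    stringsAsFactors = FALSE)
}

fixture_density <- function() {
  g <- expand.grid(cell_id = c("c0_0", "c1_0", "c2_0", "c3_0"),
                   month = 1:2, stringsAsFactors = FALSE)
  g$year <- 2021L
  g$n_w <- c(6, 3, 8, 12, 4, 5, 2, 9)
  g
}

fixture_transits <- function() {
  rbind(
    tr_row("t01", "c3_0", 1, class = "SmallMedium", speed = 18),
    tr_row("t02", "c3_0", 2, class = "SmallMedium", speed = 22),
    tr_row("t03", "c0_0", 1, class = "SmallMedium", speed = 12),
    tr_row("t04", "c3_0", 1, class = "Large", speed = 10),
    tr_row("t05", "c3_0", 2, class = "Large", speed = 14),
    tr_row("t06", "c2_0", 1, class = "Large", speed = 8),
    tr_row("t07", "c0_0", 1, class = "OGV", speed = 14),
    tr_row("t08", "c1_0", 2, class = "OGV", speed = 18),
    tr_row("t09", "c2_0", 1, class = "OGV", speed = 12),
    tr_row("t10", "c1_0", 1, class = "OGV", speed = 21, seg = 9500),
    tr_row("t11", "c0_0", 2, class = "Large", speed = 16, seg = 5000),
    tr_row("t12", "c2_0", 2, class = "SmallMedium", speed = 30, seg = 4000))
}

fixture_scenario <- function() {
  strike_scenario(fixture_transits(), fixture_density(), fixture_cells(),
                  default_depth_profiles())
}

# A compact synthetic spec used where many scenarios must be generated.
small_spec <- function(seed) {
  scenario_spec(grid_shape = c(8L, 10L),
                hotspots = list(
                  list(x = 2, y_winter = 2, y_summer = 7,
                       spread = 2, weight = 1)),
                seed = seed)
}
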