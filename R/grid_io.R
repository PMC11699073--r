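#' Transit table column names
#'
#' Canonical header of the delimited transit table: one row is one vessel
#' track segment crossing one 10 x 10 km grid cell.
#'
#' @return Character vector of column names.
#' @export
transit_schema <- function() {
  c("transit_id", "cell_id", "month", "year", "category", "size_class",
    "length_ft", "draft_m", "speed_kn", "segment_length_m", "elapsed_s",
    "exempt")
}

# Coerce and check one numeric column, reporting the first offending row.
.check_num <- function(df, col, allow_na = FALSE) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- is.na(v) & !(allow_na & (is.na(df[[col]]) | df[[col]] == ""))
  if (any(bad))
    .err("transit row ", which(bad)[1], ": field '", col,
         "' is not numeric ('", df[[col]][which(bad)[1]], "')")
  v
}

# Structural validation + type coercion of an in-memory transit table.
validate_transits <- function(transits) {
  need <- transit_schema()
  miss <- setdiff(need, names(transits))
  if (length(miss))
    .err("transit table missing columns: ", paste(miss, collapse = ", "))
  tr <- transits[need]
  for (col in c("month", "year", "speed_kn", "segment_length_m",
                "elapsed_s"))
    tr[[col]] <- .check_num(tr, col)
  for (col in c("length_ft", "draft_m"))
    tr[[col]] <- .check_num(tr, col, allow_na = TRUE)
  bad_m <- !is.na(tr$month) & (tr$month < 1 | tr$month > 12 |
                               tr$month != round(tr$month))
  if (any(bad_m))
    .err("transit row ", which(bad_m)[1], ": field 'month' must be 1-12")
  if (is.character(tr$exempt) || is.factor(tr$exempt)) {
    ex <- toupper(trimws(as.character(tr$exempt)))
    val <- ex %in% c("TRUE", "FALSE", "T", "F", "0", "1")
    if (any(!val))
      .err("transit row ", which(!val)[1], ": field 'exempt' must be logical")
    tr$exempt <- ex %in% c("TRUE", "T", "1")
  } else {
    tr$exempt <- as.logical(tr$exempt) %in% TRUE
  }
  known <- is.na(tr$size_class) | tr$size_class %in% c(size_classes(), "")
  if (any(!known))
    .err("transit row ", which(!known)[1], ": unknown size class '",
         tr$size_class[which(!known)[1]], "'")
  tr$transit_id <- as.character(tr$transit_id)
  tr$cell_id <- as.character(tr$cell_id)
  tr$category <- as.character(tr$category)
  tr
}

#' Load, validate and filter a transit table
#'
#' Reads the CSV transit table (header exactly [transit_schema()]), then
#' applies the track-quality filters: speeds outside the retained range
#' (default 0.2--50 knots, both bounds kept) and zero or negative elapsed
#' times are dropped. Size class is (re)assigned from the length bins
#' 26--65 ft (Small/Medium), 65--350 ft (Large) and over 350 ft (OGV)
#' wherever length is known; records with known length below 26 ft fall
#' outside the modelled classes and are dropped. Records with missing length
#' keep their declared size class. Counts of dropped records are reported
#' with `message()`.
#'
#' @param path CSV file path.
#' @param config A [run_config()]; supplies `speed_limits`.
#' @param quiet Suppress the drop-count messages.
#' @return Validated, filtered transit data frame.
#' @seealso [impute_vessel_characteristics()], [write_transits()]
#' @export
load_and_filter_transits <- function(path, config = run_config(),
                                     quiet = FALSE) {
  tr <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  filter_transits(validate_transits(tr), config, quiet = quiet)
}

#' @rdname load_and_filter_transits
#' @param transits An in-memory transit table (already validated).
#' @export
filter_transits <- function(transits, config = run_config(),
                            quiet = FALSE) {
  tr <- validate_transits(transits)
  lim <- config$speed_limits
  bad_speed <- tr$speed_kn < lim[1] | tr$speed_kn > lim[2]
  bad_time <- tr$elapsed_s <= 0
  keep <- !bad_speed & !bad_time
  n_speed <- sum(bad_speed)
  n_time <- sum(bad_time & !bad_speed)
  tr <- tr[keep, , drop = FALSE]
  has_len <- !is.na(tr$length_ft)
  cls <- assign_size_class(tr$length_ft)
  tr$size_class[has_len] <- cls[has_len]
  sub_min <- has_len & is.na(cls)
  n_small <- sum(sub_min)
  tr <- tr[!sub_min, , drop = FALSE]
  if (any(is.na(tr$size_class) | tr$size_class == ""))
    .err("transit with neither a usable length nor a declared size class: ",
         tr$transit_id[which(is.na(tr$size_class) | tr$size_class == "")[1]])
  if (!quiet)
    message(sprintf(
      "transits: dropped %d erroneous-speed, %d zero-elapsed, %d below 26 ft; %d retained",
      n_speed, n_time, n_small, nrow(tr)))
  rownames(tr) <- NULL
  tr
}

#' Impute missing vessel characteristics from same-category donors
#'
#' Replaces missing `length_ft` and `draft_m` values by draws made uniformly
#' at random from the pool of known values of the same attribute among
#' vessels in the same category. Records with complete attributes are never
#' altered; with a fixed seed the output is bit-reproducible.
#'
#' @param transits Validated transit table.
#' @param seed Optional integer seed.
#' @param attributes Columns to impute.
#' @return Transit table with no missing values in `attributes`.
#' @export
impute_vessel_characteristics <- function(transits, seed = NULL,
                                          attributes = c("length_ft",
                                                         "draft_m")) {
  tr <- validate_transits(transits)
  if (!is.null(seed)) set.seed(seed)
  for (attr in attributes) {
    v <- tr[[attr]]
    if (!anyNA(v)) next
    for (cat in unique(tr$category[is.na(v)])) {
      in_cat <- tr$category == cat
      donors <- v[in_cat & !is.na(v)]
      need <- which(in_cat & is.na(v))
      if (!length(donors))
        .err("no known '", attr, "' donors in category '", cat, "'")
      v[need] <- donors[sample.int(length(donors), length(need),
                                   replace = TRUE)]
    }
    tr[[attr]] <- v
  }
  tr
}

#' Build a rectangular grid-cell table
#'
#' @param nx,ny Grid dimensions (columns x, rows y; 0-based indices).
#' @param mean_depth Numeric vector of cell mean depths (m, positive
#'   downward) in column-major order (x varying fastest), or a single value.
#' @param area Cell area in square metres (nominal 1e8 for 10 x 10 km).
#' @return Data frame with `cell_id` (`"c<x>_<y>"`), `x_index`, `y_index`,
#'   `area`, `mean_depth` and an unset `region` column.
#' @export
make_grid_cells <- function(nx, ny, mean_depth, area = 1e8) {
  stopifnot(nx >= 1, ny >= 1, area > 0)
  g <- expand.grid(x_index = 0:(nx - 1), y_index = 0:(ny - 1))
  data.frame(
    cell_id = paste0("c", g$x_index, "_", g$y_index),
    x_index = g$x_index, y_index = g$y_index,
    area = area, mean_depth = rep_len(mean_depth, nrow(g)),
    region = NA_character_, stringsAsFactors = FALSE
  )
}

#' Remove cells too shallow for a whale
#'
#' Cells with mean depth strictly below `min_depth` (default 3 m) are
#' excluded from simulation; a whale cannot physically occupy them.
#'
#' @param cells Cell table with a `mean_depth` column.
#' @param min_depth Strict lower bound in metres.
#' @return The retained cells.
#' @export
filter_cells_by_depth <- function(cells, min_depth = 3) {
  if (!"mean_depth" %in% names(cells) || anyNA(cells$mean_depth))
    .err("all cells must have a mean_depth")
  out <- cells[cells$mean_depth >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Boundary-inclusive point-in-polygon (ray casting + on-segment test).
# Written in-package because region assignment needs deterministic,
# documented behaviour for centroids lying exactly on a polygon edge.
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on_seg <- abs(cross) < 1e-12 &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

#' Assign each grid cell to a geographic region
#'
#' Tests each cell centroid (`x_index`, `y_index`) against the supplied
#' region polygons in the fixed order Southeast, Mid-Atlantic, Cape Cod Bay,
#' Northeast (any extra regions afterwards, in list order); the first
#' containing polygon wins, which is the documented tie-break for centroids
#' on a shared boundary. A centroid outside every polygon is an error -- no
#' silent default region.
#'
#' @param cells Cell table.
#' @param boundaries Named list of polygons (two-column matrices of x, y
#'   vertices in grid-index units), one per region.
#' @return The cell table with `region` filled in.
#' @seealso [region_bands()]
#' @export
assign_cell_region <- function(cells, boundaries) {
  stopifnot(is.list(boundaries), !is.null(names(boundaries)))
  ord <- c(intersect(regions(), names(boundaries)),
           setdiff(names(boundaries), regions()))
  region <- rep(NA_character_, nrow(cells))
  for (nm in ord) {
    hit <- is.na(region) &
      point_in_poly(cells$x_index, cells$y_index, boundaries[[nm]])
    region[hit] <- nm
  }
  if (anyNA(region))
    .err("cells outside all region boundaries: ",
         paste(utils::head(cells$cell_id[is.na(region)], 5), collapse = ", "))
  cells$region <- region
  cells
}

#' Latitude-band region polygons
#'
#' Convenience builder for region boundaries as horizontal bands of the
#' grid, south (low y) to north (high y): Southeast, Mid-Atlantic, Cape Cod
#' Bay, Northeast. `breaks` gives the fractional northern edge of the first
#' three bands.
#'
#' @param nx,ny Grid dimensions.
#' @param breaks Increasing fractions in (0, 1), length 3.
#' @return Named list of rectangle polygons for [assign_cell_region()].
#' @export
region_bands <- function(nx, ny, breaks = c(0.25, 0.5, 0.65)) {
  stopifnot(length(breaks) == 3, all(diff(breaks) > 0),
            breaks[1] > 0, breaks[3] < 1)
  edges <- c(-0.5, ny * breaks - 0.5, ny - 0.5)
  rect <- function(y0, y1)
    cbind(c(-0.5, nx - 0.5, nx - 0.5, -0.5), c(y0, y0, y1, y1))
  setNames(
    lapply(1:4, function(i) rect(edges[i], edges[i + 1])),
    c("Southeast", "MidAtlantic", "CapeCodBay", "Northeast")
  )
}

#' Aggregate a fine density surface onto the model grid
#'
#' Sums whale counts from a fine grid (e.g. 5 km) into coarse cells (e.g.
#' 10 km) that each contain exactly `factor` x `factor` fine cells.
#' Abundance is additive, so total abundance is conserved exactly.
#'
#' @param fine Data frame with `x_index`, `y_index`, `month`, `year`, `n_w`
#'   on the fine grid (0-based indices).
#' @param factor Integer nesting factor (default 2 for 5 km -> 10 km).
#' @return Density data frame (`cell_id`, `month`, `year`, `n_w`) on the
#'   coarse grid.
#' @export
aggregate_density_grid <- function(fine, factor = 2L) {
  need <- c("x_index", "y_index", "month", "year", "n_w")
  if (!all(need %in% names(fine)))
    .err("fine surface needs columns: ", paste(need, collapse = ", "))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    .err("nesting factor must be a positive integer")
  if (any(fine$x_index != round(fine$x_index)) ||
      any(fine$y_index != round(fine$y_index)) ||
      any(fine$x_index < 0) || any(fine$y_index < 0))
    .err("fine grid indices must be non-negative integers (grids must nest)")
  if (any(fine$n_w < 0)) .err("density values must be >= 0")
  cx <- fine$x_index %/% factor
  cy <- fine$y_index %/% factor
  key <- paste0("c", cx, "_", cy, "|", fine$month, "|", fine$year)
  sums <- rowsum(fine$n_w, key)
  parts <- do.call(rbind, strsplit(rownames(sums), "|", fixed = TRUE))
  out <- data.frame(cell_id = parts[, 1],
                    month = as.integer(parts[, 2]),
                    year = as.integer(parts[, 3]),
                    n_w = as.numeric(sums),
                    stringsAsFactors = FALSE)
  out <- out[order(out$year, out$month, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_density <- function(density, cells = NULL) {
  need <- c("cell_id", "month", "year", "n_w")
  if (!all(need %in% names(density)))
    .err("density surface needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(density$n_w)) || any(density$n_w < 0))
    .err("density values must be finite and >= 0")
  if (any(density$month < 1 | density$month > 12))
    .err("density month must be 1-12")
  if (!is.null(cells)) {
    unknown <- setdiff(unique(density$cell_id), cells$cell_id)
    if (length(unknown))
      .err("density references cells not in the retained grid: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  density
}

#' Read and write model inputs and surfaces as CSV
#'
#' Plain-text readers/writers for the three gridded inputs. Density:
#' `cell_id, month, year, n_w`. Bathymetry: `cell_id, x_index, y_index,
#' mean_depth_m` (plus an optional `region` column, used when present).
#' Transits: the [transit_schema()] columns.
#'
#' @param path CSV file path.
#' @param cells Optional retained cell table to validate `cell_id`s against.
#' @return A validated data frame (readers) or `path`, invisibly (writers).
#' @name grid_csv
NULL

#' @rdname grid_csv
#' @param density Density data frame.
#' @export
read_density <- function(path, cells = NULL) {
  validate_density(read.csv(path, stringsAsFactors = FALSE), cells)
}

#' @rdname grid_csv
#' @export
write_density <- function(density, path) {
  write.csv(validate_density(density), path, row.names = FALSE)
  invisible(path)
}

#' @rdname grid_csv
#' @param area Cell area used when rebuilding the cell table.
#' @export
read_bathymetry <- function(path, area = 1e8) {
  b <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "mean_depth_m") %in% names(b)))
    .err("bathymetry needs columns cell_id, mean_depth_m")
  if (anyNA(b$mean_depth_m)) .err("bathymetry has missing depths")
  if (!all(c("x_index", "y_index") %in% names(b))) {
    m <- regmatches(b$cell_id, regexec("^c(\\d+)_(\\d+)$", b$cell_id))
    ok <- lengths(m) == 3
    if (any(!ok))
      .err("cell_id not of the form c<x>_<y>: ", b$cell_id[which(!ok)[1]])
    b$x_index <- as.integer(vapply(m, `[`, "", 2))
    b$y_index <- as.integer(vapply(m, `[`, "", 3))
  }
  data.frame(cell_id = b$cell_id, x_index = b$x_index,
             y_index = b$y_index, area = area,
             mean_depth = b$mean_depth_m,
             region = if ("region" %in% names(b)) b$region
                      else NA_character_,
             stringsAsFactors = FALSE)
}

#' @rdname grid_csv
#' @export
write_bathymetry <- function(cells, path) {
  out <- data.frame(cell_id = cells$cell_id, x_index = cells$x_index,
                    y_index = cells$y_index,
                    mean_depth_m = cells$mean_depth,
                    region = cells$region, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname grid_csv
#' @param transits Transit data frame.
#' @export
write_transits <- function(transits, path) {
  write.csv(validate_transits(transits), path, row.names = FALSE)
  invisible(path)
}
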