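#' Default regional dive-depth exposure profiles
#'
#' Tag-derived weighted proportions of time right whales spend above 5 m and
#' above 15 m, by geographic region. These proportions are model inputs, not
#' quantities the simulator estimates; recomputing them from raw tag records
#' is out of scope.
#'
#' @return Data frame with columns `region`, `p_above_5m`, `p_above_15m`.
#' @seealso [p_strike_depth()], [read_depth_profiles()]
#' @export
default_depth_profiles <- function() {
  data.frame(
    region      = c("Northeast", "CapeCodBay", "MidAtlantic", "Southeast"),
    p_above_5m  = c(0.392, 0.910, 0.876, 0.564),
    p_above_15m = c(0.587, 0.953, 0.969, 0.930),
    stringsAsFactors = FALSE
  )
}

validate_depth_profiles <- function(profiles) {
  need <- c("region", "p_above_5m", "p_above_15m")
  if (!all(need %in% names(profiles)))
    .err("depth profiles need columns: ", paste(need, collapse = ", "))
  p5 <- profiles$p_above_5m
  p15 <- profiles$p_above_15m
  if (any(p5 < 0 | p5 > 1 | p15 < 0 | p15 > 1, na.rm = FALSE) ||
      any(is.na(p5)) || any(is.na(p15)))
    .err("depth proportions must lie in [0, 1]")
  if (any(p5 > p15))
    .err("p_above_5m cannot exceed p_above_15m (time above 5 m is a subset ",
         "of time above 15 m)")
  if (anyDuplicated(profiles$region))
    .err("duplicated region in depth profiles")
  profiles
}

#' Probability a whale is within a vessel's strike depth
#'
#' Maps a regional depth-exposure profile and a vessel size class to the
#' probability that a whale occupies the upper water column within the
#' vessel's draft: the proportion of time above 5 m for Small/Medium and
#' Large vessels, and above 15 m for ocean-going vessels. The exposure
#' threshold is tied to size class, not to a vessel's individual draft,
#' because exposure is only characterised at those two depths.
#'
#' @param profile A single-row data frame (or list) with `p_above_5m` and
#'   `p_above_15m`, e.g. one row of [default_depth_profiles()].
#' @param size_class One of `r paste(size_classes(), collapse = ", ")`.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' prof <- default_depth_profiles()
#' p_strike_depth(prof[prof$region == "Southeast", ], "OGV")   # 0.930
p_strike_depth <- function(profile, size_class) {
  if (!size_class %in% size_classes())
    .err("unknown size class: ", size_class)
  if (is.data.frame(profile) && nrow(profile) != 1L)
    .err("profile must be a single region profile")
  p <- if (size_class == "OGV") profile$p_above_15m else profile$p_above_5m
  p <- as.numeric(p)
  if (is.na(p) || p < 0 || p > 1) .err("profile proportion outside [0, 1]")
  p
}

#' Bernoulli draw of whale-at-depth occupancy
#'
#' @param p Probability the whale is within strike depth.
#' @param n Number of draws.
#' @return Integer vector of 0/1 indicators.
#' @export
draw_at_depth <- function(p, n = 1L) {
  if (!is.finite(p) || p < 0 || p > 1) .err("p must lie in [0, 1]")
  rbinom(n, 1L, p)
}

#' Read regional depth-exposure profiles from CSV
#'
#' Expects columns `region`, `p_above_5m`, `p_above_15m`.
#'
#' @param path CSV file path.
#' @return Validated profiles data frame.
#' @export
read_depth_profiles <- function(path) {
  validate_depth_profiles(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_depth_profiles
#' @param profiles Profiles data frame.
#' @export
write_depth_profiles <- function(profiles, path) {
  write.csv(validate_depth_profiles(profiles), path, row.names = FALSE)
  invisible(path)
}
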