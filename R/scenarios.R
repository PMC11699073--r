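#' Slow-all speed-restriction counterfactual
#'
#' Transforms a transit table as a universal 10-knot speed restriction
#' would: every non-exempt transit faster than `threshold` knots is
#' reassigned a speed drawn uniformly from `speed_range` (default
#' 9.5--10 knots); exempt transits and transits at or below the threshold
#' are unchanged. Applying the transform twice equals applying it once.
#'
#' By default observed elapsed times are kept, so the counterfactual changes
#' only the speed used by the encounter kernel, the avoidance geometry and
#' the lethality curve; set `recompute_elapsed = TRUE` to also stretch the
#' cell transit time to `segment_length / new_speed` (see the methods
#' vignette for the trade-off this introduces).
#'
#' @param transits Validated transit data frame.
#' @param speed_range Replacement speed range in knots.
#' @param threshold Speeds strictly above this are slowed.
#' @param recompute_elapsed Recompute `elapsed_s` from the new speed.
#' @param seed Optional seed for the replacement-speed draws.
#' @return The transformed transit table.
#' @seealso [compare_scenarios()]
#' @export
slow_all_transform <- function(transits, speed_range = c(9.5, 10),
                               threshold = 10, recompute_elapsed = FALSE,
                               seed = NULL) {
  tr <- validate_transits(transits)
  stopifnot(length(speed_range) == 2L, speed_range[1] <= speed_range[2])
  if (!is.null(seed)) set.seed(seed)
  idx <- !tr$exempt & tr$speed_kn > threshold
  if (any(idx)) {
    tr$speed_kn[idx] <- runif(sum(idx), speed_range[1], speed_range[2])
    if (recompute_elapsed)
      tr$elapsed_s[idx] <- tr$segment_length_m[idx] /
        (tr$speed_kn[idx] * .KN2MS)
  }
  tr
}

#' Compare real-world and counterfactual mortality
#'
#' Per-class percent decrease in mean annual mortality,
#' `100 * (mean_real - mean_slow) / mean_real`, plus an overall decrease
#' weighted by each class's share of real-world risk. Both results should
#' come from the same seed and transit ids so that random draws are shared.
#' A class with zero real-world mortality has no defined decrease and is
#' reported as `NA`.
#'
#' @param result_real,result_slow `"strike_risk"` objects for the baseline
#'   and counterfactual runs.
#' @return A data frame of class `"strike_comparison"` with columns
#'   `size_class`, `mean_real`, `mean_slow`, `pct_decrease`, and attribute
#'   `overall_pct_decrease` (risk-share-weighted).
#' @export
compare_scenarios <- function(result_real, result_slow) {
  stopifnot(inherits(result_real, "strike_risk"),
            inherits(result_slow, "strike_risk"))
  if (result_real$seed != result_slow$seed)
    warning("results come from different seeds; draws were not shared")
  mr <- setNames(result_real$summary$mean, result_real$summary$size_class)
  ms <- setNames(result_slow$summary$mean, result_slow$summary$size_class)
  cls <- size_classes()
  pct <- ifelse(mr[cls] > 0, 100 * (mr[cls] - ms[cls]) / mr[cls], NA_real_)
  out <- data.frame(size_class = cls, mean_real = unname(mr[cls]),
                    mean_slow = unname(ms[cls]),
                    pct_decrease = unname(pct), stringsAsFactors = FALSE)
  overall <- if (sum(mr) > 0) {
    share <- mr[cls] / sum(mr[cls])
    sum(share * pct, na.rm = TRUE)
  } else NA_real_
  attr(out, "overall_pct_decrease") <- unname(overall)
  class(out) <- c("strike_comparison", "data.frame")
  out
}

#' @export
print.strike_comparison <- function(x, ...) {
  cat("Scenario comparison (percent decrease in mean annual mortality)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  ov <- attr(x, "overall_pct_decrease")
  if (!is.null(ov) && is.finite(ov))
    cat(sprintf("Risk-share-weighted overall decrease: %.2f%%\n", ov))
  invisible(x)
}

#' Derive the small-vessel AIS correction factor
#'
#' Ratio of registered to AIS-observed unique vessels, aggregated across
#' categories within each size class with AIS-count weights (the
#' category-weighted mean of per-category ratios, which equals total
#' registered over total AIS). Compensates for vessels -- chiefly those
#' under 65 ft -- that are not required to carry AIS.
#'
#' @param counts Data frame with columns `size_class`, `category`,
#'   `registered`, `ais` (unique-vessel counts, all >= 0).
#' @return Named numeric vector: one correction factor per size class
#'   present in `counts`.
#' @export
#' @examples
#' derive_correction_factor(data.frame(
#'   size_class = "SmallMedium", category = c("rec", "fish"),
#'   registered = c(20, 40), ais = c(10, 10)))  # ratios 2 and 4 -> 3
derive_correction_factor <- function(counts) {
  need <- c("size_class", "category", "registered", "ais")
  if (!all(need %in% names(counts)))
    .err("counts needs columns: ", paste(need, collapse = ", "))
  if (any(counts$registered < 0) || any(counts$ais < 0))
    .err("counts must be >= 0")
  bad <- counts$ais == 0 & counts$registered > 0
  if (any(bad))
    .err("zero AIS count with nonzero registrations in category '",
         counts$category[which(bad)[1]], "' (",
         counts$size_class[which(bad)[1]], "): ratio uninformative")
  out <- vapply(split(counts, counts$size_class), function(d) {
    if (sum(d$ais) == 0) return(NA_real_)
    sum(d$registered) / sum(d$ais)
  }, 0)
  out[!is.na(out)]
}
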