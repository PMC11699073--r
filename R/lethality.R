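#' Lethality logistic coefficients
#'
#' Coefficients of the logistic model for the probability that a strike is
#' lethal: `logit(p) = intercept + beta_speed * speed + beta_size[class] +
#' beta_species * species + beta_speed_species * speed * species`, with
#' speed in knots and `species` a 0/1 indicator (1 = non-humpback large
#' whale).
#'
#' @param intercept Intercept on the logit scale.
#' @param beta_speed Per-knot speed slope.
#' @param beta_size Named numeric vector of size-class offsets covering all
#'   of `r paste(size_classes(), collapse = ", ")`; the reference class must
#'   have offset 0.
#' @param beta_species Species-indicator offset.
#' @param beta_speed_species Speed-by-species interaction (per knot).
#' @return A list of class `"lethality_coefficients"`.
#' @seealso [lethality_probability()], [default_lethality_coefficients()]
#' @export
lethality_coefficients <- function(intercept, beta_speed, beta_size,
                                   beta_species = 0,
                                   beta_speed_species = 0) {
  vals <- c(intercept, beta_speed, beta_size, beta_species,
            beta_speed_species)
  if (any(!is.finite(vals))) .err("lethality coefficients must be finite")
  if (!all(size_classes() %in% names(beta_size)))
    .err("beta_size must be named for all of: ",
         paste(size_classes(), collapse = ", "))
  if (!any(beta_size == 0))
    .err("one size class must be the reference (offset 0)")
  structure(list(intercept = intercept, beta_speed = beta_speed,
                 beta_size = beta_size[size_classes()],
                 beta_species = beta_species,
                 beta_speed_species = beta_speed_species),
            class = "lethality_coefficients")
}

#' Default lethality coefficients
#'
#' A documented placeholder coefficient set, *not* fitted values from any
#' strike database: the published analyses behind the lethality curve do not
#' print their coefficients, so quantitative fidelity requires user-supplied
#' values. The defaults are chosen so that (a) lethality rises steeply with
#' speed for the two sub-350-ft classes and (b) an OGV strike is
#' near-certainly lethal at any speed.
#'
#' @return A [lethality_coefficients()] object.
#' @export
default_lethality_coefficients <- function() {
  lethality_coefficients(
    intercept = -4.0,
    beta_speed = 0.35,
    beta_size = c(SmallMedium = 0, Large = 0.6, OGV = 8.0),
    beta_species = 0,
    beta_speed_species = 0
  )
}

#' Probability that a strike is lethal
#'
#' Inverse-logit of the linear predictor in vessel speed, size class and
#' species indicator; strictly inside (0, 1).
#'
#' @param coeffs A [lethality_coefficients()] object.
#' @param speed Vessel speed in knots (>= 0); vectorised.
#' @param size_class Vessel size class; vectorised (recycled against
#'   `speed`).
#' @param species_indicator 0/1 indicator (1 = non-humpback large whale).
#' @return Numeric vector of lethality probabilities.
#' @export
#' @examples
#' co <- lethality_coefficients(-1, 0.2, c(SmallMedium = 0, Large = 0, OGV = 0))
#' lethality_probability(co, 10, "Large")  # plogis(1) = 0.731
lethality_probability <- function(coeffs, speed, size_class,
                                  species_indicator = 1) {
  stopifnot(inherits(coeffs, "lethality_coefficients"))
  if (any(!is.finite(speed)) || any(speed < 0))
    .err("speed must be finite and >= 0")
  if (!all(size_class %in% size_classes()))
    .err("unknown size class: ",
         paste(unique(setdiff(size_class, size_classes())), collapse = ", "))
  if (!all(species_indicator %in% c(0, 1)))
    .err("species_indicator must be 0 or 1")
  lp <- coeffs$intercept + coeffs$beta_speed * speed +
    unname(coeffs$beta_size[size_class]) +
    coeffs$beta_species * species_indicator +
    coeffs$beta_speed_species * speed * species_indicator
  plogis(lp)
}

#' Import lethality coefficients from a CSV table
#'
#' Expects two columns, `term` and `value`, with terms `intercept`, `speed`,
#' `size_<class>` for each size class, `species` and `speed_species`
#' (missing `species`/`speed_species` terms default to 0).
#'
#' @param path CSV file path.
#' @return A [lethality_coefficients()] object.
#' @export
read_lethality_coefficients <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "value") %in% names(tab)))
    .err("coefficient table needs columns term, value")
  get <- function(term, default = NULL) {
    i <- match(term, tab$term)
    if (is.na(i)) {
      if (is.null(default)) .err("missing coefficient term: ", term)
      default
    } else tab$value[i]
  }
  lethality_coefficients(
    intercept = get("intercept"),
    beta_speed = get("speed"),
    beta_size = setNames(
      vapply(size_classes(), function(cl) get(paste0("size_", cl)), 0),
      size_classes()),
    beta_species = get("species", 0),
    beta_speed_species = get("speed_species", 0)
  )
}
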