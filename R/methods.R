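#' @export
print.strike_risk <- function(x, digits = 3, ...) {
  cat("Vessel strike encounter risk simulation\n")
  cat(sprintf("  %d bootstrap iterations, seed %d, year(s) %s\n",
              x$n_iterations, x$seed, paste(x$years, collapse = ", ")))
  cat("\nMean annual mortality by vessel size class:\n")
  print.data.frame(x$summary, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Summarise a strike risk simulation
#'
#' @param object A `"strike_risk"` object.
#' @param ... Unused.
#' @return A list of class `"summary.strike_risk"` with the per-class
#'   summary table, the risk apportionment (percent of total risk per
#'   class) and total mean annual mortality.
#' @export
summary.strike_risk <- function(object, ...) {
  structure(list(summary = object$summary,
                 apportionment = object$apportionment,
                 total_mean = sum(object$summary$mean),
                 n_iterations = object$n_iterations,
                 years = object$years, seed = object$seed),
            class = "summary.strike_risk")
}

#' @export
print.summary.strike_risk <- function(x, digits = 3, ...) {
  cat(sprintf("Annual vessel-strike mortality (%d iterations, seed %d)\n",
              x$n_iterations, x$seed))
  tab <- x$summary
  if (!is.null(x$apportionment))
    tab$pct_of_risk <- unname(x$apportionment[tab$size_class])
  print.data.frame(tab, row.names = FALSE, digits = digits)
  cat(sprintf("Total mean annual mortality: %.*f whales/year\n",
              max(0, digits - 1), x$total_mean))
  invisible(x)
}

#' Plot bootstrap mortality distributions
#'
#' Histogram of the per-iteration annual mortality for each vessel size
#' class, with the bootstrap mean marked.
#'
#' @param x A `"strike_risk"` object.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.strike_risk <- function(x, ...) {
  cls <- size_classes()
  op <- par(mfrow = c(1, length(cls)), mar = c(4, 4, 3, 1))
  on.exit(par(op))
  for (cl in cls) {
    d <- x$draws$mortality[x$draws$size_class == cl]
    ann <- tapply(d, x$draws$iteration[x$draws$size_class == cl], mean)
    hist(ann, main = cl, xlab = "Annual mortality (whales/yr)",
         col = "grey85", border = "grey40", ...)
    abline(v = mean(ann), lwd = 2)
  }
  mtext("Bootstrap annual vessel-strike mortality", outer = TRUE,
        line = -1.2, cex = 0.9)
  invisible(x)
}

#' Draw additional bootstrap replicates
#'
#' Re-runs the stored scenario for `nsim` fresh iterations, leaving the
#' fitted object untouched. Useful for checking bootstrap convergence.
#'
#' @param object A `"strike_risk"` object (which retains its scenario).
#' @param nsim Number of new iterations.
#' @param seed Seed for the new run.
#' @param ... Unused.
#' @return The `draws` data frame of the new run.
#' @export
simulate.strike_risk <- function(object, nsim = 100, seed = NULL, ...) {
  cfg <- object$config
  cfg$n_iterations <- as.integer(nsim)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  strike_risk(object$scenario, cfg)$draws
}
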