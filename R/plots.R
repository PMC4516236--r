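# Base-graphics methods for the analysis objects.

#' Plot a tornado diagram
#'
#' Horizontal bars from the outcome at each parameter's low bound to the
#' outcome at its high bound, widest span on top, with the base-case
#' outcome as a vertical reference line.
#'
#' @param x An `amd_tornado` object.
#' @param top Number of parameters to display (default 15).
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.amd_tornado <- function(x, top = 15, ...) {
  d <- utils::head(x[order(-x$span), ], top)
  d <- d[nrow(d):1, ]
  base <- attr(x, "base_outcome")
  xlim <- range(c(d$low, d$high, base), finite = TRUE)
  op <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", ylab = "",
                 xlab = if (attr(x, "outcome") == "icer")
                   "ICER (JPY/QALY)" else "blindness reduction (%)",
                 main = "One-way sensitivity analysis", ...)
  graphics::segments(d$low, seq_len(nrow(d)), d$high, seq_len(nrow(d)),
                     lwd = 8, col = "steelblue", lend = 1)
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$label, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Plot the cost-effectiveness plane of a PSA
#'
#' Incremental QALY (x) versus incremental cost (y) per draw, with the
#' willingness-to-pay threshold as a dashed line and draws in the
#' cost-effective region highlighted.
#'
#' @param x An `amd_psa` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.amd_psa <- function(x, ...) {
  d <- x$draws
  ce <- d$inc_qaly > 0 & d$inc_cost / d$inc_qaly < x$wtp
  graphics::plot(d$inc_qaly, d$inc_cost,
                 col = ifelse(ce, "forestgreen", "grey40"), pch = 16,
                 cex = 0.5, xlab = "incremental QALY",
                 ylab = "incremental cost (JPY)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(a = 0, b = x$wtp, lty = 2)
  invisible(x)
}

#' Plot per-age blindness-reduction curves
#'
#' Cumulative bilateral-blindness incidence per person by age for the two
#' strategies, plus the per-age percentage reduction.
#'
#' @param x An `amd_reduction` object.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.amd_reduction <- function(x, ...) {
  pa <- x$per_age
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(pa$age, cbind(pa$cum_blind_nonscreened,
                                  pa$cum_blind_screened),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "age", ylab = "cumulative blindness per person",
                    main = "Bilateral blindness by age", ...)
  graphics::legend("topleft", c("non-screened", "screened"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  graphics::plot(pa$age, pa$reduction_pct, type = "l", xlab = "age",
                 ylab = "reduction (%)", main = "Blindness reduction by age")
  invisible(x)
}

#' Plot state occupancy of a model run
#'
#' Stacked per-age occupancy of the joint two-eye stage categories.
#'
#' @param x An `amd_cohort` object.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.amd_cohort <- function(x, ...) {
  occ <- x$occupancy
  graphics::matplot(x$per_age$age, occ, type = "l", lty = 1,
                    xlab = "age", ylab = "occupancy (fraction of cohort)",
                    main = paste("State occupancy,", x$mode), ...)
  invisible(x)
}
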