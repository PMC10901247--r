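# Minimal per-pair comparison plot (base graphics): SNP effects with the
# fitted lines of each method, the usual visual check that the estimators
# agree in sign and slope.

#' Scatter plot of SNP effects with method fit lines
#'
#' Plots by against bx with error bars and one line per estimate (through
#' the origin for IVW and the weighted median slope; with intercept for
#' MR-Egger).
#'
#' @param h a `harmonized_set`.
#' @param estimates list of `mr_estimate` (from [run_all_methods()]).
#' @param ... passed to [plot()].
#' @return NULL, invisibly.
#' @export
mr_method_plot <- function(h, estimates, ...) {
  plot(h$bx, h$by, pch = 19, xlab = "SNP effect on exposure",
       ylab = "SNP effect on outcome", ...)
  segments(h$bx, h$by - 1.96 * h$se_y, h$bx, h$by + 1.96 * h$se_y,
           col = "grey60")
  cols <- c(ivw = "firebrick", egger = "steelblue",
            weighted_median = "darkgreen", wald = "black")
  for (e in estimates) {
    intercept <- if (e$method == "egger") e$extras$egger_intercept else 0
    graphics::abline(a = intercept, b = e$beta, col = cols[[e$method]], lwd = 2,
                     lty = if (e$method == "egger") 2 else 1)
  }
  graphics::legend("topleft", legend = vapply(estimates, `[[`, "", "method"),
                   col = cols[vapply(estimates, `[[`, "", "method")],
                   lwd = 2, bty = "n")
  invisible(NULL)
}
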