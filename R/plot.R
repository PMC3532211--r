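#' Plot a sweep
#'
#' Two stacked panels against the grid variable (effort or overlap): stage
#' biomasses of both species, and -- for effort sweeps -- per-species and
#' combined revenue.
#'
#' @param x a `flatmix_curve`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.flatmix_curve <- function(x, ...) {
  df <- as.data.frame(x)
  xv <- if (x$kind == "effort") df$E else df$omega
  xlab <- if (x$kind == "effort") "effort E" else "resource overlap omega"
  stages <- c("J_p", "LJ_p", "A_p", "J_s", "LJ_s", "A_s")
  old <- graphics::par(mfrow = c(if (x$kind == "effort") 2 else 1, 1),
                       mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::matplot(xv, as.matrix(df[stages]), type = "l", lty = rep(1:3, 2),
                    col = rep(c("firebrick", "steelblue"), each = 3),
                    xlab = xlab, ylab = "biomass (g/L)", ...)
  graphics::legend("topright", bty = "n", cex = 0.8, lty = rep(1:3, 2),
                   col = rep(c("firebrick", "steelblue"), each = 3),
                   legend = c("plaice J", "plaice LJ", "plaice A",
                              "sole J", "sole LJ", "sole A"))
  if (x$kind == "effort") {
    graphics::matplot(xv, as.matrix(df[c("revenue_plaice", "revenue_sole",
                                         "revenue_total")]),
                      type = "l", lty = c(2, 2, 1),
                      col = c("firebrick", "steelblue", "black"),
                      xlab = xlab, ylab = "revenue (EUR/L/d)")
    graphics::legend("topright", bty = "n", cex = 0.8, lty = c(2, 2, 1),
                     col = c("firebrick", "steelblue", "black"),
                     legend = c("plaice", "sole", "combined"))
  }
  invisible(x)
}
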