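#' Plot CSP component features across epochs
#'
#' Diagnostic plot of selected CSP feature columns over epochs, one curve
#' per component, with epochs grouped by label along the x axis.  Well
#' separated classes show the leading and trailing components moving in
#' opposite directions between the label groups.
#'
#' @param ft a [FeatureTable-class].
#' @param components feature column indices to draw; defaults to the first,
#'   middle and last component.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return Invisibly, the plotted matrix (epochs x components).
#' @export
plotCSPComponents <- function(ft, components = NULL, ...) {
  stopifnot(is(ft, "FeatureTable"))
  nf <- ncol(ft@X)
  if (is.null(components))
    components <- unique(c(1L, max(1L, nf %/% 2L), nf))
  ord <- order(match(ft@y, c(1, 0, -1)))
  M <- ft@X[ord, components, drop = FALSE]
  graphics::matplot(M, type = "l", lty = 1,
                    xlab = "epoch (grouped by label)",
                    ylab = "CSP log-variance feature",
                    main = sprintf("CSP components, band %s", ft@band), ...)
  grp <- ft@y[ord]
  brk <- which(diff(grp) != 0)
  if (length(brk)) graphics::abline(v = brk + 0.5, col = "grey60", lty = 3)
  graphics::legend("topright", bty = "n", lty = 1,
                   col = seq_along(components),
                   legend = sprintf("comp %d", components))
  invisible(M)
}
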