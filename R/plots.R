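#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a coverage-curvature fit
#'
#' Points with SEM error bars and the fitted through-origin line.
#'
#' @param object A `curvature_fit` from [fit_through_origin()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.curvature_fit <- function(object, ...) {
  d <- object$data
  if (!"sem" %in% names(d)) d$sem <- 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phi, y = .data$two_kappa_m)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "darkgreen") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$two_kappa_m - .data$sem,
                                        ymax = .data$two_kappa_m + .data$sem),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::expand_limits(x = 0, y = 0) +
    ggplot2::labs(x = expression(phi),
                  y = expression(2 * kappa * m ~ "(" * k[B] * T / nm * ")"),
                  title = object$label)
}
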