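#' Trace plot of retained draws
#'
#' @param object A `hic_chain`.
#' @param pars Parameters to show (column names of `object$draws`);
#'   defaults to `tau`, `gamma` and the component intercepts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hic_chain <- function(object, pars = NULL, ...) {
  draws <- object$draws
  if (is.null(pars)) {
    pars <- intersect(c("tau", "gamma",
                        sprintf("beta_k%d_p0", seq_len(object$K))),
                      names(draws))
  }
  long <- tidyr::pivot_longer(draws[, c(".draw", pars)], -".draw",
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$.draw, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = NULL,
                  title = "Posterior traces") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Probability heatmap of interaction calls
#'
#' Upper-triangle heatmap of the posterior true-signal probability; darker
#' colours mean higher probability.
#'
#' @param calls Call tibble from [call_interactions()].
#' @param fill Column to colour by (default `p_signal`).
#' @return A ggplot object.
#' @export
plot_calls <- function(calls, fill = "p_signal") {
  ggplot2::ggplot(calls, ggplot2::aes(.data$i, .data$j,
                                      fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin i", y = "bin j", fill = fill,
                  title = "Posterior interaction probabilities") +
    ggplot2::theme_minimal()
}
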