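#' Plot a composite-likelihood profile
#'
#' Plots the per-model composite log-likelihood relative to the neutral
#' reference along one grid axis (proposed position or a sweep parameter) —
#' the standard way to visualize where and how strongly selection is
#' supported.
#'
#' @param results A results tibble from [fit_mode()] (one mode or several
#'   bound together).
#' @param neutral_cle Scalar neutral composite log-likelihood.
#' @param axis Grid axis to profile over; see [cle_profile()].
#' @return A ggplot object.
#' @export
plot_profile <- function(results, neutral_cle, axis = "selected_sites") {
  prof <- cle_profile(results, neutral_cle, axis)
  ggplot2::ggplot(prof,
                  ggplot2::aes(x = .data[[axis]], y = .data$mcle,
                               color = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = axis, y = "composite log-likelihood (vs neutral)",
                  color = "model")
}

#' @rdname plot_profile
#' @param object A `cle_fit` from [fit_mode()].
#' @param ... Unused.
#' @export
autoplot.cle_fit <- function(object, neutral_cle = NULL,
                             axis = "selected_sites", ...) {
  if (is.null(neutral_cle)) neutral_cle <- 0
  plot_profile(object, neutral_cle, axis)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
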