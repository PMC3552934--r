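#' Plot an isotonic fit
#'
#' Raw input values (points, sized by weight) against the fitted nondecreasing
#' step function, with pooled blocks sharing one level.
#'
#' @param object An `isotonic_fit` from [pava()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.isotonic_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value, size = .data$weight),
                        shape = 1) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted), direction = "mid",
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::scale_size_continuous(range = c(2, 5)) +
    ggplot2::labs(x = "group", y = "value", size = "weight",
                  title = "Weighted isotonic regression") +
    ggplot2::theme_minimal()
}

#' Plot an estimation result
#'
#' For EM fits with a convergence trace, shows the observed-data
#' log-likelihood over iterations; otherwise (and additionally) the estimated
#' group-mean profile.
#'
#' @param object A `semiecol_fit`.
#' @param what `"mu"` (group-mean profile) or `"trace"` (log-likelihood over
#'   EM iterations, EM fits only).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.semiecol_fit <- function(object, what = c("mu", "trace"), ...) {
  what <- match.arg(what)
  if (what == "trace") {
    if (is.null(object$trace)) abort("this fit has no iteration trace.")
    return(
      ggplot2::ggplot(object$trace,
                      ggplot2::aes(x = .data$iter, y = .data$loglik)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::labs(x = "EM iteration", y = "observed-data log-likelihood",
                      title = paste0(object$method, " convergence")) +
        ggplot2::theme_minimal())
  }
  if (is.null(object$mu_hat)) abort("this fit carries no group-mean estimates.")
  td <- tibble(group = seq_along(object$mu_hat), mu_hat = object$mu_hat)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$group, y = .data$mu_hat)) +
    ggplot2::geom_line(colour = "grey50") + ggplot2::geom_point() +
    ggplot2::labs(x = "group", y = "estimated mean exposure",
                  title = paste0(object$method, " group-mean profile")) +
    ggplot2::theme_minimal()
}

#' Plot a bias table
#'
#' Mean relative bias of the slope by method across scenario cells, with
#' +/- 2 Monte-Carlo-SE error bars, faceted by measurement-error variance and
#' number of observed exposures.
#'
#' @param object A `bias_table` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bias_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$method, y = .data$bias_pct,
                               colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$bias_pct - 2 * .data$mc_se_bias_pct,
      ymax = .data$bias_pct + 2 * .data$mc_se_bias_pct), width = 0.2) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$sigma_eta2),
      cols = ggplot2::vars(.data$n_x), labeller = ggplot2::label_both) +
    ggplot2::labs(y = "relative bias of slope (%)", x = NULL,
                  title = "Slope bias by estimation method") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
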