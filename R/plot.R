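#' Plot evaluation metrics along the penalty grid
#'
#' For a [run_sweep()] result, draws precision, recall and f-score against
#' `-log10(lambda)`; for a [run_cross_comparison()] result, the f-score
#' between the two estimated networks against the first dataset's
#' `-log10(lambda)`. Weaker penalties (larger `-log10(lambda)`) give denser
#' networks, so these curves show the accuracy/complexity trade-off.
#'
#' @param object A `grn_sweep` or `grn_cross` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grn_sweep
#' @export
autoplot.grn_sweep <- function(object, ...) {
  long <- tibble::tibble(
    neglog10_lambda = rep(object$neglog10_lambda, 3L),
    metric = rep(c("precision", "recall", "f-score"),
                 each = nrow(object)),
    value = c(object$precision, object$recall, object$fscore)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$neglog10_lambda, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](lambda)), y = "metric",
                  colour = NULL,
                  title = "Estimated network vs gold standard along the penalty grid") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.grn_sweep
#' @method autoplot grn_cross
#' @export
autoplot.grn_cross <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$neglog10_lambda_a,
                                       y = .data$fscore)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](lambda) ~ "(dataset A)"),
                  y = "f-score between estimates",
                  title = "Agreement of networks estimated from two datasets") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
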