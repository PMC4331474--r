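#' Plot methods
#'
#' ggplot2 [ggplot2::autoplot()] methods for the package's result objects:
#' the membrane-potential trace (or spike raster) of a `spike_train`, the
#' convergence history of an `abc_result`, the per-class average firing
#' rates of a `spiking_classifier`, and the learning-error curves of a
#' `spiking_experiment`.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name spikebee-autoplot
#' @importFrom rlang .data
NULL

#' @rdname spikebee-autoplot
#' @export
autoplot.spike_train <- function(object, ...) {
  if (!is.null(object$trace)) {
    ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$t, y = .data$v)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (ms)", y = "membrane potential v (mV)",
                    title = paste0("Izhikevich neuron, I = ", object$current,
                                   " (", object$n_spikes, " spikes)")) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tidy.spike_train(object),
                    ggplot2::aes(x = .data$time, y = 1)) +
      ggplot2::geom_point(shape = "|", size = 4) +
      ggplot2::scale_y_continuous(breaks = NULL) +
      ggplot2::labs(x = "time (ms)", y = NULL,
                    title = paste0("Spike raster, I = ", object$current)) +
      ggplot2::theme_minimal()
  }
}

#' @rdname spikebee-autoplot
#' @export
autoplot.abc_result <- function(object, ...) {
  ggplot2::ggplot(tidy.abc_result(object),
                  ggplot2::aes(x = .data$cycle, y = .data$best_f)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "best-so-far objective",
                  title = "ABC convergence") +
    ggplot2::theme_minimal()
}

#' @rdname spikebee-autoplot
#' @export
autoplot.spiking_classifier <- function(object, ...) {
  afr <- object$afr
  afr$class <- factor(afr$class)
  ggplot2::ggplot(afr, ggplot2::aes(x = .data$afr, y = .data$class)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "average firing rate (spikes/ms)", y = "class",
                  title = "Per-class average firing rates (AFR)") +
    ggplot2::theme_minimal()
}

#' @rdname spikebee-autoplot
#' @export
autoplot.spiking_experiment <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$cycle, y = .data$best_error,
                               group = .data$run)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "generation", y = "learning error (best-so-far)",
                  title = "Learning-error curves across runs") +
    ggplot2::theme_minimal()
}
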