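#' Plot an event raster
#'
#' @param raster Binary event raster.
#' @param frames Optional 1-based frame indices to display.
#' @return A ggplot object (frames on x, neurons on y, active frames drawn).
#' @export
plot_raster <- function(raster, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(ncol(raster))
  d <- which(raster[, frames, drop = FALSE] == 1L, arr.ind = TRUE)
  df <- tibble::tibble(frame = frames[d[, 2]], neuron = d[, 1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$neuron)) +
    ggplot2::geom_tile(fill = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "frame", y = "neuron") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coact_sweep <- function(object, ...) {
  s <- summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$p_connect,
                                  y = .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sem,
      ymax = .data$mean_accuracy + .data$sem)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "input connection probability",
                  y = "classification accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coact_nn <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::labs(x = "output weight", y = "hidden units") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.results_bundle <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$runs,
    dplyr::all_of(c("accuracy_real", "accuracy_swap", "accuracy_sharc")),
    names_to = "test_set", values_to = "accuracy")
  d$test_set <- sub("accuracy_", "", d$test_set)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$test_set, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "test set", y = "accuracy") +
    ggplot2::theme_minimal()
}
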